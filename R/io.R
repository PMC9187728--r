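# CSV dialect: header names carry the units; internal tibbles use short names.
.csv_cols <- c(temperature = "temperature_C", ppfd = "ppfd_umol_m2_s",
               blue_ratio = "blue_ratio", replicate = "replicate",
               pn = "pn_umol_m2_s")

#' Read and write gas-exchange CSV files
#'
#' The on-disk dialect is a UTF-8 CSV with "." as the decimal separator and
#' header `temperature_C, ppfd_umol_m2_s, blue_ratio, replicate, pn_umol_m2_s`
#' (condition-level files omit `replicate`; prediction inputs may omit
#' `pn_umol_m2_s`). Internally the same data carry the short column names
#' `temperature`, `ppfd`, `blue_ratio`, `replicate`, `pn`.
#'
#' @param path File path.
#' @return `read_gas_exchange()` returns a tibble with the short column
#'   names; `write_gas_exchange()` returns `path` invisibly.
#' @export
read_gas_exchange <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  known <- .csv_cols[.csv_cols %in% names(raw)]
  missing_core <- setdiff(c("temperature_C", "ppfd_umol_m2_s", "blue_ratio"),
                          names(raw))
  if (length(missing_core))
    abort(paste("malformed gas-exchange CSV; missing column(s):",
                paste(missing_core, collapse = ", ")))
  out <- raw[, known]
  names(out) <- names(known)
  if (nrow(out) == 0) {
    out[] <- lapply(out, as.double)
    return(out)
  }
  bad <- !vapply(out, is.numeric, logical(1))
  if (any(bad)) {
    probe <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
    for (col in names(out)[bad]) {
      v <- suppressWarnings(as.numeric(probe[[known[[col]]]]))
      rows <- which(is.na(v) & !is.na(probe[[known[[col]]]]))
      abort(sprintf("non-numeric values in column '%s' at row(s) %s",
                    known[[col]], paste(head(rows, 5), collapse = ", ")))
    }
  }
  out
}

#' @rdname read_gas_exchange
#' @param data Tibble with the short column names.
#' @export
write_gas_exchange <- function(data, path) {
  stopifnot(is.data.frame(data))
  known <- .csv_cols[names(.csv_cols) %in% names(data)]
  out <- data[, names(known)]
  names(out) <- unname(known)
  readr::write_csv(out, path)
  invisible(path)
}

.model_format_version <- "1.0"

#' Serialize and restore fitted models as JSON
#'
#' Writes everything needed to apply a fitted `"rbf_model"` or
#' `"grnn_model"` -- centers/stored samples, widths, weights, spread,
#' normalization parameters, feature order -- together with a format
#' version; `read_model()` refuses files with a different major version.
#'
#' @param model A fitted `"rbf_model"` or `"grnn_model"`.
#' @param path Output path for the JSON document.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored model object.
#' @export
write_model <- function(model, path) {
  type <- if (inherits(model, "rbf_model")) "rbf"
          else if (inherits(model, "grnn_model")) "grnn"
          else abort("`model` must be an rbf_model or grnn_model")
  doc <- list(format_version = .model_format_version, type = type,
              norm = as.data.frame(model$norm[, c("feature", "z_min", "z_max")]),
              feature_order = model$feature_order)
  if (type == "rbf") {
    doc <- c(doc, list(
      centers = unname(as.matrix(model$centers)), widths = model$widths,
      weights = model$weights, spread = model$spread,
      spread_mode = model$spread_mode, ridge = model$ridge,
      bias = model$bias, h = model$h, seed = model$seed,
      train_mse_norm = model$train_mse_norm, n_train = model$n_train))
  } else {
    doc <- c(doc, list(X = unname(as.matrix(model$X)), y = model$y,
                       spread = model$spread))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format_version, .model_format_version))
    abort(sprintf("model format version mismatch: file has '%s', package reads '%s'",
                  doc$format_version %||% "<none>", .model_format_version))
  norm <- structure(as_tibble(doc$norm), class = c("pn_norm", class(as_tibble(doc$norm))))
  if (identical(doc$type, "rbf")) {
    structure(
      list(centers = as.matrix(doc$centers), widths = as.numeric(doc$widths),
           weights = as.numeric(doc$weights),
           spread = doc$spread, spread_mode = doc$spread_mode,
           ridge = doc$ridge, bias = isTRUE(doc$bias), h = doc$h,
           seed = doc$seed, norm = norm, feature_order = doc$feature_order,
           train_mse_norm = doc$train_mse_norm, n_train = doc$n_train),
      class = "rbf_model")
  } else if (identical(doc$type, "grnn")) {
    X <- as.matrix(doc$X)
    colnames(X) <- doc$feature_order
    structure(list(X = X, y = as.numeric(doc$y), spread = doc$spread,
                   norm = norm, feature_order = doc$feature_order),
              class = "grnn_model")
  } else {
    abort(sprintf("unknown model type '%s'", doc$type %||% "<none>"))
  }
}
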