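#' Write a PPG trace to CSV (and ground truth to a sidecar JSON)
#'
#' Columns are `time`, `i660`, `i940`. If `truth` is supplied it is written
#' alongside as JSON.
#'
#' @param ppg A [dw_ppg()] object.
#' @param path Output CSV path.
#' @param truth Optional list/data.frame of ground-truth values.
#' @param truth_path Sidecar path (default: `path` with a `.truth.json`
#'   suffix).
#' @return `path`, invisibly.
#' @export
write_ppg <- function(ppg, path, truth = NULL, truth_path = NULL) {
  df <- data.frame(time = ppg$time, i660 = ppg$i_red, i940 = ppg$i_ir)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth)) {
    if (is.null(truth_path)) {
      truth_path <- paste0(sub("\\.csv$", "", path), ".truth.json")
    }
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a PPG trace from CSV
#'
#' Expects columns `time`, `i660`, `i940` (as written by [write_ppg()]).
#'
#' @param path CSV path.
#' @return A [dw_ppg()] object.
#' @export
read_ppg <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "i660", "i940")
  if (!all(need %in% names(df))) {
    stop_invalid_input("PPG CSV must contain columns time, i660, i940")
  }
  dw_ppg(df$time, df$i660, df$i940, meta = list(source = path))
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds a mapping of [ppg_config()] argument names; unknown keys
#' are rejected. An optional top-level `coefficients` block (a list of two
#' wavelength entries, see [coefficients_from_config()]) is returned as an
#' attribute.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param seed Optional seed overriding the file's value (applied before
#'   validation, so stochastic configs can omit it from the file).
#' @return A `ppg_sim_config`, with attribute `coefs` if the file supplied
#'   coefficients.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  coefs <- NULL
  if (!is.null(raw$coefficients)) {
    coefs <- coefficients_from_config(raw$coefficients)
    raw$coefficients <- NULL
  }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  known <- names(formals(ppg_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- do.call(ppg_config, raw)
  if (!is.null(coefs)) attr(cfg, "coefs") <- coefs
  cfg
}
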