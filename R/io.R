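TIMECOURSE_COLUMNS <- c("substrate", "concentration_uM", "time_min",
                        "replicate", "product_nM")

#' Write a time-course dataset as tidy CSV (plus JSON provenance sidecar)
#'
#' One canonical CSV dialect is used throughout the package: comma
#' separated, dot decimal, header required, with the units embedded in
#' the column names (`concentration_uM`, `time_min`, `product_nM`). If
#' the dataset carries provenance (generating model, parameters, seed) it
#' is written next to the CSV as `<path>.provenance.json`.
#'
#' @param dataset a `proteodyn_dataset` (or data.frame with the schema
#'   columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(dataset, path) {
  miss <- setdiff(TIMECOURSE_COLUMNS, colnames(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  out <- dataset[, TIMECOURSE_COLUMNS]
  # full-precision doubles so a write -> read round trip is exact
  for (col in colnames(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  prov <- attr(dataset, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a time-course dataset from CSV
#'
#' Schema-validated load of the canonical tidy layout. The header must
#' carry the expected unit-suffixed column names (this is how units are
#' asserted); malformed or negative-product rows raise an error naming
#' the offending row numbers; design cells missing relative to the full
#' concentration x time x replicate grid are recorded in the
#' `missing_cells` attribute. A provenance sidecar, if present, is
#' re-attached.
#'
#' @param path CSV path.
#' @return a `proteodyn_dataset`.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TIMECOURSE_COLUMNS, colnames(d))
  if (length(miss))
    stop("malformed header; missing column(s): ",
         paste(miss, collapse = ", "),
         " (units are asserted through the column names)")
  for (col in c("concentration_uM", "time_min", "replicate", "product_nM")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop("malformed rows (non-numeric ", col, "): ",
           paste(utils::head(bad, 10), collapse = ", "))
    if (anyNA(v))
      stop("malformed rows (empty ", col, "): ",
           paste(utils::head(which(is.na(v)), 10), collapse = ", "))
    d[[col]] <- v
  }
  neg <- which(d$product_nM < 0)
  if (length(neg))
    stop("negative product concentrations in rows: ",
         paste(utils::head(neg, 10), collapse = ", "))
  # design completeness over the full grid
  full <- expand.grid(concentration_uM = unique(d$concentration_uM),
                      time_min = unique(d$time_min),
                      replicate = unique(d$replicate))
  key <- function(x) paste(x$concentration_uM, x$time_min, x$replicate)
  missing_cells <- full[!key(full) %in% key(d), , drop = FALSE]
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    attr(d, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  attr(d, "missing_cells") <- missing_cells
  class(d) <- c("proteodyn_dataset", "data.frame")
  d
}

#' Write a trajectory as tidy CSV
#'
#' Long format: `time_min`, `species`, `value`.
#'
#' @param trajectory any of the package's trajectory data.frames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  sp <- setdiff(colnames(trajectory), "time")
  long <- do.call(rbind, lapply(sp, function(s)
    data.frame(time_min = trajectory$time, species = s,
               value = trajectory[[s]])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

RUN_CONFIG_KEYS <- c("model", "parameters", "design", "dataset",
                     "protocol", "solver", "seed", "output_dir")

#' Read and validate a run configuration (YAML or JSON)
#'
#' A run configuration names a model, parameter overrides, a shipped
#' design (by name) or a dataset path, a protocol block, solver
#' tolerances, a seed and an output directory. Unknown keys are rejected
#' before any computation.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated config list of class `proteodyn_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model)) stop("config must name a model")
  if (!all(cfg$model %in% MODEL_IDS))
    stop("config names unknown model(s): ",
         paste(setdiff(cfg$model, MODEL_IDS), collapse = ", "))
  if (!is.null(cfg$parameters)) {
    bad <- setdiff(names(cfg$parameters), names(param_template()))
    if (length(bad))
      stop("config sets unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$design) && is.character(cfg$design) &&
      !cfg$design %in% names(default_designs()))
    stop("unknown design '", cfg$design, "'; shipped designs: ",
         paste(names(default_designs()), collapse = ", "))
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || length(cfg$seed) != 1))
    stop("seed must be a single number")
  structure(cfg, class = c("proteodyn_config", class(cfg)))
}
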