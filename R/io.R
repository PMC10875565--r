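config_required_keys <- c("N", "w", "a", "dt")
config_known_keys <- c(config_required_keys,
                       "c1", "d1", "c2", "d2", "S1", "S2",
                       "k0", "scenario", "n_reps", "seed", "horizon",
                       "y0", "max_steps")

#' Read and validate a JSON model configuration
#'
#' Configurations are flat JSON objects whose keys mirror the model
#' parameter names: `N, w, a, dt` are required, payoffs come either raw
#' (`c1, d1, c2, d2`) or composite (`S1, S2`; raw takes precedence), and
#' run-level keys (`k0, scenario, n_reps, seed, horizon, y0, max_steps`)
#' are passed through. Grid keys (`a`, `w`, `S1`) may be JSON arrays for
#' sweep configurations. Unknown keys raise a warning; missing required
#' keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A named list of validated configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration file not found: %s", path),
          class = "ecomoran_io_error")
  }
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("malformed JSON in %s: %s", path,
                                  conditionMessage(e)),
                          class = "ecomoran_io_error")
                  })
  if (!is.list(cfg) || is.null(names(cfg))) {
    abort("configuration must be a JSON object of named values.",
          class = "ecomoran_io_error")
  }
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")),
         class = "ecomoran_unknown_keys")
    cfg <- cfg[setdiff(names(cfg), unknown)]
  }
  missing <- setdiff(config_required_keys, names(cfg))
  if (length(missing) > 0) {
    abort(sprintf("missing required configuration key(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ecomoran_io_error")
  }
  has_raw <- all(c("c1", "d1", "c2", "d2") %in% names(cfg))
  has_S <- all(c("S1", "S2") %in% names(cfg))
  if (!has_raw && !has_S) {
    abort("configuration needs either {c1,d1,c2,d2} or {S1,S2}.",
          class = "ecomoran_io_error")
  }
  cfg
}

#' Build model parameters from a configuration list
#'
#' Takes scalar values from a list such as [read_config()] returns; raw
#' payoffs take precedence over composite sums.
#'
#' @param config Named list with model keys.
#' @return A [model_params()] object.
#' @export
as_model_params <- function(config) {
  has_raw <- all(c("c1", "d1", "c2", "d2") %in% names(config))
  if (has_raw) {
    model_params(N = config$N, w = config$w, a = config$a, dt = config$dt,
                 c1 = config$c1, d1 = config$d1,
                 c2 = config$c2, d2 = config$d2)
  } else {
    model_params(N = config$N, w = config$w, a = config$a, dt = config$dt,
                 S1 = config$S1, S2 = config$S2)
  }
}

#' Write a configuration list to JSON
#'
#' Inverse of [read_config()]: `read_config(write_config(cfg, path))`
#' reproduces the configuration exactly.
#'
#' @param config Named list of configuration values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a record table as TSV
#'
#' Tab-separated output with a header row and floating-point values at
#' 17 significant digits, so a re-run with the same seed reproduces the
#' file byte for byte and values round-trip exactly.
#'
#' @param records A data frame (list columns are not serialisable and
#'   raise an error; `tidyr::unnest()` first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    abort("`records` must be a data frame.", class = "ecomoran_io_error")
  }
  if (any(vapply(records, is.list, logical(1)))) {
    abort("list columns cannot be written as TSV; `tidyr::unnest()` first.",
          class = "ecomoran_io_error")
  }
  out <- as.data.frame(lapply(records, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }), check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(records) == 0) out <- out[0, , drop = FALSE]
  status <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) conditionMessage(e),
     warning = function(w) conditionMessage(w))
  if (!isTRUE(status)) {
    abort(sprintf("could not write %s: %s", path, status),
          class = "ecomoran_io_error")
  }
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("table not found: %s", path), class = "ecomoran_io_error")
  }
  as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' Write a run manifest next to a result table
#'
#' Records provenance of one experiment run: the seed, replicate counts,
#' package and R versions. JSON, one file per run.
#'
#' @param path Manifest output path.
#' @param seed Root seed of the run.
#' @param extra Named list of additional fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, extra = list()) {
  manifest <- c(list(
    package = "ecomoran",
    package_version = as.character(utils::packageVersion("ecomoran")),
    r_version = as.character(getRversion()),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
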