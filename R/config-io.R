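#' Read and write simulation configs as flat key-value files
#'
#' Configs are stored as flat JSON (`.json`) or YAML (`.yml`/`.yaml`,
#' requires the yaml package) documents whose keys mirror the [sim_config()]
#' fields. Overrides supplied as `...` to `read_sim_config()` take
#' precedence over file values.
#'
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @param config a [sim_config()] to write.
#' @param ... field overrides applied after reading.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path, ...) {
  vals <- .read_kv(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- config[names(config) %in% names(formals(sim_config))]
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs", call. = FALSE)
    }
    writeLines(yaml::as.yaml(vals), path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

.read_kv <- function(path) {
  if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
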