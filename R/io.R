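# Configuration and result serialization.  Config files are flat JSON;
# result tables are CSV with a commented header recording version, seed and
# the full configuration, so every run is reproducible from its output file
# alone.

.config_defaults <- function() list(
  variant = "two_set", dynamics = "AM",
  n = 2000L, p_am = 10L, p_spr = 10L,
  nu = 0.5, temperature = 0, in_degree = 500L,
  flip_fraction = 0.1, transient = 35L,
  alpha = 0.05, branch = "retrieval",
  seed = 1L, out = NULL
)

#' Load a run configuration from a JSON file
#'
#' Reads a flat JSON object, validates it against the known keys, and fills
#' unspecified keys with their defaults.  Unknown keys are rejected by
#' name.
#'
#' @param path path to a JSON file.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$variant %in% c("one_set", "two_set"))
    stop("invalid value for key variant: ", cfg$variant)
  if (!cfg$dynamics %in% c("AM", "SPR"))
    stop("invalid value for key dynamics: ", cfg$dynamics)
  for (k in c("n", "p_am", "p_spr", "seed"))
    if (cfg[[k]] < 1) stop("invalid value for key ", k, ": must be >= 1")
  if (cfg$nu < 0 || cfg$nu > 1) stop("invalid value for key nu")
  if (cfg$temperature < 0) stop("invalid value for key temperature")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config` (or plain named list of known keys).
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a result table as CSV with a commented metadata header
#'
#' Header lines start with `#` and record the package version plus every
#' metadata entry (typically the command, seed and full configuration);
#' the column order of the table is preserved.
#'
#' @param table a `data.frame`.
#' @param path output path.
#' @param metadata named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("mixnet"))
  writeLines(sprintf("# mixnet %s", version), con)
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(metadata[[k]]), collapse = " ")), con)
  writeLines(paste(names(table), collapse = ","), con)
  if (nrow(table) > 0)
    utils::write.table(table, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()`: the `data.frame`, with the header lines in
#'   attribute `metadata`.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) > 1) {
    utils::read.csv(text = body, stringsAsFactors = FALSE)
  } else {
    cols <- strsplit(body[1], ",")[[1]]
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  attr(df, "metadata") <- meta
  df
}
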