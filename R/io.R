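## Configuration files, delimited-text readers/writers, run manifests.

.CONFIG_KEYS <- c("R", "P_m", "P_d", "K", "grid", "geometry", "boundary",
                  "n_steps", "mu_r", "mu_s", "strategy", "liquid_S_scope",
                  "event_mode", "init_liquid", "seed")

#' Load a simulation configuration from a structured text file
#'
#' Reads a YAML `key: value` file into a validated [sim_config()]. Omitted
#' keys take the model defaults (`P_d = 0.1`, `K = 5000`, 100 x 100 `hex6`
#' grid, `n_steps = 400000`, `P_m = 0.1`). Recognized keys: `R`, `P_m`,
#' `P_d`, `K`, `grid` (a two-element `[height, width]` list), `geometry`,
#' `boundary`, `n_steps`, `mu_r`, `mu_s`, `strategy`, `liquid_S_scope`,
#' `event_mode`, `init_liquid`, `seed`. Unknown keys and out-of-range
#' values raise a config error naming the key.
#'
#' @param path path to the config file.
#' @param overrides named list applied on top of the file (CLI overrides).
#' @return a [sim_config()].
#' @export
load_config <- function(path, overrides = list()) {
  vals <- if (file.exists(path)) yaml::read_yaml(path) else
    stop(sprintf("config file not found: %s", path))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain key: value pairs")
  vals <- modifyList(vals, overrides)
  unknown <- setdiff(names(vals), .CONFIG_KEYS)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  lat_args <- list()
  if (!is.null(vals$grid)) {
    if (length(vals$grid) != 2L)
      stop("config key 'grid' must be [height, width]")
    lat_args$height <- vals$grid[[1L]]
    lat_args$width <- vals$grid[[2L]]
  }
  if (!is.null(vals$geometry)) lat_args$neighbourhood <- vals$geometry
  if (!is.null(vals$boundary)) lat_args$boundary <- vals$boundary
  lattice <- tryCatch(do.call(lattice_spec, lat_args), error = function(e)
    stop(sprintf("config keys 'grid'/'geometry'/'boundary': %s",
                 conditionMessage(e)), call. = FALSE))
  args <- vals[setdiff(names(vals),
                       c("grid", "geometry", "boundary"))]
  args$lattice <- lattice
  tryCatch(do.call(sim_config, args), error = function(e)
    stop(sprintf("config error: %s", conditionMessage(e)), call. = FALSE))
}

#' Canonical text form of a configuration
#'
#' One `key=value` token per field in fixed order; used in run manifests so
#' a manifest pins the exact parameter set.
#'
#' @param cfg a [sim_config()].
#' @return a single string.
#' @export
config_string <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  paste(
    sprintf("R=%g", cfg$R), sprintf("P_m=%g", cfg$P_m),
    sprintf("P_d=%g", cfg$P_d), sprintf("K=%d", cfg$K),
    sprintf("grid=%dx%d", cfg$lattice$height, cfg$lattice$width),
    sprintf("geometry=%s", cfg$lattice$neighbourhood),
    sprintf("boundary=%s", cfg$lattice$boundary),
    sprintf("n_steps=%d", cfg$n_steps),
    sprintf("mu_r=%g", cfg$mu_r), sprintf("mu_s=%g", cfg$mu_s),
    sprintf("strategy=%s", cfg$strategy),
    sprintf("liquid_S_scope=%s", cfg$liquid_S_scope),
    sprintf("event_mode=%s", cfg$event_mode),
    sprintf("init_liquid=%d", cfg$init_liquid),
    sprintf("seed=%d", cfg$seed),
    sep = " ")
}

#' Delimited-text writers and readers
#'
#' Comma-separated tables with a header row. `write_trajectory()` /
#' `read_trajectory()` handle snapshot time series (`append = TRUE` resumes
#' an existing file); `write_grid()` / `read_grid()` handle surface
#' snapshots, sorted by `(row, col)` for diffability; `write_genotypes()` /
#' `read_genotypes()` handle genotype tables. All pairs round-trip:
#' `read(write(x))` equals `x`.
#'
#' @param x the data frame to write.
#' @param path file path.
#' @param append append rows without a header (trajectories only).
#' @return the data frame, invisibly for writers.
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_trajectory <- function(x, path, append = FALSE) {
  write.table(x, path, sep = ",", row.names = FALSE,
              col.names = !append, append = append, qmethod = "double")
  invisible(x)
}

#' @rdname sim_io
#' @export
read_trajectory <- function(path) {
  .read_checked(path)
}

#' @rdname sim_io
#' @export
write_grid <- function(x, path) {
  x <- x[order(x$row, x$col), , drop = FALSE]
  rownames(x) <- NULL
  write.csv(x, path, row.names = FALSE)
  invisible(x)
}

#' @rdname sim_io
#' @export
read_grid <- function(path) {
  .read_checked(path)
}

#' @rdname sim_io
#' @export
write_genotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(x)
}

#' @rdname sim_io
#' @export
read_genotypes <- function(path) {
  .read_checked(path)
}

# read.csv with a parse error that names the offending line
.read_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) stop(sprintf("empty file: %s", path))
  nfield <- length(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  bad <- which(vapply(strsplit(lines, ",", fixed = TRUE), length, 0L)
               != nfield)
  if (length(bad) > 0)
    stop(sprintf("malformed file %s at line %d: expected %d fields",
                 path, bad[1L], nfield))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Plain-text record of a run: canonical config string, seed, package
#' version, start/end step and the output file inventory. Re-running the
#' same config and seed reproduces the listed outputs byte for byte.
#'
#' @param path manifest file path.
#' @param cfg the [sim_config()] of the run.
#' @param t_start,t_end first and last time step covered.
#' @param files character vector of output files produced.
#' @export
write_manifest <- function(path, cfg, t_start, t_end, files = character()) {
  lines <- c(
    sprintf("config: %s", config_string(cfg)),
    sprintf("seed: %d", cfg$seed),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("stickysim"))),
    sprintf("t_start: %d", as.integer(t_start)),
    sprintf("t_end: %d", as.integer(t_end)),
    sprintf("files: %s", paste(files, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
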