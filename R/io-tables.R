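#' Write/read tab-separated tables
#'
#' Plain TSV with a header row; the interchange format for lobule
#' tables, electrode catalogs and montage solutions.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `path` (write) or a data frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a lead field as a single hierarchical container
#'
#' JSON container with datasets `LF_X`, `LF_Y`, `LF_Z`, the region
#' names, the electrode table and provenance hashes, so optimization
#' can be re-run without repeating the assembly. Numeric precision is
#' preserved in full.
#'
#' @param lf A `lead_field`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(lf, path) {
  payload <- list(
    format = "fieldsteer-leadfield",
    format_version = 1L,
    regions = lf$regions,
    electrode_ids = colnames(lf$LF$X),
    reference_id = lf$reference_id,
    LF_X = lf$LF$X, LF_Y = lf$LF$Y, LF_Z = lf$LF$Z,
    electrodes = lf$electrodes,
    provenance = lf$provenance)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a lead field container
#'
#' @param path Input `.json` written by [write_leadfield()].
#' @return A `lead_field`.
#' @export
read_leadfield <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "fieldsteer-leadfield")) {
    stop(path, " is not a lead-field container")
  }
  dn <- list(p$regions, p$electrode_ids)
  LF <- list(X = matrix(p$LF_X, length(p$regions), dimnames = dn),
             Y = matrix(p$LF_Y, length(p$regions), dimnames = dn),
             Z = matrix(p$LF_Z, length(p$regions), dimnames = dn))
  structure(list(LF = LF, regions = p$regions,
                 electrodes = as.data.frame(p$electrodes),
                 reference_id = p$reference_id,
                 provenance = p$provenance),
            class = "lead_field")
}

#' Per-direction TSV export of a lead field
#' @param lf A `lead_field`.
#' @param direction `"X"`, `"Y"` or `"Z"`.
#' @param path Output path.
#' @export
write_leadfield_tsv <- function(lf, direction, path) {
  direction <- match.arg(direction, c("X", "Y", "Z"))
  df <- data.frame(region = lf$regions, lf$LF[[direction]],
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Write a montage solution as TSV plus a JSON run report
#'
#' @param ms A `montage_solution`.
#' @param path TSV path for the currents (`electrode`, `current_mA`);
#'   the JSON report (residual, constraints, configuration echo) goes
#'   next to it with extension `.report.json`.
#' @param config Optional configuration list to echo into the report.
#' @return `path`, invisibly.
#' @export
write_montage_solution <- function(ms, path, config = NULL) {
  write_tsv(data.frame(electrode = names(ms$x), current_mA = ms$x), path)
  report <- list(direction = ms$direction, residual = ms$residual,
                 constraints = ms$constraints, active = ms$active,
                 config = config,
                 package_version = as.character(utils::packageVersion("fieldsteer")))
  jsonlite::write_json(report, sub("\\.tsv$", ".report.json", path),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------

config_schema <- function() {
  list(
    phantom = c("resolution", "shells"),
    grid = c("spacing"),
    catalog = c("n", "scheme", "cap_deg", "diameter_cm", "reference_id"),
    montage = c("preset"),
    target = c("regions", "direction", "magnitude", "spillover_weight",
               "total_cap_mA", "per_electrode_cap_mA"),
    solver = c("method", "tol", "maxit"),
    seed = NULL)
}

#' Default run configuration
#'
#' The resolved configuration of a pipeline run: phantom geometry,
#' extraction grid, electrode catalog, montage preset, optimization
#' target and solver settings. Round-trips losslessly through YAML.
#'
#' @return Nested list with a `format_version` tag.
#' @export
default_run_config <- function() {
  list(
    format_version = 1L,
    phantom = list(resolution = 8),
    grid = list(spacing = 1),
    catalog = list(n = 24, scheme = "quasi-uniform", cap_deg = 150,
                   diameter_cm = 1, reference_id = "Cz"),
    montage = list(preset = "celnik"),
    target = list(regions = c("Right_VIIb", "Right_VIIIa",
                              "Right_VIIIb", "Right_IX"),
                  direction = "Z", magnitude = 0.3,
                  spillover_weight = 1, total_cap_mA = 4),
    solver = list(method = "cholesky", tol = 1e-8, maxit = 10000),
    seed = 1L)
}

#' Read and validate a run configuration
#'
#' YAML key-value file checked against the configuration schema:
#' unknown sections or keys are errors (silent typos in tolerance
#' names are the classic failure mode), missing keys fall back to
#' [default_run_config()].
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  known_top <- c(names(schema), "format_version")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown) > 0L) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in intersect(names(cfg), names(schema))) {
    if (is.null(schema[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad) > 0L) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  out <- utils::modifyList(default_run_config(), cfg)
  out
}

#' Write a run configuration as YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
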