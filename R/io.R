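# File I/O: the CSV voltammogram dialect (comment-prefixed metadata header)
# and key-value (YAML) analysis / drug-definition configs.

#' Read a voltammogram from CSV
#'
#' The single voltammogram dialect: optional `# key: value` metadata lines,
#' then a header naming the two numeric columns with their units embedded
#' (`potential_mV` or `potential_V`; `current_uA`, `current_nA` or
#' `current_A`), then the data.  Values are converted to the internal volts /
#' amperes contract.  Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return A [voltammogram()]; header metadata lands in `$metadata`, and a
#'   `scan_rate` (or `scan_rate_mV_s`) metadata key populates the scan rate.
#' @export
read_voltammogram <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines)
  metadata <- list()
  for (i in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", lines[i])
    m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
    if (length(m) == 3) {
      val <- type.convert(trimws(m[3]), as.is = TRUE)
      metadata[[trimws(m[2])]] <- val
    }
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) abort_format("no data rows found")
  header <- strsplit(body[1], ",")[[1]]
  header <- trimws(header)
  p_col <- grep("^potential(_(mV|V))?$", header)
  c_col <- grep("^current(_(uA|nA|A))?$", header)
  if (length(p_col) != 1L || length(c_col) != 1L)
    abort_format("header must name a potential_{mV|V} and a current_{uA|nA|A} column")
  p_unit <- sub("^potential_?", "", header[p_col])
  c_unit <- sub("^current_?", "", header[c_col])
  if (p_unit == "") abort_format("potential column must declare its unit (potential_mV or potential_V)")
  if (c_unit == "") abort_format("current column must declare its unit (current_uA, current_nA or current_A)")

  rows <- strsplit(body[-1], ",")
  nums <- lapply(rows, function(r) suppressWarnings(as.numeric(trimws(r))))
  bad <- which(vapply(nums, function(x) length(x) < max(p_col, c_col) || anyNA(x[c(p_col, c_col)]),
                      logical(1)))
  if (length(bad)) {
    line_no <- seq_along(body)[-1][bad]
    # map back to raw file line numbers
    raw_lines <- setdiff(seq_along(lines), meta_lines)
    raw_lines <- raw_lines[nzchar(trimws(lines[raw_lines]))]
    abort_format(sprintf("malformed (non-numeric) data row(s) at line(s): %s",
                         paste(raw_lines[line_no], collapse = ", ")))
  }
  pot <- vapply(nums, `[[`, numeric(1), p_col)
  cur <- vapply(nums, `[[`, numeric(1), c_col)
  pot <- switch(p_unit, mV = mV_to_V(pot), V = pot)
  cur <- switch(c_unit, uA = uA_to_A(cur), nA = nA_to_A(cur), A = cur)
  scan_rate <- NA_real_
  if (!is.null(metadata$scan_rate)) scan_rate <- as.numeric(metadata$scan_rate)
  if (!is.null(metadata$scan_rate_mV_s)) scan_rate <- mV_to_V(as.numeric(metadata$scan_rate_mV_s))
  voltammogram(pot, cur, scan_rate = scan_rate, metadata = metadata)
}

#' Write a voltammogram to CSV
#'
#' Inverse of [read_voltammogram()]: metadata as `# key: value` comments,
#' then a two-column table in the requested units.
#'
#' @param v A [voltammogram()].
#' @param path Output path.
#' @param potential_unit `"mV"` or `"V"`.
#' @param current_unit `"uA"`, `"nA"` or `"A"`.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(v, path, potential_unit = c("mV", "V"),
                               current_unit = c("uA", "nA", "A")) {
  stopifnot(inherits(v, "voltammogram"))
  potential_unit <- match.arg(potential_unit)
  current_unit <- match.arg(current_unit)
  meta <- v$metadata
  if (is.finite(v$scan_rate) && is.null(meta$scan_rate)) meta$scan_rate <- v$scan_rate
  hdr <- character(0)
  for (k in names(meta)) {
    val <- meta[[k]]
    if (is.null(val) || length(val) == 0) next
    hdr <- c(hdr, sprintf("# %s: %s", k, paste(format(val), collapse = " ")))
  }
  pot <- switch(potential_unit, mV = V_to_mV(v$potential), V = v$potential)
  cur <- switch(current_unit, uA = v$current / 1e-6, nA = v$current / 1e-9, A = v$current)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("potential_%s,current_%s", potential_unit, current_unit), con)
  writeLines(sprintf("%.10g,%.10g", pot, cur), con)
  invisible(path)
}

#' Load drug definitions from a key-value (YAML) config file
#'
#' The file maps drug names to definitions with fields `pka` (list),
#' optionally `charges`, `labels`, `molar_mass` and
#' `most_protonated_charge`.
#'
#' @param path YAML file path.
#' @return Named list of [protolytic_system()] objects.
#' @export
read_drug_definitions <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || !length(raw))
    abort_config("drug definition file must map drug names to definitions")
  out <- lapply(names(raw), function(nm) protolytic_system_from_list(nm, raw[[nm]]))
  names(out) <- names(raw)
  out
}

#' Read and validate an analysis configuration
#'
#' A YAML file with top-level sections `drugs` (as in
#' [read_drug_definitions()]), `conditions` (`temperature` in K), `geometry`
#' (`kind`, `radius_cm`) and `output_dir`, plus optional per-stage parameter
#' blocks consumed by [run_pipeline()].  Missing required fields are all
#' reported in one validation error.
#'
#' @param path YAML file path.
#' @return A validated list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) cfg <- list()
  missing <- character(0)
  if (is.null(cfg$drugs) || !length(cfg$drugs)) missing <- c(missing, "drugs")
  if (is.null(cfg$conditions$temperature)) missing <- c(missing, "conditions.temperature")
  if (is.null(cfg$geometry$kind)) missing <- c(missing, "geometry.kind")
  if (is.null(cfg$geometry$radius_cm)) missing <- c(missing, "geometry.radius_cm")
  if (is.null(cfg$output_dir)) missing <- c(missing, "output_dir")
  if (length(missing))
    abort_config(sprintf("analysis config is missing required field(s): %s",
                         paste(missing, collapse = ", ")))
  cfg$systems <- lapply(names(cfg$drugs),
                        function(nm) protolytic_system_from_list(nm, cfg$drugs[[nm]]))
  names(cfg$systems) <- names(cfg$drugs)
  cfg$conditions_obj <- ities_conditions(cfg$conditions$temperature)
  cfg$geometry_obj <- cell_geometry(cfg$geometry$kind, cfg$geometry$radius_cm)
  cfg$source_path <- path
  class(cfg) <- "analysis_config"
  cfg
}
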