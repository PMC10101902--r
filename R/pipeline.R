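# Pipeline driver tying the analysis stages together behind one entry
# point.  Each stage reads its inputs (files or config parameters), runs the
# corresponding package functions, and writes plain-text results with
# provenance (package version, config hash, seed) into the configured
# output directory.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain$systems <- plain$conditions_obj <- plain$geometry_obj <- NULL
  writeLines(yaml::as.yaml(plain), tmp)
  unname(tools::md5sum(tmp))
}

write_result_file <- function(values, path, provenance) {
  lines <- c(sprintf("# %s: %s", names(provenance), unlist(provenance)),
             sprintf("%s: %s", names(values),
                     vapply(values, function(v) paste(format(v, digits = 10), collapse = " "), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Run one stage of the ITIES analysis pipeline
#'
#' Dispatches a subcommand over a validated [read_analysis_config()] object:
#' \describe{
#'   \item{speciation}{fraction table + dominance ranges per configured drug}
#'   \item{partition-fit}{fit Eq-style boundary lines to a (ph, potential_mV)
#'     CSV and report KD, formal potential and logP}
#'   \item{calibrate}{calibration line, LOD/LOQ and (area-normalized)
#'     sensitivity from a (concentration, signal) CSV}
#'   \item{standard-addition}{x-intercept concentration and pill content from
#'     an (added_concentration, signal) CSV}
#'   \item{transport}{diffusion coefficient from a
#'     (scan_rate_mV_s, peak_current_uA) CSV}
#'   \item{peaks}{peak pair of a voltammogram CSV}
#'   \item{detect}{binary presence call of a sample vs a blank voltammogram}
#'   \item{simulate}{synthetic macroscopic voltammogram written to CSV}
#' }
#'
#' @param config An `analysis_config` from [read_analysis_config()].
#' @param subcommand One of the stages above.
#' @param input Path to the stage's input CSV (stages that need one).
#' @param input2 Second input path (blank voltammogram for `detect`).
#' @param seed Integer seed forwarded to stochastic stages.
#' @param ... Stage-specific overrides (e.g. `drug`, `pka`, `search_window`).
#' @return The stage result object, invisibly; results are also written to
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config,
                         subcommand = c("speciation", "partition-fit",
                                        "calibrate", "standard-addition",
                                        "transport", "peaks", "detect",
                                        "simulate"),
                         input = NULL, input2 = NULL, seed = NULL, ...) {
  if (!inherits(config, "analysis_config"))
    abort_config("`config` must come from read_analysis_config()")
  subcommand <- match.arg(subcommand)
  dots <- list(...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "itieskit",
               version = as.character(utils::packageVersion("itieskit")),
               config_hash = config_hash(config),
               seed = if (is.null(seed)) "NULL" else seed,
               subcommand = subcommand)
  cond <- config$conditions_obj
  geom <- config$geometry_obj
  out_path <- function(name) file.path(config$output_dir, name)

  read_xy_csv <- function(path, cols) {
    if (is.null(path) || !file.exists(path))
      abort_format(sprintf("stage '%s' needs an existing input CSV", subcommand))
    df <- utils::read.csv(path, comment.char = "#")
    miss <- setdiff(cols, names(df))
    if (length(miss))
      abort_format(sprintf("input CSV is missing column(s): %s", paste(miss, collapse = ", ")))
    df
  }

  result <- switch(
    subcommand,
    "speciation" = {
      ph <- if (!is.null(dots$ph_grid)) dots$ph_grid else seq(0, 14, by = 0.1)
      res <- lapply(names(config$systems), function(nm) {
        sys <- config$systems[[nm]]
        fr <- species_fractions(sys, ph)
        df <- data.frame(ph = ph, fr, check.names = FALSE)
        utils::write.csv(df, out_path(sprintf("speciation_%s.csv", nm)), row.names = FALSE)
        dominance_ranges(sys)
      })
      names(res) <- names(config$systems)
      write_result_file(list(drugs = paste(names(res), collapse = " ")),
                        out_path("speciation_summary.txt"), prov)
      res
    },
    "partition-fit" = {
      df <- read_xy_csv(input, c("ph", "potential_mV"))
      pka <- dots$pka %||% config$partition$pka
      if (is.null(pka)) abort_config("partition-fit needs `pka` (argument or config$partition$pka)")
      model <- fit_partition_model(df$ph, mV_to_V(df$potential_mV), pka = pka,
                                   z = dots$z %||% 1L, conditions = cond)
      write_result_file(list(
        kd = model$kd, log10_kd = model$fit$log10_kd,
        se_log10_kd = model$fit$se_log10_kd,
        formal_potential_mV = V_to_mV(model$formal_potential),
        se_formal_potential_mV = V_to_mV(model$fit$se_formal_potential),
        logp = logp_from_potential(model$formal_potential, model$z, cond),
        residual_norm_V = model$fit$residual_norm, n = model$fit$n,
        temperature_K = cond$temperature
      ), out_path("partition_fit.txt"), prov)
      model
    },
    "calibrate" = {
      df <- read_xy_csv(input, c("concentration", "signal"))
      cal <- fit_calibration(df$concentration, df$signal, area = geom$area)
      write_result_file(list(
        slope = cal$slope, intercept = cal$intercept,
        sigma_intercept = cal$sigma_intercept, r_squared = cal$r_squared,
        lod = cal$lod, loq = cal$loq,
        normalized_sensitivity = cal$normalized_sensitivity,
        area_cm2 = geom$area
      ), out_path("calibration.txt"), prov)
      cal
    },
    "standard-addition" = {
      df <- read_xy_csv(input, c("added_concentration", "signal"))
      sa <- standard_addition(
        df$added_concentration, df$signal,
        dilution_factor = dots$dilution_factor %||% config$standard_addition$dilution_factor,
        stock_volume = dots$stock_volume %||% config$standard_addition$stock_volume_L,
        molar_mass = dots$molar_mass %||% config$standard_addition$molar_mass,
        volume_correction = isTRUE(dots$volume_correction %||%
                                     config$standard_addition$volume_correction),
        standard_concentration = dots$standard_concentration %||%
          config$standard_addition$standard_concentration
      )
      write_result_file(list(
        slope = sa$slope, intercept = sa$intercept,
        x_intercept_concentration = sa$x_intercept_concentration,
        content_mass_mg = 1e3 * sa$content_mass, r_squared = sa$r_squared
      ), out_path("standard_addition.txt"), prov)
      sa
    },
    "transport" = {
      df <- read_xy_csv(input, c("scan_rate_mV_s", "peak_current_uA"))
      conc <- dots$concentration_mol_cm3 %||% config$transport$concentration_mol_cm3
      if (is.null(conc)) abort_config("transport needs `concentration_mol_cm3`")
      est <- diffusion_from_scan_rate_series(
        mV_to_V(df$scan_rate_mV_s), uA_to_A(df$peak_current_uA),
        z = dots$z %||% 1L, area = geom$area, concentration = conc,
        conditions = cond)
      write_result_file(list(
        diffusion_cm2_s = est$diffusion, slope_A_per_sqrtVs = est$slope,
        intercept_A = est$intercept, r_squared = est$r_squared
      ), out_path("transport.txt"), prov)
      est
    },
    "peaks" = {
      v <- read_voltammogram(input)
      win <- dots$search_window %||% mV_to_V(unlist(config$peaks$search_window_mV))
      if (is.null(win)) abort_config("peaks needs `search_window` (V) or config$peaks$search_window_mV")
      pk <- extract_peaks(v, win)
      write_result_file(list(
        forward_peak_potential_mV = V_to_mV(pk$forward_peak_potential),
        forward_peak_current_A = pk$forward_peak_current,
        backward_peak_potential_mV = V_to_mV(pk$backward_peak_potential),
        backward_peak_current_A = pk$backward_peak_current,
        midpoint_potential_mV = V_to_mV(pk$midpoint_potential),
        baseline = pk$baseline_method
      ), out_path("peaks.txt"), prov)
      pk
    },
    "detect" = {
      v <- read_voltammogram(input)
      if (is.null(input2)) abort_format("detect needs a blank voltammogram via `input2`")
      blank <- read_voltammogram(input2)
      expected <- dots$expected_potential %||% mV_to_V(config$detect$expected_potential_mV)
      tol <- dots$tolerance %||% mV_to_V(config$detect$tolerance_mV %||% 50)
      call <- detect_analyte(v, blank, expected, tol)
      write_result_file(list(signal_present = call,
                             expected_potential_mV = V_to_mV(expected),
                             tolerance_mV = V_to_mV(tol)),
                        out_path("detect.txt"), prov)
      call
    },
    "simulate" = {
      sim <- config$simulate %||% list()
      sp <- transfer_species(
        sim$label %||% "analyte", sim$z %||% 1L,
        mV_to_V(sim$formal_potential_mV %||% 242),
        sim$diffusion_cm2_s %||% 12e-6,
        concentration = uM_to_M(sim$concentration_uM %||% 20))
      cfg <- sim_config(
        mV_to_V(sim$start_mV %||% 0), mV_to_V(sim$vertex_mV %||% 500),
        scan_rate = mV_to_V(sim$scan_rate_mV_s %||% 20),
        geometry = geom, noise_sd = uA_to_A(sim$noise_sd_uA %||% 0.05),
        seed = seed)
      v <- simulate_macro_itv(sp, cfg, cond)
      write_voltammogram(v, out_path("simulated_itv.csv"))
      v
    }
  )
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
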