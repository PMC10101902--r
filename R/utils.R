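# Internal helpers: structured conditions, seeded RNG scope, unit conversions.

ities_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "itieskit_error", "error"), call = call))
}

abort_invalid  <- function(msg) ities_error(msg, "itieskit_invalid_input")
abort_lookup   <- function(msg) ities_error(msg, "itieskit_lookup_error")
abort_dof      <- function(msg) ities_error(msg, "itieskit_dof_error")
abort_fit      <- function(msg) ities_error(msg, "itieskit_fit_error")
abort_config   <- function(msg) ities_error(msg, "itieskit_config_error")
abort_format   <- function(msg) ities_error(msg, "itieskit_format_error")
abort_physical <- function(msg) ities_error(msg, "itieskit_physical_error")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number stream seeded to `seed`, then
#' restores the previous stream so callers' randomness is unaffected.  With
#' `seed = NULL` the code runs against the ambient stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) abort_invalid(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort_invalid(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# Unit conversions.  Internal contract: potentials in V, currents in A,
# lengths in cm, diffusion in cm^2 s^-1, interfacial concentrations in
# mol cm^-3; user-facing concentrations in mol L^-1 (M) unless stated.

#' Unit conversion helpers
#'
#' Small conversions between the user-facing units (mV, uA, nA, uM) and the
#' internal SI/CGS contract (V, A, mol cm^-3).
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
mV_to_V <- function(x) x / 1e3

#' @rdname units
#' @export
V_to_mV <- function(x) x * 1e3

#' @rdname units
#' @export
uA_to_A <- function(x) x * 1e-6

#' @rdname units
#' @export
nA_to_A <- function(x) x * 1e-9

#' @rdname units
#' @export
uM_to_M <- function(x) x * 1e-6

#' @rdname units
#' @export
M_to_mol_cm3 <- function(x) x * 1e-3

# summary.lm warns on zero-residual fits; noiseless synthetic data is a
# legitimate input here, so that specific warning is muffled.
quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
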