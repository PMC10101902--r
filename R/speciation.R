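#' Define a multi-pKa acid-base (protolytic) system
#'
#' A protolytic system is the ordered ladder of acid dissociation steps of an
#' ionizable drug: `length(pka) + 1` species ranging from the most protonated
#' to the least, each deprotonation lowering the charge by one.  Nitrazepam
#' (pKa 3.2, 10.8) has three species (monocation, neutral, monoanion);
#' 7-aminonitrazepam (pKa 2.5, 4.6, 13.1) has four (dication through
#' monoanion).
#'
#' @param name Drug name.
#' @param pka Numeric vector of acid dissociation exponents, strictly
#'   ascending.
#' @param charges Integer charges of the species, length `length(pka) + 1`,
#'   ordered from most protonated to least; adjacent entries must differ by
#'   exactly -1.  Defaults to a ladder ending wherever `most_protonated_charge`
#'   starts.
#' @param labels Species labels; defaults are built from the charges.
#' @param molar_mass Optional molar mass in g/mol (used for content
#'   back-calculation).
#' @param most_protonated_charge Charge of the first species when `charges`
#'   is not supplied.
#' @return An object of class `protolytic_system`.
#' @examples
#' nit <- protolytic_system("nitrazepam", c(3.2, 10.8), charges = c(1, 0, -1))
#' species_fractions(nit, ph = 2)
#' @export
protolytic_system <- function(name, pka, charges = NULL, labels = NULL,
                              molar_mass = NULL, most_protonated_charge = 1L) {
  if (!is.character(name) || length(name) != 1L)
    abort_invalid("`name` must be a single string")
  if (!is.numeric(pka) || length(pka) < 1L || anyNA(pka) || any(!is.finite(pka)))
    abort_invalid("`pka` must be a finite numeric vector")
  if (is.unsorted(pka, strictly = TRUE))
    abort_invalid("`pka` values must be strictly ascending")
  n_sp <- length(pka) + 1L
  if (is.null(charges)) charges <- seq(most_protonated_charge, by = -1L, length.out = n_sp)
  charges <- as.integer(charges)
  if (length(charges) != n_sp)
    abort_invalid("`charges` must have length `length(pka) + 1`")
  if (any(diff(charges) != -1L))
    abort_invalid("adjacent species charges must differ by exactly -1 (one proton per step)")
  if (is.null(labels)) {
    labels <- paste0(name, ifelse(charges > 0, paste0("+", ifelse(charges > 1, charges, "")),
                                  ifelse(charges < 0, paste0("-", ifelse(charges < -1, -charges, "")), "0")))
  }
  if (length(labels) != n_sp || anyDuplicated(labels))
    abort_invalid("`labels` must be unique and have length `length(pka) + 1`")
  if (!is.null(molar_mass)) check_scalar(molar_mass, "molar_mass", positive = TRUE)
  structure(
    list(name = name, pka = as.numeric(pka), charges = charges,
         labels = labels, molar_mass = molar_mass),
    class = "protolytic_system"
  )
}

#' @export
print.protolytic_system <- function(x, ...) {
  cat(sprintf("Protolytic system '%s': %d species, pKa = %s\n",
              x$name, length(x$labels), paste(format(x$pka), collapse = ", ")))
  cat("  species:", paste(sprintf("%s (z=%+d)", x$labels, x$charges), collapse = ", "), "\n")
  invisible(x)
}

#' Equilibrium concentration fractions of all species at a given pH
#'
#' The fraction of species `i` (0-indexed from the most protonated form) is
#' `10^L_i / sum_j 10^L_j` with the cumulative exponent
#' `L_i = sum_{k <= i} (pH - pKa_k)`, `L_0 = 0`.  Exponents are shifted by
#' their maximum before exponentiation so fractions stay finite at any pH.
#'
#' @param system A [protolytic_system()].
#' @param ph pH value(s); any finite numeric vector.
#' @return For scalar `ph`, a named numeric vector of fractions summing to 1;
#'   for vector `ph`, a matrix with one row per pH and one column per species.
#' @examples
#' anit <- protolytic_system("7a-NIT", c(2.5, 4.6, 13.1), charges = c(2, 1, 0, -1))
#' species_fractions(anit, 2.0)  # dication fraction ~0.759
#' @export
species_fractions <- function(system, ph) {
  stopifnot(inherits(system, "protolytic_system"))
  if (!is.numeric(ph) || length(ph) < 1L || anyNA(ph) || any(!is.finite(ph)))
    abort_invalid("`ph` must be finite numeric")
  one <- function(p) {
    L <- c(0, cumsum(p - system$pka))   # log10 of relative species abundances
    x <- 10^(L - max(L))
    x / sum(x)
  }
  if (length(ph) == 1L) {
    out <- one(ph)
    names(out) <- system$labels
    return(out)
  }
  out <- t(vapply(ph, one, numeric(length(system$labels))))
  dimnames(out) <- list(NULL, system$labels)
  out
}

#' Fraction of a single named species at a given pH
#'
#' @inheritParams species_fractions
#' @param species_label One of `system$labels`.
#' @return Numeric fraction(s) in \[0, 1\].
#' @export
fraction_of <- function(system, species_label, ph) {
  stopifnot(inherits(system, "protolytic_system"))
  idx <- match(species_label, system$labels)
  if (is.na(idx))
    abort_lookup(sprintf("unknown species label '%s'; available: %s",
                         species_label, paste(system$labels, collapse = ", ")))
  fr <- species_fractions(system, ph)
  if (is.matrix(fr)) fr[, idx] else unname(fr[idx])
}

#' pH ranges over which each species dominates
#'
#' Each species is the most abundant form between consecutive pKa values, so
#' the dominance ranges partition the whole pH axis at the pKa boundaries.
#'
#' @inheritParams species_fractions
#' @return A data frame with columns `species`, `ph_low`, `ph_high`.
#' @examples
#' nit <- protolytic_system("NIT", c(3.2, 10.8), charges = c(1, 0, -1))
#' dominance_ranges(nit)
#' @export
dominance_ranges <- function(system) {
  stopifnot(inherits(system, "protolytic_system"))
  bounds <- c(-Inf, system$pka, Inf)
  data.frame(
    species = system$labels,
    ph_low  = bounds[-length(bounds)],
    ph_high = bounds[-1],
    stringsAsFactors = FALSE
  )
}

#' Build a protolytic system from a parsed drug-definition list
#'
#' Used by [read_drug_definitions()] to turn one entry of a key-value config
#' file (fields `pka`, `charges`, optionally `labels` and `molar_mass`) into a
#' [protolytic_system()].
#'
#' @param name Drug name.
#' @param def Named list with at least `pka`.
#' @return A `protolytic_system`.
#' @keywords internal
protolytic_system_from_list <- function(name, def) {
  if (is.null(def$pka)) abort_config(sprintf("drug '%s': missing `pka`", name))
  protolytic_system(
    name, as.numeric(unlist(def$pka)),
    charges = if (!is.null(def$charges)) as.integer(unlist(def$charges)),
    labels = if (!is.null(def$labels)) as.character(unlist(def$labels)),
    molar_mass = def$molar_mass,
    most_protonated_charge = if (!is.null(def$most_protonated_charge))
      as.integer(def$most_protonated_charge) else 1L
  )
}
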