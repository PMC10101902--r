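# Shared fixtures: the two benzodiazepine protolytic systems and the
# standard laboratory conditions.

cond20 <- function() ities_conditions(293.15)

nit_system <- function() {
  protolytic_system("NIT", pka = c(3.2, 10.8), charges = c(1, 0, -1),
                    labels = c("NIT+", "NIT0", "NIT-"), molar_mass = 281.27)
}

anit_system <- function() {
  protolytic_system("7a-NIT", pka = c(2.5, 4.6, 13.1), charges = c(2, 1, 0, -1),
                    labels = c("7a-NIT2+", "7a-NIT+", "7a-NIT0", "7a-NIT-"))
}

macro_geometry <- function() cell_geometry("macro", 0.65)
micro_geometry <- function() cell_geometry("micro", 12e-4)

# Standard macroscopic calibration concentration series, uM
macro_concentrations <- function() c(10, 12.5, 15, 17.5, 20, 22.5, 25, 30)
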