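# Unit system: Angstrom, picosecond, kcal/mol, Kelvin, amu.

#' Physical constants used throughout the package
#'
#' Boltzmann constant in kcal/mol/K and the conversion factor from
#' kcal/mol to amu*A^2/ps^2 (so that acceleration = force * KCAL_PER_MOL_TO_INTERNAL / mass).
#'
#' @format Named numeric vector.
#' @keywords internal
#' @export
egress_constants <- c(
  kB = 0.0019872041,              # kcal/mol/K
  kcal_to_internal = 418.4        # 1 kcal/mol = 418.4 amu A^2/ps^2
)

.kB <- 0.0019872041
.F2A <- 418.4  # multiply force (kcal/mol/A) by this / mass (amu) to get A/ps^2

`%||%` <- function(a, b) if (is.null(a)) b else a
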