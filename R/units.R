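## Internal unit system: micrometres, femtograms, seconds.
##
## Chosen so that micron-sized agents, femtogram masses and second-scale
## mechanics stay near unity in double precision. Handy coincidences:
##   1 kg m^-3  == 1 fg um^-3   (concentrations and densities pass through)
##   1 m^2 s^-1 == 1e12 um^2 s^-1
##   1 N m^-1   == 1e18 fg s^-2
##   1 Pa s     == 1e12 fg um^-1 s^-1
##   1 N        == 1e24 fg um s^-2
## Rates given per hour are converted to per second on use.

.UM2_PER_M2 <- 1e12
.FGS2_PER_NM <- 1e18     # spring constant N/m -> fg/s^2
.FGUMS_PER_PAS <- 1e12   # viscosity Pa s -> fg/(um s)
.SEC_PER_HOUR <- 3600

#' Convert a first-order rate from per-hour to per-second
#' @param r rate in h^-1
#' @return rate in s^-1
#' @keywords internal
perHourToPerSec <- function(r) r / .SEC_PER_HOUR

#' Stokes drag coefficient of a sphere in internal units
#'
#' \eqn{\zeta = 6 \pi \mu r}, such that the drag force is
#' \eqn{\zeta (U - v)} in fg um s^-2.
#'
#' @param radius sphere radius (um)
#' @param muFluid dynamic viscosity (Pa s)
#' @return drag coefficient in fg s^-1
#' @keywords internal
stokesZeta <- function(radius, muFluid) {
  6 * pi * (muFluid * .FGUMS_PER_PAS) * radius
}
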