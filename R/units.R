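# Unit conventions: geometry in mm, physics internally in SI,
# reported velocities in cm/s and pressures in mmHg.

PA_PER_MMHG <- 133.322
M3S_PER_MLMIN <- 1e-6 / 60

mmhg_to_pa <- function(p) p * PA_PER_MMHG
pa_to_mmhg <- function(p) p / PA_PER_MMHG
mlmin_to_m3s <- function(q) q * M3S_PER_MLMIN
m3s_to_mlmin <- function(q) q / M3S_PER_MLMIN
mm_to_m <- function(x) x * 1e-3
cms_to_ms <- function(v) v * 1e-2
ms_to_cms <- function(v) v * 1e2

#' Poiseuille resistance of a cylindrical segment
#'
#' Viscous resistance `8 mu L / (pi r^4)` of a straight circular conduit,
#' in SI units (Pa.s/m^3).
#'
#' @param length_mm Segment length (mm).
#' @param radius_mm Lumen radius (mm).
#' @param viscosity Dynamic viscosity (Pa.s).
#' @return Resistance in Pa.s/m^3.
#' @export
poiseuille_resistance <- function(length_mm, radius_mm, viscosity = 0.004) {
  stopifnot(length_mm > 0, radius_mm > 0, viscosity > 0)
  8 * viscosity * mm_to_m(length_mm) / (pi * mm_to_m(radius_mm)^4)
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
  invisible(NULL)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
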