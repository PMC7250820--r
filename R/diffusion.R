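#' Diffusion context for clearance-rate ceilings
#'
#' Bundles the physical inputs of diffusion-limited nutrient capture: the
#' solute diffusivity `D`, the (equivalent-sphere) cell radius `a`, and the
#' number `N` and radius `s` of absorbing porin patches on the outer
#' membrane.
#'
#' The default diffusivity `7e-10` m^2/s is a standard literature magnitude
#' for orthophosphate in seawater; every derived ratio accepts `D` as an
#' input, so the default only sets a scale.
#'
#' @param diffusivity Solute diffusivity in m^2/s (> 0), default `7e-10`.
#' @param cell_radius Cell radius in m (> 0).
#' @param porin_count Number of absorbing porin patches (>= 0), default 0
#'   (no porin restriction requested).
#' @param porin_radius Porin patch radius in m; required positive when
#'   `porin_count > 0`. Default `1e-9`.
#' @return An object of class `diffusion_context`.
#' @examples
#' diffusion_context(cell_radius = 0.5e-6)
#' @export
diffusion_context <- function(diffusivity = 7e-10,
                              cell_radius,
                              porin_count = 0,
                              porin_radius = 1e-9) {
  .check_num(diffusivity, "diffusivity", positive = TRUE, len = 1)
  .check_num(cell_radius, "cell_radius", positive = TRUE, len = 1)
  .check_num(porin_count, "porin_count", nonneg = TRUE, len = 1)
  if (porin_count > 0)
    .check_num(porin_radius, "porin_radius", positive = TRUE, len = 1)
  structure(
    list(diffusivity = diffusivity, cell_radius = cell_radius,
         porin_count = porin_count, porin_radius = porin_radius),
    class = "diffusion_context"
  )
}

#' Equivalent-sphere diffusion context for a non-spherical cell
#'
#' The theoretical ceiling below is exact for a sphere; for rods we use the
#' radius of the sphere with equal surface area (an approximation — exact
#' capacitance formulas for spherocylinders are deliberately out of scope).
#'
#' @param geom A [cell_geometry()] object.
#' @param ... Passed on to [diffusion_context()] (`diffusivity`,
#'   `porin_count`, `porin_radius`).
#' @return A `diffusion_context`.
#' @export
diffusion_context_for_cell <- function(geom, ...) {
  stopifnot(inherits(geom, "cell_geometry"))
  area_m2 <- surface_and_volume(geom)[["area_um2"]] * 1e-12
  diffusion_context(cell_radius = sqrt(area_m2 / (4 * pi)), ...)
}

## 4*pi*D*a in m^3/s -> l/min
.m3s_to_lmin <- function(x) x * 1e3 * 60

#' Diffusion-limited (maximal) clearance rate of a spherical absorber
#'
#' The Smoluchowski/Berg-Purcell ceiling `4 pi D a` for a perfectly
#' absorbing sphere, converted to litres of water cleared of solute per
#' minute. Measured per-cell clearance rates are compared against this
#' ceiling ("n-fold below the theoretical maximum").
#'
#' @param ctx A [diffusion_context()].
#' @return Clearance in l/min.
#' @examples
#' max_clearance_sphere(diffusion_context(1e-9, 0.5e-6))  # 3.77e-10 l/min
#' @export
max_clearance_sphere <- function(ctx) {
  stopifnot(inherits(ctx, "diffusion_context"))
  .m3s_to_lmin(4 * pi * ctx$diffusivity * ctx$cell_radius)
}

#' Porin-restricted clearance rate
#'
#' Berg-Purcell disc-absorber result for `N` absorbing patches of radius `s`
#' on an otherwise reflecting sphere: `4 pi D a * N s / (N s + pi a)`.
#' Saturates at the full-sphere ceiling as `N -> Inf` and reaches half of it
#' at `N s = pi a`; only a small fraction of the surface needs to be porin
#' to approach the diffusion limit.
#'
#' @param ctx A [diffusion_context()] with `porin_count`/`porin_radius` set.
#' @return Clearance in l/min (0 when `porin_count` is 0).
#' @export
porin_restricted_clearance <- function(ctx) {
  stopifnot(inherits(ctx, "diffusion_context"))
  Ns <- ctx$porin_count * ctx$porin_radius
  max_clearance_sphere(ctx) * Ns / (Ns + pi * ctx$cell_radius)
}

#' Fold-gap between the diffusion ceiling and a measured clearance rate
#'
#' `max_clearance_sphere(ctx) / measured_cl`: e.g. maximal field rates of
#' oceanic SAR11, *Prochlorococcus* and *Synechococcus* sit ~30x, 40x and
#' 25x below their diffusion ceilings.
#'
#' @param measured_cl Measured clearance in l/min (> 0).
#' @param ctx A [diffusion_context()].
#' @return Fold below maximum (dimensionless, >= 1 when measured <= ceiling).
#' @export
clearance_deficit <- function(measured_cl, ctx) {
  .check_num(measured_cl, "measured_cl", positive = TRUE)
  max_clearance_sphere(ctx) / measured_cl
}

#' Biovolume-specific clearance rate
#'
#' Clearance normalised by cell volume: how many times its own volume of
#' water a cell clears of solute per minute (reported magnitudes for marine
#' picoplankton are 1e4-1e5 cell volumes per minute).
#'
#' @param cl Clearance in l/min (>= 0).
#' @param cell_volume Cell volume in litres (> 0).
#' @return Cell volumes cleared per minute.
#' @examples
#' biovolume_specific_clearance(1.8e-11, 7e-16)  # ~2.6e4
#' @export
biovolume_specific_clearance <- function(cl, cell_volume) {
  .check_num(cl, "cl", nonneg = TRUE)
  .check_num(cell_volume, "cell_volume", positive = TRUE)
  cl / cell_volume
}

#' Time to accumulate one cellular P quota at a given concentration
#'
#' `quota / (cl * conc * N_A)` minutes: the time for a cell clearing `cl`
#' litres per minute at ambient concentration `conc` to take up `quota`
#' phosphorus atoms. At 1e-6 mol/l a cultured *Synechococcus*-sized quota
#' (1.93e7 atoms) doubles in roughly 3 h.
#'
#' @param cl Clearance in l/min (> 0).
#' @param conc Ambient concentration in mol/l (> 0).
#' @param quota Cell quota in atoms (> 0).
#' @return Time in minutes.
#' @examples
#' quota_doubling_time(1.78e-13, 1e-6, 1.93e7)  # ~180 min
#' @export
quota_doubling_time <- function(cl, conc, quota) {
  .check_num(cl, "cl", positive = TRUE)
  .check_num(conc, "conc", positive = TRUE)
  .check_num(quota, "quota", positive = TRUE)
  quota / (cl * conc * .N_A)
}
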