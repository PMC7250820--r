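#' Cell geometry description
#'
#' Constructs a validated cell-geometry object for a spherical or
#' spherocylindrical (rod) cell together with its periplasm depth. Lengths of
#' the cell body are given in micrometres; the periplasm depth in metres
#' (bacterial periplasm depths are conventionally quoted in metres, with
#' 1e-8 m a standard estimate for marine picocyanobacteria).
#'
#' For a spherocylinder, `total_length_um` is tip-to-tip, so the cylindrical
#' section has length `total_length_um - diameter_um`; `total_length_um ==
#' diameter_um` degenerates to a sphere.
#'
#' @param shape `"sphere"` or `"spherocylinder"`.
#' @param diameter_um Cell diameter in micrometres.
#' @param total_length_um Tip-to-tip length in micrometres. Defaults to the
#'   diameter (a sphere); must be `>= diameter_um`.
#' @param periplasm_depth_m Periplasm (shell) depth in metres, default `1e-8`.
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry("sphere", diameter_um = 0.8)
#' cell_geometry("spherocylinder", diameter_um = 0.4, total_length_um = 1.0)
#' @export
cell_geometry <- function(shape = c("sphere", "spherocylinder"),
                          diameter_um,
                          total_length_um = diameter_um,
                          periplasm_depth_m = 1e-8) {
  shape <- match.arg(shape)
  .check_num(diameter_um, "diameter_um", positive = TRUE, len = 1)
  .check_num(total_length_um, "total_length_um", positive = TRUE, len = 1)
  .check_num(periplasm_depth_m, "periplasm_depth_m", nonneg = TRUE, len = 1)
  if (total_length_um < diameter_um)
    .stopf("total_length_um (%g) must be >= diameter_um (%g)",
           total_length_um, diameter_um)
  if (shape == "sphere" && total_length_um != diameter_um)
    .stopf("a sphere must have total_length_um equal to diameter_um")
  if (periplasm_depth_m >= .um_to_m(diameter_um) / 2)
    .stopf("periplasm_depth_m must be smaller than the cell radius")
  structure(
    list(shape = shape,
         diameter_um = diameter_um,
         total_length_um = total_length_um,
         periplasm_depth_m = periplasm_depth_m),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  sv <- surface_and_volume(x)
  cat(sprintf("Cell geometry: %s, d = %g um, L = %g um, periplasm %g m\n",
              x$shape, x$diameter_um, x$total_length_um, x$periplasm_depth_m))
  cat(sprintf("  area %.4g um^2, volume %.4g um^3 (%.4g l), SA:V %.4g um^-1\n",
              sv["area_um2"], sv["volume_um3"],
              .um3_to_l(sv["volume_um3"]), sv["sa_to_v_um"]))
  invisible(x)
}

#' Volume of an ellipsoid given its three axis diameters
#'
#' `V = pi/6 * d1 * d2 * d3`, with diameters in nanometres and the result in
#' litres. Used for globular-protein volumes from crystallographic bounding
#' dimensions; for the phosphate-binding protein PstS the published bounding
#' dimensions 3.5 x 4 x 7 nm give ~5.1e-23 l.
#'
#' @param d1,d2,d3 Axis diameters in nm; all must be positive.
#' @return Volume in litres.
#' @examples
#' ellipsoid_volume(3.5, 4, 7)   # ~5.1e-23 l, a PstS subunit
#' ellipsoid_volume(2, 2, 2)     # sphere of diameter 2 nm
#' @export
ellipsoid_volume <- function(d1, d2, d3) {
  .check_num(d1, "d1", positive = TRUE)
  .check_num(d2, "d2", positive = TRUE)
  .check_num(d3, "d3", positive = TRUE)
  .nm3_to_l(pi / 6 * d1 * d2 * d3)
}

## closed-form area/volume in um^2 / um^3 for a sphere or spherocylinder with
## diameter d and tip-to-tip length L (cylinder section L - d)
.shape_area_volume <- function(shape, d, L) {
  if (shape == "sphere" || L == d) {
    c(area = pi * d^2, volume = pi / 6 * d^3)
  } else {
    h <- L - d
    c(area = pi * d * h + pi * d^2,
      volume = pi / 4 * d^2 * h + pi / 6 * d^3)
  }
}

#' Surface area, volume and surface-to-volume ratio of a cell
#'
#' Closed-form sphere / spherocylinder expressions. The surface-to-volume
#' ratio is the standard comparator for nutrient-uptake effectiveness across
#' cell morphologies (small curved rods such as SAR11 roughly double the
#' ratio of similarly sized cocci).
#'
#' @param geom A [cell_geometry()] object.
#' @return Named numeric vector: `area_um2`, `volume_um3`, `sa_to_v_um`
#'   (ratio, um^-1).
#' @examples
#' surface_and_volume(cell_geometry("sphere", 1))          # pi, pi/6, 6
#' surface_and_volume(cell_geometry("spherocylinder", 0.4, 1.0))
#' @export
surface_and_volume <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  av <- .shape_area_volume(geom$shape, geom$diameter_um, geom$total_length_um)
  c(area_um2 = unname(av["area"]),
    volume_um3 = unname(av["volume"]),
    sa_to_v_um = unname(av["area"] / av["volume"]))
}

#' Periplasmic shell volume of a cell
#'
#' Exact outer-minus-inner volume of the shell of thickness
#' `periplasm_depth_m` under the cell's shape. For a sphere this is
#' `(pi/6) (d^3 - (d - 2t)^3)`; for a spherocylinder the analogous closed
#' form shrinks both the diameter and the tip-to-tip length by `2t`. In the
#' thin-shell limit the result converges to `surface area x depth`.
#'
#' A 0.8 um coccus with a 1e-8 m periplasm has a shell of ~2e-17 l, the
#' magnitude usually quoted for marine *Synechococcus*.
#'
#' @param geom A [cell_geometry()] object.
#' @return Shell volume in litres.
#' @examples
#' periplasm_shell_volume(cell_geometry("sphere", 0.8))  # ~2e-17 l
#' @export
periplasm_shell_volume <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  t_um <- .m_to_um(geom$periplasm_depth_m)
  d <- geom$diameter_um
  L <- geom$total_length_um
  if (t_um >= d / 2) .stopf("periplasm depth must be smaller than the radius")
  outer <- .shape_area_volume(geom$shape, d, L)["volume"]
  inner <- .shape_area_volume(geom$shape, d - 2 * t_um, L - 2 * t_um)["volume"]
  .um3_to_l(unname(outer - inner))
}

#' Convert a molecule count in a volume to a molar concentration
#'
#' `n / (N_A * volume)`. The central arithmetic behind periplasmic
#' feasibility arguments: e.g. 4e6 Pi molecules in a 2.1e-17 l periplasm is
#' ~0.3 mol/l, and even two free molecules in 2e-17 l already exceed the
#' 1e-7 mol/l concentration needed for efficient ABC-transporter import.
#'
#' @param n Number of molecules (>= 0).
#' @param volume Volume in litres (> 0).
#' @return Concentration in mol/l.
#' @examples
#' molecules_to_concentration(4e6, 2.1e-17)  # ~0.3 mol/l
#' molecules_to_concentration(2, 2e-17)      # > 1e-7 mol/l
#' @export
molecules_to_concentration <- function(n, volume) {
  .check_num(n, "n", nonneg = TRUE)
  .check_num(volume, "volume", positive = TRUE)
  n / (.N_A * volume)
}

#' Inverse of [molecules_to_concentration()]
#'
#' @param conc Concentration in mol/l (>= 0).
#' @param volume Volume in litres (> 0).
#' @return Number of molecules.
#' @export
concentration_to_molecules <- function(conc, volume) {
  .check_num(conc, "conc", nonneg = TRUE)
  .check_num(volume, "volume", positive = TRUE)
  conc * .N_A * volume
}

#' How many rigid units fit in a container volume
#'
#' `floor(container_volume / unit_volume)`: the zeroth-order packing bound
#' used to ask whether enough phosphate-binding PstS subunits could fit in
#' the periplasm to hold the observed labile Pi stock.
#'
#' @param container_volume Container volume in litres (> 0).
#' @param unit_volume Volume of one unit in litres (> 0).
#' @return Integer-valued count (as numeric, since counts can exceed
#'   `.Machine$integer.max`).
#' @examples
#' packing_capacity(2e-17, 5.1e-23)  # ~4e5 subunits
#' @export
packing_capacity <- function(container_volume, unit_volume) {
  .check_num(container_volume, "container_volume", positive = TRUE)
  .check_num(unit_volume, "unit_volume", positive = TRUE)
  floor(container_volume / unit_volume)
}

#' Fold-deficit of a packing capacity against a requirement
#'
#' `required / capacity`: e.g. sequestering 6.7e6 labile Pi molecules
#' one-per-subunit against a ~3.9e5-subunit capacity is a ~17-fold deficit.
#'
#' @param required Number of units required (>= 0).
#' @param capacity Available capacity (> 0), e.g. from [packing_capacity()].
#' @return Fold deficit (dimensionless).
#' @examples
#' deficit_ratio(6.7e6, packing_capacity(2e-17, 5.1e-23))  # ~17
#' @export
deficit_ratio <- function(required, capacity) {
  .check_num(required, "required", nonneg = TRUE)
  .check_num(capacity, "capacity", positive = TRUE)
  required / capacity
}

#' Osmolarity increment from accumulating a salt
#'
#' `salt_conc * particles_per_formula`. A neutral ion pair contributes one
#' osmotically active particle per formula unit, so accumulating 0.5 mol/l of
#' paired Pi salt raises periplasmic osmolarity by ~0.5 osmol/l — roughly
#' half the osmolarity of seawater.
#'
#' @param salt_conc Salt concentration in mol/l (>= 0).
#' @param particles_per_formula Osmotically active particles per formula unit
#'   (>= 0); 1 for a neutral ion pair, 2 for a fully dissociated 1:1 salt.
#' @return Osmolarity increment in osmol/l.
#' @examples
#' osmolarity_increment(0.5, 1)  # 0.5 osmol/l
#' @export
osmolarity_increment <- function(salt_conc, particles_per_formula = 1) {
  .check_num(salt_conc, "salt_conc", nonneg = TRUE)
  .check_num(particles_per_formula, "particles_per_formula", nonneg = TRUE)
  salt_conc * particles_per_formula
}

#' Report a value at full precision and rounded to 1 and 2 significant figures
#'
#' Convenience for quoting "paper-style" rounded values next to the exact
#' arithmetic; computational functions in this package never round.
#'
#' @param x Numeric value(s).
#' @return A data frame with columns `value`, `signif1`, `signif2`.
#' @examples
#' paper_style(ellipsoid_volume(3.5, 4, 7))
#' @export
paper_style <- function(x) {
  .check_num(x, "x")
  data.frame(value = x, signif1 = signif(x, 1), signif2 = signif(x, 2))
}
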