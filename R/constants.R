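#' Physical constants used throughout the package
#'
#' Avogadro's number and the molar mass of phosphorus, as a locked list.
#' All package arithmetic that converts between molecules, moles and grams
#' goes through these values; they are fixed and not user-configurable.
#'
#' @return A list with elements `avogadro` (mol^-1) and
#'   `phosphorus_molar_mass` (g mol^-1).
#' @examples
#' physical_constants()$avogadro
#' @export
physical_constants <- function() {
  list(
    avogadro = 6.02214076e23,
    phosphorus_molar_mass = 30.974
  )
}

## internal shorthands
.N_A <- 6.02214076e23
.M_P <- 30.974

## unit conversions centralised here: lengths are um for cells, nm for
## proteins, m for membrane/periplasm depths; volumes are litres.
.um3_to_l <- function(v) v * 1e-15
.nm3_to_l <- function(v) v * 1e-24
.um_to_m <- function(x) x * 1e-6
.m_to_um <- function(x) x * 1e6

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                       len = NULL, finite = TRUE) {
  if (!is.numeric(x)) .stopf("'%s' must be numeric", name)
  if (!is.null(len) && length(x) != len)
    .stopf("'%s' must have length %d", name, len)
  if (finite && any(!is.finite(x))) .stopf("'%s' must be finite", name)
  if (positive && any(x <= 0)) .stopf("'%s' must be > 0", name)
  if (nonneg && any(x < 0)) .stopf("'%s' must be >= 0", name)
  invisible(x)
}
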