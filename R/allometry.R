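#' Aboveground biomass of a tree from its diameter
#'
#' Single-predictor allometric model for moist tropical forest,
#' `ln(AGB) = -1.562 + 2.148 * ln(dbh)`, fitted by Chave and colleagues for a
#' Guianan site; predicts whole-tree aboveground biomass (kg, oven-dry) from
#' diameter at breast height (cm).
#'
#' @param dbh Numeric vector of diameters at breast height, cm. All values
#'   must be strictly positive.
#' @return Numeric vector of tree aboveground biomass, kg.
#' @export
#' @examples
#' agb_from_dbh(c(15, 29.3, 149.1))
agb_from_dbh <- function(dbh) {
  if (!is.numeric(dbh)) abort("`dbh` must be numeric")
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    abort("`dbh` must be strictly positive and finite (cm)")
  }
  exp(-1.562 + 2.148 * log(dbh))
}
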