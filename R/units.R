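#' Convert ambient oxygen percentage to dissolved concentration
#'
#' Linear map anchored at 21% ambient O2 = 209 uM dissolved oxygen, the
#' cell-culture normoxia reference; 2% maps to 19.9 uM (3 significant
#' figures), the standard in-vitro hypoxia condition.
#'
#' @param pct Ambient O2 percentage, in `[0, 21]`.
#' @param signif_digits Significant digits used for display rounding
#'   (`NULL` for the exact value).
#' @return Dissolved O2 concentration in uM.
#' @export
#' @examples
#' o2_percent_to_concentration(21) # 209
#' o2_percent_to_concentration(2)  # 19.9
o2_percent_to_concentration <- function(pct, signif_digits = 3) {
  if (!is.numeric(pct) || any(is.na(pct)) || any(pct < 0) ||
      any(pct > 21)) {
    stop("ambient O2 percentage must lie in [0, 21]", call. = FALSE)
  }
  conc <- 209 * pct / 21
  if (!is.null(signif_digits)) conc <- signif(conc, signif_digits)
  conc
}

#' Convert molecule copy numbers to concentration
#'
#' Micromolar concentration of `copies` molecules in a cell of the given
#' volume (default 1 pL, the conventional endothelial cell volume used for
#' copy-number normalisation).
#'
#' @param copies Molecule count (non-negative).
#' @param volume_pL Cell volume in picolitres (> 0).
#' @return Concentration in uM.
#' @export
#' @examples
#' copies_to_concentration(602214)   # ~1 uM in 1 pL
copies_to_concentration <- function(copies, volume_pL = 1) {
  if (any(copies < 0)) stop("copy number must be >= 0", call. = FALSE)
  if (any(volume_pL <= 0)) stop("cell volume must be > 0", call. = FALSE)
  avogadro <- 6.02214076e23
  moles <- copies / avogadro
  litres <- volume_pL * 1e-12
  moles / litres * 1e6
}
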