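# evaluate expr with a local RNG state, restoring the caller's afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Moles from mass
#'
#' Convenience for preparation stoichiometry, e.g. 8.28 g of a
#' 2-hydroxypropyl-beta-cyclodextrin of average molecular weight 1380 g/mol
#' is 6e-3 mol.
#'
#' @param mass_g mass in grams.
#' @param mw molecular weight in g/mol.
#' @return Amount of substance in mol.
#' @export
moles_from_mass <- function(mass_g, mw) {
  if (mw <= 0) stop("molecular weight must be positive", call. = FALSE)
  mass_g / mw
}
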