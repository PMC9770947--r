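#' Monoisotopic residue and modification masses
#'
#' Bundled monoisotopic mass tables used throughout the package: the twenty
#' standard amino acid residue masses, a small table of named modifications,
#' and physical constants (water, the averagine isotope spacing used to model
#' +/- 1 Da deconvolution errors).
#'
#' @format `AA_MONO` is a named numeric vector of residue masses in Da;
#'   `MOD_MONO` a named numeric vector of modification delta masses in Da.
#' @name masses
NULL

#' @rdname masses
#' @export
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname masses
#' @export
MOD_MONO <- c(
  acetyl = 42.01057,
  phospho = 79.96633,
  methyl = 14.01565,
  trimethyl = 42.04695,
  oxidation = 15.99491,
  carbamidomethyl = 57.02146,
  carbamidomethylation = 57.02146
)

# water (H2O) and the averagine isotope spacing, monoisotopic Da
WATER_MONO <- 18.010565
ISOTOPE_DA <- 1.00235

#' Resolve a named modification to its monoisotopic mass
#'
#' Unknown modification names are carried symbolically: they resolve to `NA`
#' rather than raising an error, so proteoform strings with site-specific or
#' non-standard annotations still parse.
#'
#' @param name character vector of modification names.
#' @return numeric vector of delta masses in Da (`NA` where unknown).
#' @export
mod_mass <- function(name) {
  m <- MOD_MONO[tolower(name)]
  names(m) <- name
  unname(m)
}
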