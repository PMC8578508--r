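#' Amino-acid residue mass tables
#'
#' Residue (i.e. dehydrated) masses of the 20 standard amino acids on the
#' average or monoisotopic scale, in Da. Summing residue masses over a chain
#' and adding one water gives the intact chain mass.
#'
#' @param scale `"average"` or `"monoisotopic"`.
#' @return Named numeric vector of 20 residue masses (Da).
#' @examples
#' aa_residue_masses()[["G"]] + water_mass()  # free glycine, 75.07 Da
#' @export
aa_residue_masses <- function(scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  if (scale == "average") .aa_avg else .aa_mono
}

.aa_avg <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.aa_mono <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

#' @rdname aa_residue_masses
#' @export
water_mass <- function(scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  if (scale == "average") 18.01524 else 18.010565
}

# standard UniMod shifts
.mod_shifts <- list(
  phospho = c(average = 79.9799, monoisotopic = 79.96633),
  acetyl  = c(average = 42.0367, monoisotopic = 42.01057)
)

#' Mass-computation options
#'
#' @param scale mass scale, `"average"` (default; matches typical intact-mass
#'   reporting) or `"monoisotopic"`.
#' @param include_water add one water for the intact chain (default `TRUE`;
#'   set `FALSE` to obtain the residue-sum of a chain segment).
#' @param adduct extra terminal/adduct mass in Da (default 0), e.g. for an
#'   uncleaved expression tag modelled as a lumped mass.
#' @return A list of class `mass_options`.
#' @export
mass_options <- function(scale = c("average", "monoisotopic"),
                         include_water = TRUE, adduct = 0) {
  scale <- match.arg(scale)
  stopifnot(is.logical(include_water), length(include_water) == 1L,
            is.numeric(adduct), length(adduct) == 1L)
  structure(list(scale = scale, include_water = include_water, adduct = adduct),
            class = "mass_options")
}

# residue-sum of a plain sequence string; errors name the offending position
.sequence_mass <- function(sequence, scale) {
  chars <- strsplit(sequence, "")[[1]]
  tab <- aa_residue_masses(scale)
  m <- tab[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("unknown residue code '", chars[bad], "' at sequence position ", bad,
         call. = FALSE)
  }
  sum(m)
}
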