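#' Amino-acid scales and alphabets
#'
#' Constants shared across the package: the 20-letter standard alphabet, the
#' 18-letter building-block alphabet (standard minus tryptophan and cysteine),
#' the TOP-IDP disorder-propensity scale, and the average residue-mass table.
#'
#' @name scales
NULL

#' Standard 20-letter amino-acid alphabet (one-letter codes)
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

#' TOP-IDP disorder propensity scale
#'
#' Per-residue disorder propensities from the TOP-IDP scale (Campen et al.,
#' 2008). Higher values are more disorder-promoting; tryptophan (W) is the
#' most order-promoting residue and proline (P) the most disorder-promoting.
#'
#' @format Named numeric vector over the 20 standard one-letter codes.
#' @export
TOP_IDP <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
  L = -0.326, V = -0.121, C = -0.020, N =  0.007, T =  0.059,
  A =  0.060, G =  0.166, R =  0.180, D =  0.192, H =  0.303,
  Q =  0.318, S =  0.341, K =  0.586, E =  0.736, P =  0.987
)[AA_STANDARD]

#' 18-letter building-block alphabet
#'
#' The standard alphabet with W and C removed: W is the most order-promoting
#' residue and C can stabilize tertiary structure through disulphide bonds,
#' so neither is used when proposing building blocks.
#' @export
AA_BLOCK <- setdiff(AA_STANDARD, c("W", "C"))

#' 18-letter alphabet ordered by increasing disorder propensity (TOP-IDP)
#' @export
AA_BLOCK_BY_DISORDER <- AA_BLOCK[order(TOP_IDP[AA_BLOCK])]

# Average residue masses (Da), Expasy values; free amino acid = residue + water
AA_RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)

MASS_WATER <- 18.01528

# Split a sequence string into validated one-letter residues
aa_chars <- function(sequence, alphabet = AA_STANDARD, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- !(aa %in% alphabet)
  if (any(bad))
    stop(what, " contains non-amino-acid character(s): ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  aa
}
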