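#' Reference per-residue disorder scorer
#'
#' The designer only requires a scorer satisfying a simple contract: given an
#' amino-acid string it returns one score per residue in \[0, 1\],
#' deterministically, with higher scores denoting higher predicted disorder.
#' Any predictor honouring the contract can be plugged in (see
#' [score_profile()]'s `model` argument and [as_disorder_scorer()]).
#'
#' The reference implementation shipped here follows the energy-estimation
#' family of predictors: the stabilizing interaction energy of each residue is
#' estimated from the amino-acid composition of its sequential neighbourhood
#' (separations 2 to 100, the "long-disorder" regime), weighted by a symmetric
#' pairwise matrix seeded from the TOP-IDP order-propensity scale; energies
#' are mapped to \[0, 1\] by a monotone logistic transform and smoothed by a
#' centred 21-residue mean. Neighbourhoods and smoothing windows are truncated
#' at the termini and renormalized by the actual residue count.
#'
#' @param energy_matrix Symmetric numeric matrix of pairwise interaction
#'   weights with rows/columns named by the 20 one-letter codes. Lower
#'   (more negative) values are more stabilizing, hence more order-promoting.
#'   The default is the negated outer product of shifted TOP-IDP order
#'   weights, `-(shift - TOP_IDP) %o% (shift - TOP_IDP)`.
#' @param propensity_shift Scalar added to the negated TOP-IDP scale so all
#'   order weights are strictly positive (keeps the transform monotone in the
#'   marginal propensity of every residue).
#' @param neighborhood_min,neighborhood_max Sequential separation bounds (in
#'   residues) of the composition neighbourhood used for energy estimation.
#' @param smoothing_window Odd window length (residues) of the centred mean
#'   applied to the transformed scores.
#' @param transform_midpoint,transform_slope Location and scale of the
#'   logistic energy-to-score map `plogis((e - midpoint) / slope)`. Defaults
#'   are calibrated so that mean scores of long random sequences over the
#'   18-letter building-block alphabet span the working range of target
#'   disorder probabilities (0.55 to 0.95).
#'
#' @return An object of class `disorder_model`.
#' @examples
#' m <- disorder_model()
#' p <- score_profile(strrep("P", 30), m)   # proline-rich: high disorder
#' q <- score_profile(strrep("F", 30), m)   # phenylalanine: low disorder
#' mean(p) > mean(q)
#' @export
disorder_model <- function(energy_matrix = NULL,
                           propensity_shift = 1.2,
                           neighborhood_min = 2L,
                           neighborhood_max = 100L,
                           smoothing_window = 21L,
                           transform_midpoint = -1.60,
                           transform_slope = 0.25) {
  if (is.null(energy_matrix)) {
    s <- propensity_shift - TOP_IDP
    if (any(s <= 0))
      stop("propensity_shift must exceed the largest TOP-IDP value",
           call. = FALSE)
    energy_matrix <- -outer(s, s)
    dimnames(energy_matrix) <- list(AA_STANDARD, AA_STANDARD)
  }
  stopifnot(is.matrix(energy_matrix),
            nrow(energy_matrix) == ncol(energy_matrix),
            !is.null(rownames(energy_matrix)),
            identical(rownames(energy_matrix), colnames(energy_matrix)))
  if (max(abs(energy_matrix - t(energy_matrix))) > 1e-9)
    stop("energy_matrix must be symmetric", call. = FALSE)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be a positive odd integer", call. = FALSE)
  if (transform_slope <= 0)
    stop("transform_slope must be positive (monotone transform)",
         call. = FALSE)
  if (neighborhood_min < 1L || neighborhood_max < neighborhood_min)
    stop("require 1 <= neighborhood_min <= neighborhood_max", call. = FALSE)
  structure(
    list(energy_matrix = energy_matrix,
         neighborhood_min = as.integer(neighborhood_min),
         neighborhood_max = as.integer(neighborhood_max),
         smoothing_window = smoothing_window,
         transform_midpoint = transform_midpoint,
         transform_slope = transform_slope),
    class = "disorder_model")
}

#' @export
print.disorder_model <- function(x, ...) {
  cat("Reference disorder scorer\n")
  cat("  alphabet:", paste(rownames(x$energy_matrix), collapse = ""), "\n")
  cat(sprintf("  neighbourhood separations: %d..%d residues\n",
              x$neighborhood_min, x$neighborhood_max))
  cat(sprintf("  smoothing window: %d residues\n", x$smoothing_window))
  cat(sprintf("  logistic transform: midpoint %.4g, slope %.4g\n",
              x$transform_midpoint, x$transform_slope))
  invisible(x)
}

#' Score a sequence, one disorder probability per residue
#'
#' Returns the per-residue disorder profile of an amino-acid sequence under a
#' scorer. `model` may be a [disorder_model()] (the reference implementation)
#' or any function taking a sequence string and returning one numeric score
#' in \[0, 1\] per residue (an external-predictor adapter).
#'
#' @param sequence Single amino-acid string over the 20-letter alphabet.
#' @param model A `disorder_model` or a scorer function.
#' @return Numeric vector of per-residue disorder scores in \[0, 1\], of the
#'   same length as `sequence`.
#' @seealso [profile_stats()], [score_block_in_context()]
#' @export
score_profile <- function(sequence, model = disorder_model()) {
  if (is.function(model)) {
    scores <- model(sequence)
    n <- nchar(sequence)
    if (length(scores) != n)
      stop("scorer returned ", length(scores), " scores for a ", n,
           "-residue sequence", call. = FALSE)
    if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
      stop("scorer returned scores outside [0, 1]", call. = FALSE)
    return(as.numeric(scores))
  }
  stopifnot(inherits(model, "disorder_model"))
  alphabet <- rownames(model$energy_matrix)
  aa <- aa_chars(sequence, alphabet)
  idx <- match(aa, alphabet)
  n <- length(idx)
  k <- length(alphabet)

  # neighbourhood composition: counts of each residue type at sequential
  # separation in [nb_min, nb_max] of every position, termini truncated
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), idx)] <- 1
  cum <- rbind(0, apply(ind, 2L, cumsum))
  pos <- seq_len(n)
  lo <- pmax(pos - model$neighborhood_max, 1L)
  hi <- pmin(pos + model$neighborhood_max, n)
  counts <- cum[hi + 1L, , drop = FALSE] - cum[lo, , drop = FALSE]
  # remove the excluded core |i - j| < nb_min (includes the residue itself)
  for (d in 0:(model$neighborhood_min - 1L)) {
    at <- pos - d
    ok <- at >= 1L
    counts[cbind(pos[ok], idx[at[ok]])] <-
      counts[cbind(pos[ok], idx[at[ok]])] - 1
    if (d > 0L) {
      at <- pos + d
      ok <- at <= n
      counts[cbind(pos[ok], idx[at[ok]])] <-
        counts[cbind(pos[ok], idx[at[ok]])] - 1
    }
  }
  total <- rowSums(counts)
  weights <- model$energy_matrix[idx, , drop = FALSE]
  energy <- ifelse(total > 0,
                   rowSums(counts * weights) / pmax(total, 1L),
                   # degenerate short sequence: self-composition fallback
                   diag(model$energy_matrix)[idx])
  raw <- stats::plogis((energy - model$transform_midpoint) /
                         model$transform_slope)

  # centred running mean, truncated and renormalized at the termini
  half <- (model$smoothing_window - 1L) %/% 2L
  craw <- c(0, cumsum(raw))
  lo <- pmax(pos - half, 1L)
  hi <- pmin(pos + half, n)
  (craw[hi + 1L] - craw[lo]) / (hi - lo + 1L)
}

#' Mean and range of a disorder profile over a span
#'
#' Computes the two statistics the acceptance rules consume: the arithmetic
#' mean disorder score and the score range delta = max - min (a smoothness
#' measure; the lower the delta, the flatter the profile).
#'
#' @param profile Numeric vector of per-residue scores (see
#'   [score_profile()]).
#' @param span Optional integer vector `c(from, to)` (1-based, inclusive)
#'   restricting the statistics to a sub-span; defaults to the full profile.
#' @return List with components `mean` and `delta`.
#' @export
profile_stats <- function(profile, span = NULL) {
  stopifnot(is.numeric(profile), length(profile) >= 1L)
  if (is.null(span)) span <- c(1L, length(profile))
  stopifnot(length(span) == 2L)
  from <- as.integer(span[1L]); to <- as.integer(span[2L])
  if (from < 1L || to > length(profile) || from > to)
    stop("span [", from, ", ", to, "] is empty or outside the profile",
         call. = FALSE)
  x <- profile[from:to]
  list(mean = mean(x), delta = max(x) - min(x))
}

#' Score a building block inside its tandem-repeat context
#'
#' A candidate 10-residue building block is evaluated by repeating it seven
#' times and scoring the 70-mer, so that the central copy sees three full
#' blocks of flanking context on each side (enough to clear both the
#' 21-residue smoothing window's reach and terminal truncation effects).
#' Statistics are returned for the central block's 10 positions (31-40).
#'
#' @param block 10-residue string over the standard alphabet.
#' @param model Scorer, as in [score_profile()].
#' @param repeats Odd number of tandem copies (default 7).
#' @param block_size Expected block length (default 10).
#' @return List with `mean` and `delta` over the central block.
#' @export
score_block_in_context <- function(block, model = disorder_model(),
                                   repeats = 7L, block_size = 10L) {
  repeats <- as.integer(repeats)
  if (repeats < 3L || repeats %% 2L == 0L)
    stop("repeats must be an odd integer >= 3", call. = FALSE)
  if (nchar(block) != block_size)
    stop("block must have exactly ", block_size, " residues (got ",
         nchar(block), ")", call. = FALSE)
  profile <- score_profile(strrep(block, repeats), model)
  start <- ((repeats - 1L) %/% 2L) * block_size + 1L
  profile_stats(profile, c(start, start + block_size - 1L))
}

#' Wrap an external per-residue predictor as a scorer
#'
#' Adapter for plugging any disorder predictor into the designer: `fun` must
#' accept a plain amino-acid string and return one numeric score per residue.
#' Scores are validated to lie in \[0, 1\] on every call.
#'
#' @param fun Function from sequence string to numeric vector.
#' @return A scorer function usable wherever a `model` is accepted.
#' @export
as_disorder_scorer <- function(fun) {
  stopifnot(is.function(fun))
  function(sequence) as.numeric(fun(sequence))
}

#' Write scorer parameters to a flat key-value file
#'
#' Serializes a [disorder_model()] to a YAML file (keys: `alphabet`,
#' `energy_matrix` as row-major numeric vector, `neighborhood_min`,
#' `neighborhood_max`, `smoothing_window`, `transform_midpoint`,
#' `transform_slope`). [read_scorer_params()] restores an identical model.
#'
#' @param model A `disorder_model`.
#' @param path Output file path.
#' @export
write_scorer_params <- function(model, path) {
  stopifnot(inherits(model, "disorder_model"))
  yaml::write_yaml(list(
    alphabet = rownames(model$energy_matrix),
    energy_matrix = as.numeric(t(model$energy_matrix)),
    neighborhood_min = model$neighborhood_min,
    neighborhood_max = model$neighborhood_max,
    smoothing_window = model$smoothing_window,
    transform_midpoint = model$transform_midpoint,
    transform_slope = model$transform_slope
  ), path)
  invisible(path)
}

#' @rdname write_scorer_params
#' @return `read_scorer_params` returns the restored `disorder_model`.
#' @export
read_scorer_params <- function(path) {
  p <- yaml::read_yaml(path)
  k <- length(p$alphabet)
  mat <- matrix(as.numeric(p$energy_matrix), nrow = k, byrow = TRUE,
                dimnames = list(p$alphabet, p$alphabet))
  disorder_model(energy_matrix = mat,
                 neighborhood_min = p$neighborhood_min,
                 neighborhood_max = p$neighborhood_max,
                 smoothing_window = p$smoothing_window,
                 transform_midpoint = p$transform_midpoint,
                 transform_slope = p$transform_slope)
}
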