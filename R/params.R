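#' Designer parameters
#'
#' Collects every tunable of the design procedure in one validated object.
#' Defaults are the working values of the method: 10-residue building blocks
#' evaluated in a 7x tandem-repeat context, a smoothness threshold of 0.15 on
#' the score range (delta), an accuracy threshold of 0.025 on the deviation of
#' the mean score from the target, at most 200 rejected candidates per central
#' insertion before the whole sequence is discarded, sequence lengths of
#' 50-200 residues, 1-10 sequences per request, and the nine-value target
#' grid 0.55-0.95 in 0.05 steps.
#'
#' @param block_size Building-block length in residues.
#' @param repeat_count Tandem copies used when evaluating a block in context.
#' @param delta_threshold Maximum allowed score range (max - min) of an
#'   accepted block or sequence profile.
#' @param mean_threshold Maximum allowed absolute deviation of the mean score
#'   from the target disorder probability.
#' @param max_rejections_per_insertion Rejected candidates tolerated at one
#'   central-insertion step before the whole sequence is discarded.
#' @param max_restarts Whole-sequence discards tolerated before a design
#'   request fails with an error.
#' @param length_min,length_max Bounds on the requested sequence length.
#' @param n_min,n_max Bounds on the number of sequences per request.
#' @param dt_grid Strictly increasing vector of selectable target disorder
#'   probabilities.
#' @param blocks_per_family Accepted blocks required to complete one family.
#' @param max_proposals Global cap on block proposals during library
#'   construction (guards termination under a pathological scorer).
#' @return An object of class `design_params`.
#' @export
design_params <- function(block_size = 10L,
                          repeat_count = 7L,
                          delta_threshold = 0.15,
                          mean_threshold = 0.025,
                          max_rejections_per_insertion = 200L,
                          max_restarts = 50L,
                          length_min = 50L,
                          length_max = 200L,
                          n_min = 1L,
                          n_max = 10L,
                          dt_grid = seq(0.55, 0.95, by = 0.05),
                          blocks_per_family = 50L,
                          max_proposals = 1e6) {
  stopifnot(block_size >= 1L, repeat_count >= 3L,
            delta_threshold > 0, mean_threshold > 0,
            max_rejections_per_insertion >= 1L, max_restarts >= 1L,
            length_min <= length_max, n_min >= 1L, n_min <= n_max,
            blocks_per_family >= 1L, max_proposals >= 1)
  if (length(dt_grid) < 1L || is.unsorted(dt_grid, strictly = TRUE))
    stop("dt_grid must be strictly increasing", call. = FALSE)
  structure(
    list(block_size = as.integer(block_size),
         repeat_count = as.integer(repeat_count),
         delta_threshold = delta_threshold,
         mean_threshold = mean_threshold,
         max_rejections_per_insertion = as.integer(max_rejections_per_insertion),
         max_restarts = as.integer(max_restarts),
         length_min = as.integer(length_min),
         length_max = as.integer(length_max),
         n_min = as.integer(n_min),
         n_max = as.integer(n_max),
         dt_grid = as.numeric(dt_grid),
         blocks_per_family = as.integer(blocks_per_family),
         max_proposals = max_proposals),
    class = "design_params")
}

# absolute tolerance applied to the inclusive threshold comparisons so that
# values computed exactly at a boundary are not rejected by rounding noise
BOUNDARY_EPS <- 1e-12

# format a Dt grid value as a stable family label ("0.55", ..., "0.95")
dt_label <- function(dt) sprintf("%.2f", dt)

# nearest grid value, ties resolved toward the lower Dt
nearest_dt <- function(mean_score, grid) {
  d <- abs(grid - mean_score)
  grid[which.min(d)]  # which.min takes the first (lower) of tied values
}

check_dt <- function(dt, params) {
  if (length(dt) != 1L || !any(abs(params$dt_grid - dt) < 1e-9))
    stop("dt must be one of the grid values {",
         paste(dt_label(params$dt_grid), collapse = ", "), "}",
         call. = FALSE)
  params$dt_grid[which.min(abs(params$dt_grid - dt))]
}
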