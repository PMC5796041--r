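#' Round a requested length up to the assembly length
#'
#' The assembler works in whole building blocks, so a requested length `l` is
#' first rounded to `l_r`, the smallest multiple of the block size (10) that
#' is at least `l`; the surplus residues are trimmed off again at the end.
#'
#' @param l Requested length, within `params$length_min..length_max`.
#' @param params [design_params()].
#' @return Integer `l_r`.
#' @examples
#' round_length(100)  # 100
#' round_length(101)  # 110
#' @export
round_length <- function(l, params = design_params()) {
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < params$length_min ||
      l > params$length_max)
    stop("requested length must lie between ", params$length_min, " and ",
         params$length_max, " residues", call. = FALSE)
  b <- params$block_size
  as.integer(ceiling(l / b) * b)
}

# Fisher-Yates shuffle of a block's residues (uses the global RNG)
shuffle_block <- function(block) {
  paste(sample(strsplit(block, "", fixed = TRUE)[[1L]]), collapse = "")
}

# draw one block sequence uniformly from a family
draw_block <- function(library, dt) {
  f <- library$families[[dt_label(dt)]]
  if (is.null(f) || nrow(f) == 0L)
    stop("family ", dt_label(dt), " of the library is empty", call. = FALSE)
  f$sequence[sample.int(nrow(f), 1L)]
}

#' Generate an initial sequence for a design
#'
#' Strategy `"repeat"` (the method's default) draws one block from the
#' requested family, shuffles its residues once, and tandem-repeats it
#' `i = l_r / 10` times. In a repeated sequence every residue sees the same
#' composition, which makes the smoothed profile nearly flat and the mean
#' close to the family score, so most starts already satisfy the acceptance
#' rules. Strategy `"concat"` instead concatenates `i` independently drawn
#' (and shuffled) blocks of the family; it is retained for the comparison
#' harness ([compare_init_strategies()]) because it yields markedly fewer
#' acceptable starts.
#'
#' @param dt Target disorder probability (grid member).
#' @param l_r Assembly length, a multiple of the block size.
#' @param library Completed [build_block_library()].
#' @param params [design_params()].
#' @param strategy `"repeat"` or `"concat"`.
#' @return List with `sequence` (length `l_r`) and `blocks` (the shuffled
#'   block(s) used, in order).
#' @export
init_sequence <- function(dt, l_r, library, params = design_params(),
                          strategy = c("repeat", "concat")) {
  strategy <- match.arg(strategy)
  dt <- check_dt(dt, params)
  b <- params$block_size
  if (l_r %% b != 0L || l_r < b)
    stop("l_r must be a positive multiple of ", b, call. = FALSE)
  i <- l_r %/% b
  if (strategy == "repeat") {
    blk <- shuffle_block(draw_block(library, dt))
    list(sequence = strrep(blk, i), blocks = blk)
  } else {
    blks <- vapply(seq_len(i),
                   function(k) shuffle_block(draw_block(library, dt)),
                   character(1))
    list(sequence = paste(blks, collapse = ""), blocks = blks)
  }
}

#' Insert a block at the centre of a sequence, preserving length
#'
#' The block (shuffled first, unless `shuffle = FALSE` for provenance
#' replay) is inserted between positions `L/2` and `L/2 + 1` of the
#' length-`L` sequence, after which the five N-terminal and five C-terminal
#' residues are deleted so the length stays constant.
#'
#' @param sequence Current sequence; its length must be a multiple of the
#'   block size.
#' @param block Block to insert (block-size residues).
#' @param params [design_params()].
#' @param shuffle Shuffle the block's residues before insertion?
#' @return List with `sequence` (same length as the input) and `block` (the
#'   residues as inserted, post-shuffle).
#' @export
central_insert <- function(sequence, block, params = design_params(),
                           shuffle = TRUE) {
  b <- params$block_size
  n <- nchar(sequence)
  if (n %% b != 0L || n < b)
    stop("sequence length must be a positive multiple of ", b, call. = FALSE)
  if (nchar(block) != b)
    stop("block must have exactly ", b, " residues", call. = FALSE)
  if (shuffle) block <- shuffle_block(block)
  half <- b %/% 2L
  mid <- n %/% 2L
  widened <- paste0(substr(sequence, 1L, mid), block,
                    substr(sequence, mid + 1L, n))
  list(sequence = substr(widened, half + 1L, nchar(widened) - half),
       block = block)
}

#' Dual acceptance rule for a candidate sequence
#'
#' A candidate is kept only if its smoothed disorder profile is flat enough
#' (`delta <= 0.15`) and accurate enough (`|Dt - mean| <= 0.025`), both
#' bounds inclusive and evaluated over the entire sequence.
#'
#' @param profile Per-residue scores of the whole candidate sequence.
#' @param dt Target disorder probability.
#' @param params [design_params()].
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
accept_sequence <- function(profile, dt, params = design_params()) {
  st <- profile_stats(profile)
  # inclusive bounds, robust to floating-point rounding at the boundary
  st$delta <= params$delta_threshold + BOUNDARY_EPS &&
    abs(dt - st$mean) <= params$mean_threshold + BOUNDARY_EPS
}

#' Trim an assembled sequence to the requested length
#'
#' Removes `l_r - l` residues one at a time. At each step the two terminal
#' residues' scores (read from the frozen profile of the accepted
#' length-`l_r` sequence) are compared and the residue whose score deviates
#' more from the target is removed; ties trim the N-terminus.
#'
#' @param sequence Accepted sequence of length `l_r`.
#' @param profile Its disorder profile (not re-scored during trimming).
#' @param l Requested final length, `l <= l_r < l + 10`.
#' @param dt Target disorder probability.
#' @return The length-`l` sequence.
#' @export
trim_to_length <- function(sequence, profile, l, dt) {
  n <- nchar(sequence)
  stopifnot(length(profile) == n, l <= n)
  from <- 1L; to <- n
  while (to - from + 1L > l) {
    if (abs(profile[to] - dt) > abs(profile[from] - dt))
      to <- to - 1L
    else
      from <- from + 1L  # ties and larger N-terminal deviation trim N-term
  }
  substr(sequence, from, to)
}

#' Design one artificial disordered sequence
#'
#' Runs the full assembly procedure for a requested length `l` and target
#' disorder probability `dt`: (1) round `l` up to `l_r`; (2) initialize by
#' tandem-repeating one shuffled family block `i = l_r/10` times; (3) perform
#' `j = i - 1` central insertions of shuffled same-family blocks, re-scoring
#' the entire sequence after each insertion and accepting it only under the
#' dual rule ([accept_sequence()]); a candidate failing the rule is discarded
#' and another block drawn, up to `max_rejections_per_insertion` (200) times,
#' after which the whole sequence is discarded and assembly restarts from a
#' fresh initial block; (4) trim to length `l` ([trim_to_length()]).
#'
#' @param l Requested length (50-200).
#' @param dt Target disorder probability (grid member).
#' @param library Completed block library.
#' @param model Scorer.
#' @param params [design_params()].
#' @param seed Optional integer seed (set for a reproducible design).
#' @param rank Rank of this design within its request (used in the name).
#' @return An object of class `designed_sequence`: `sequence` (length `l`),
#'   `requested_dt`, `achieved_mean` and `achieved_delta` (evaluated at
#'   length `l_r`, where the acceptance rule is guaranteed), `final_mean` and
#'   `final_delta` (re-checked after trimming, logged but not enforced),
#'   `name`, and `provenance` (seed, initial and inserted shuffled blocks,
#'   per-insertion rejection counts, discarded-sequence count).
#' @export
design_sequence <- function(l, dt, library, model = disorder_model(),
                            params = design_params(), seed = NULL,
                            rank = 1L) {
  if (!is.null(seed)) set.seed(seed)
  dt <- check_dt(dt, params)
  l <- as.integer(l)
  l_r <- round_length(l, params)
  j <- l_r %/% params$block_size - 1L
  discarded <- 0L
  repeat {
    init <- init_sequence(dt, l_r, library, params, strategy = "repeat")
    sequence <- init$sequence
    inserted <- character(0)
    rejections <- integer(0)
    aborted <- FALSE
    for (step in seq_len(j)) {
      rej <- 0L
      repeat {
        cand <- central_insert(sequence, draw_block(library, dt), params,
                               shuffle = TRUE)
        if (accept_sequence(score_profile(cand$sequence, model), dt,
                            params)) {
          sequence <- cand$sequence
          inserted <- c(inserted, cand$block)
          rejections <- c(rejections, rej)
          break
        }
        rej <- rej + 1L
        if (rej >= params$max_rejections_per_insertion) {
          aborted <- TRUE
          break
        }
      }
      if (aborted) break
    }
    if (!aborted) break
    discarded <- discarded + 1L
    if (discarded > params$max_restarts)
      stop("design failed: ", discarded, " whole sequences discarded ",
           "(limit ", params$max_restarts, ") for l = ", l, ", dt = ",
           dt_label(dt), call. = FALSE)
  }
  profile <- score_profile(sequence, model)
  st <- profile_stats(profile)
  final <- trim_to_length(sequence, profile, l, dt)
  fst <- profile_stats(score_profile(final, model))
  structure(
    list(sequence = final,
         requested_dt = dt,
         achieved_mean = st$mean,
         achieved_delta = st$delta,
         final_mean = fst$mean,
         final_delta = fst$delta,
         name = name_sequence(l, st$mean, rank),
         provenance = list(seed = seed, l = l, l_r = l_r, dt = dt,
                           init_block = init$blocks,
                           inserted_blocks = inserted,
                           rejections = rejections,
                           discarded = discarded)),
    class = "designed_sequence")
}

#' @export
print.designed_sequence <- function(x, ...) {
  cat(">", x$name, "\n", sep = "")
  cat(x$sequence, "\n")
  cat(sprintf("mean %.3f  delta %.3f  (at l_r; after trim: %.3f / %.3f)\n",
              x$achieved_mean, x$achieved_delta, x$final_mean,
              x$final_delta))
  invisible(x)
}

# per-design seed: documented counter scheme off the master seed
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 10007 * k) %% .Machine$integer.max)
}

#' Design a batch of artificial disordered sequences
#'
#' Runs [design_sequence()] `n` times (1-10 designs per request). Each design
#' gets its own seed, derived deterministically from the master seed by a
#' counter scheme (`master + 10007 * rank`, reduced modulo the integer
#' range), so batches are reproducible and designs independent. Names carry
#' the rank in generation order.
#'
#' @param n Number of sequences (within `params$n_min..n_max`).
#' @param l,dt,library,model,params As in [design_sequence()].
#' @param seed Master integer seed for the batch.
#' @param add_tryptophan Append a single W to each final sequence (handy for
#'   A280 quantification of an expressed construct); off by default.
#' @return List of `designed_sequence` objects, ranks 1..n.
#' @export
design_batch <- function(n, l, dt, library, model = disorder_model(),
                         params = design_params(), seed = 1L,
                         add_tryptophan = FALSE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < params$n_min || n > params$n_max)
    stop("number of sequences must lie between ", params$n_min, " and ",
         params$n_max, call. = FALSE)
  designs <- lapply(seq_len(n), function(k)
    design_sequence(l, dt, library, model, params,
                    seed = derive_seed(seed, k), rank = k))
  if (add_tryptophan)
    designs <- lapply(designs, function(d) {
      d$sequence <- paste0(d$sequence, "W")
      d
    })
  designs
}

#' Replay a design from its provenance, without random numbers
#'
#' Re-executes the recorded block choices: tandem-repeats the stored initial
#' (already shuffled) block, applies the stored inserted blocks with
#' shuffling disabled, and repeats the deterministic trim. The result must
#' equal the recorded sequence; this verifies that a design is fully
#' determined by its provenance.
#'
#' @param design A `designed_sequence`.
#' @param model Scorer used for the original design (needed for the trim).
#' @param params [design_params()].
#' @return The reconstructed sequence string.
#' @export
replay_design <- function(design, model = disorder_model(),
                          params = design_params()) {
  p <- design$provenance
  sequence <- strrep(p$init_block, p$l_r %/% params$block_size)
  for (blk in p$inserted_blocks)
    sequence <- central_insert(sequence, blk, params,
                               shuffle = FALSE)$sequence
  trim_to_length(sequence, score_profile(sequence, model), p$l, p$dt)
}
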