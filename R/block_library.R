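#' Propose a random building block
#'
#' Draws `block_size` residues uniformly, with replacement, from the
#' 18-letter alphabet (the 20 standard residues minus W and C). Uses R's
#' global random number generator; seed upstream with [set.seed()] for
#' reproducibility.
#'
#' @param block_size Block length in residues (default 10).
#' @return A single amino-acid string.
#' @export
propose_block <- function(block_size = 10L) {
  paste(sample(AA_BLOCK, block_size, replace = TRUE), collapse = "")
}

#' Evaluate a candidate block and assign it to a target-score family
#'
#' Scores the block in its tandem-repeat context
#' ([score_block_in_context()]) and applies the filing rules: the block is
#' rejected if its score range delta exceeds `params$delta_threshold`
#' (profile not smooth enough), or if its mean score is farther than
#' `params$mean_threshold` from the nearest grid value (so family labels stay
#' meaningful). Otherwise it is assigned to the family with the closest
#' target disorder probability; a mean exactly equidistant between two grid
#' values goes to the lower one.
#'
#' @param block Candidate block string.
#' @param model Scorer (see [score_profile()]).
#' @param params [design_params()].
#' @return A list with `accepted` (logical), `sequence`, `mean`, `delta`,
#'   and, when accepted, `family` (the assigned grid value); when rejected,
#'   `reason` is one of `"delta"` or `"mean"`.
#' @export
evaluate_block <- function(block, model = disorder_model(),
                           params = design_params()) {
  st <- score_block_in_context(block, model,
                               repeats = params$repeat_count,
                               block_size = params$block_size)
  if (st$delta > params$delta_threshold + BOUNDARY_EPS)
    return(list(accepted = FALSE, sequence = block,
                mean = st$mean, delta = st$delta, reason = "delta"))
  fam <- nearest_dt(st$mean, params$dt_grid)
  if (abs(fam - st$mean) > params$mean_threshold + BOUNDARY_EPS)
    return(list(accepted = FALSE, sequence = block,
                mean = st$mean, delta = st$delta, reason = "mean"))
  list(accepted = TRUE, sequence = block,
       mean = st$mean, delta = st$delta, family = fam)
}

#' Build the building-block library
#'
#' Rejection-samples random 10-mers until every family of the target-score
#' grid holds `params$blocks_per_family` accepted blocks (50 by default, over
#' the nine families 0.55-0.95). Families fill independently; an accepted
#' block whose family is already full is discarded. Construction is a pure
#' function of `(seed, model, params)`.
#'
#' @param model Scorer.
#' @param params [design_params()].
#' @param seed Integer seed for the proposal stream.
#' @return An object of class `block_library`: a list with `grid`, `families`
#'   (one data.frame per family: `sequence`, `mean`, `delta`), `seed`, and a
#'   `tally` of proposal/rejection counts.
#' @examples
#' \donttest{
#' lib <- build_block_library(disorder_model(), seed = 1)
#' sapply(lib$families, nrow)   # 50 blocks in each of the nine families
#' }
#' @export
build_block_library <- function(model = disorder_model(),
                                params = design_params(),
                                seed = 1L) {
  set.seed(seed)
  grid <- params$dt_grid
  target <- params$blocks_per_family
  fams <- stats::setNames(
    rep(list(list(sequence = character(), mean = numeric(),
                  delta = numeric())), length(grid)),
    dt_label(grid))
  fill <- integer(length(grid))
  tally <- c(proposals = 0L, rejected_delta = 0L, rejected_mean = 0L,
             discarded_full = 0L)
  while (any(fill < target)) {
    if (tally[["proposals"]] >= params$max_proposals) {
      short <- dt_label(grid[fill < target])
      stop("proposal cap (", format(params$max_proposals, scientific = FALSE),
           ") reached with incomplete families: ",
           paste(short, collapse = ", "), call. = FALSE)
    }
    tally[["proposals"]] <- tally[["proposals"]] + 1L
    ev <- evaluate_block(propose_block(params$block_size), model, params)
    if (!ev$accepted) {
      key <- paste0("rejected_", ev$reason)
      tally[[key]] <- tally[[key]] + 1L
      next
    }
    fi <- which(abs(grid - ev$family) < 1e-9)
    if (fill[fi] >= target) {
      tally[["discarded_full"]] <- tally[["discarded_full"]] + 1L
      next
    }
    fams[[fi]]$sequence <- c(fams[[fi]]$sequence, ev$sequence)
    fams[[fi]]$mean <- c(fams[[fi]]$mean, ev$mean)
    fams[[fi]]$delta <- c(fams[[fi]]$delta, ev$delta)
    fill[fi] <- fill[fi] + 1L
  }
  families <- lapply(fams, function(f)
    data.frame(sequence = f$sequence, mean = f$mean, delta = f$delta,
               stringsAsFactors = FALSE))
  structure(list(grid = grid, families = families,
                 seed = as.integer(seed), tally = tally),
            class = "block_library")
}

#' @export
print.block_library <- function(x, ...) {
  cat("Building-block library:", length(x$families), "families\n")
  sizes <- vapply(x$families, nrow, integer(1))
  cat("  blocks per family:", paste(sizes, collapse = " "), "\n")
  cat("  seed:", x$seed, "| proposals:", x$tally[["proposals"]], "\n")
  invisible(x)
}

#' Acceptance fraction as a function of the smoothness threshold
#'
#' Proposes `n_proposals` random blocks, records each one's score range
#' (delta) and nearest family, and tabulates, for every (family, threshold)
#' pair, the fraction of that family's proposals whose delta does not exceed
#' the threshold. Acceptance is monotone non-decreasing in the threshold by
#' construction; the sweep quantifies how a stricter smoothness requirement
#' trades acceptance rate against profile flatness.
#'
#' @param model Scorer.
#' @param thresholds Positive numeric vector of candidate delta thresholds.
#' @param n_proposals Number of random blocks to propose.
#' @param params [design_params()].
#' @param seed Integer seed.
#' @return A list of class `delta_sweep`: `table` (data.frame with `family`,
#'   `threshold`, `accepted_fraction`, `n`) and `proposals` (the raw
#'   per-proposal log: `sequence`, `mean`, `delta`, `family`).
#' @export
sweep_delta_threshold <- function(model = disorder_model(),
                                  thresholds = c(0.10, 0.15, 0.20),
                                  n_proposals = 2000L,
                                  params = design_params(),
                                  seed = 1L) {
  stopifnot(all(thresholds > 0), n_proposals >= 1L)
  set.seed(seed)
  blocks <- vapply(seq_len(n_proposals),
                   function(i) propose_block(params$block_size), character(1))
  st <- lapply(blocks, score_block_in_context, model = model,
               repeats = params$repeat_count, block_size = params$block_size)
  means <- vapply(st, `[[`, numeric(1), "mean")
  deltas <- vapply(st, `[[`, numeric(1), "delta")
  fams <- vapply(means, nearest_dt, numeric(1), grid = params$dt_grid)
  proposals <- data.frame(sequence = blocks, mean = means, delta = deltas,
                          family = fams, stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(params$dt_grid, function(dt) {
    in_fam <- abs(fams - dt) < 1e-9
    do.call(rbind, lapply(sort(thresholds), function(th) {
      data.frame(family = dt, threshold = th,
                 accepted_fraction = if (any(in_fam))
                   mean(deltas[in_fam] <= th) else NA_real_,
                 n = sum(in_fam))
    }))
  }))
  structure(list(table = tab, proposals = proposals), class = "delta_sweep")
}

#' Residue-usage frequencies of a completed library
#'
#' Counts how often each of the 18 building-block residues occurs in every
#' family and normalizes to frequencies. Columns follow the TOP-IDP order of
#' increasing disorder propensity (F most order-promoting, P most
#' disorder-promoting among the 18).
#'
#' @param library A completed [build_block_library()] result.
#' @return Numeric matrix, one row per family, one column per residue
#'   (TOP-IDP order); each row sums to 1.
#' @export
residue_usage <- function(library) {
  stopifnot(inherits(library, "block_library"))
  freq <- t(vapply(library$families, function(f) {
    letters <- unlist(strsplit(paste(f$sequence, collapse = ""), "",
                               fixed = TRUE))
    counts <- table(factor(letters, levels = AA_BLOCK_BY_DISORDER))
    as.numeric(counts) / length(letters)
  }, numeric(length(AA_BLOCK_BY_DISORDER))))
  colnames(freq) <- AA_BLOCK_BY_DISORDER
  rownames(freq) <- names(library$families)
  freq
}

#' Write / read a building-block library
#'
#' The library is stored as FASTA (one record per block, header encoding the
#' family and the block's mean and delta, e.g.
#' `bb0001|family=0.70|mean=0.70341|delta=0.00823`) together with a YAML
#' sidecar (`<path>.yml`) recording the construction seed, the tally, and the
#' scorer parameters. `read_block_library()` re-validates every invariant
#' (block length, 18-letter alphabet, delta threshold, family membership)
#' and errors on violation.
#'
#' @param library A `block_library`.
#' @param path FASTA output path; the sidecar is written next to it.
#' @param model Scorer whose parameters are recorded in the sidecar.
#' @param params [design_params()] used for validation on read.
#' @export
write_block_library <- function(library, path, model = NULL) {
  stopifnot(inherits(library, "block_library"))
  recs <- unlist(lapply(names(library$families), function(lab) {
    f <- library$families[[lab]]
    if (nrow(f) == 0L) return(character())
    stats::setNames(f$sequence, sprintf(
      "bb%04d|family=%s|mean=%.17g|delta=%.17g",
      seq_len(nrow(f)), lab, f$mean, f$delta))
  }))
  aas <- Biostrings::AAStringSet(recs)
  Biostrings::writeXStringSet(aas, path, width = 60L)
  meta <- list(grid = as.numeric(library$grid), seed = library$seed,
               tally = as.list(library$tally))
  if (!is.null(model) && inherits(model, "disorder_model"))
    meta$scorer <- list(
      neighborhood_min = model$neighborhood_min,
      neighborhood_max = model$neighborhood_max,
      smoothing_window = model$smoothing_window,
      transform_midpoint = model$transform_midpoint,
      transform_slope = model$transform_slope)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_block_library
#' @return `read_block_library` returns the restored `block_library`.
#' @export
read_block_library <- function(path, params = design_params()) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  fields <- strsplit(names(aas), "|", fixed = TRUE)
  get_num <- function(f, key) {
    hit <- grep(paste0("^", key, "="), f, value = TRUE)
    if (length(hit) != 1L)
      stop("malformed library header: missing ", key, call. = FALSE)
    as.numeric(sub(paste0("^", key, "="), "", hit))
  }
  fam <- vapply(fields, get_num, numeric(1), key = "family")
  mean_s <- vapply(fields, get_num, numeric(1), key = "mean")
  delta <- vapply(fields, get_num, numeric(1), key = "delta")

  meta_path <- paste0(path, ".yml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  grid <- if (!is.null(meta$grid)) as.numeric(meta$grid) else params$dt_grid

  for (i in seq_along(seqs)) {
    aa <- aa_chars(seqs[i], AA_STANDARD, "block")
    if (length(aa) != params$block_size)
      stop("block ", i, " has length ", length(aa), call. = FALSE)
    if (any(aa %in% c("W", "C")))
      stop("block ", i, " contains W or C", call. = FALSE)
    if (delta[i] > params$delta_threshold)
      stop("block ", i, " violates the delta threshold", call. = FALSE)
    if (!any(abs(grid - fam[i]) < 1e-9))
      stop("block ", i, " has family ", fam[i], " outside the grid",
           call. = FALSE)
  }
  families <- stats::setNames(lapply(grid, function(dt) {
    sel <- abs(fam - dt) < 1e-9
    data.frame(sequence = unname(seqs[sel]), mean = mean_s[sel],
               delta = delta[sel], stringsAsFactors = FALSE)
  }), dt_label(grid))
  structure(list(grid = grid, families = families,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed)
                        else NA_integer_,
                 tally = if (!is.null(meta$tally)) unlist(meta$tally)
                         else NULL),
            class = "block_library")
}
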