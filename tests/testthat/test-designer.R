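test_that("requested lengths round up to the next multiple of ten", {
  expect_equal(round_length(100), 100L)
  expect_equal(round_length(101), 110L)
  for (l in 50:200) {
    lr <- round_length(l)
    expect_true(l <= lr && lr < l + 10 && lr %% 10 == 0)
  }
  expect_error(round_length(49), "50")
  expect_error(round_length(201), "200")
})

test_that("repeat initialization tandem-repeats one shuffled family block", {
  set.seed(21)
  init <- init_sequence(0.70, 50L, fixture_library)
  expect_equal(nchar(init$sequence), 50L)
  expect_length(init$blocks, 1L)
  # five exact copies of the shuffled block
  expect_equal(init$sequence, strrep(init$blocks, 5))
  # shuffling preserves composition: residue multiset = 5x block multiset
  seq_tab <- table(strsplit(init$sequence, "")[[1L]])
  blk_tab <- table(strsplit(init$blocks, "")[[1L]])
  expect_equal(seq_tab, blk_tab * 5L, ignore_attr = TRUE)
  # the shuffled block keeps the composition of some family member
  fam <- fixture_library$families[["0.70"]]
  canon <- function(s) paste(sort(strsplit(s, "")[[1L]]), collapse = "")
  expect_true(canon(init$blocks) %in% vapply(fam$sequence, canon, ""))
  # determinism
  set.seed(33); a <- init_sequence(0.60, 100L, fixture_library)
  set.seed(33); b <- init_sequence(0.60, 100L, fixture_library)
  expect_identical(a, b)
  expect_error(init_sequence(0.70, 55L, fixture_library), "multiple")
  expect_error(init_sequence(0.72, 50L, fixture_library), "grid")
})

test_that("central insertion preserves length and does honest bookkeeping", {
  # hand-executed example: insert D-block into the middle of an A-sequence
  out <- central_insert(strrep("A", 20), strrep("D", 10), shuffle = FALSE)
  expect_equal(out$sequence, paste0(strrep("A", 5), strrep("D", 10),
                                    strrep("A", 5)))
  set.seed(4)
  for (rep in 1:10) {
    L <- 10L * sample(2:20, 1L)
    s <- random_sequence(L)
    b <- random_sequence(10L)
    out <- central_insert(s, b)
    expect_equal(nchar(out$sequence), L)
    # multiset: input - 5 leading - 5 trailing + inserted block
    expected <- c(strsplit(substr(s, 6, L - 5), "")[[1L]],
                  strsplit(out$block, "")[[1L]])
    expect_equal(sort(strsplit(out$sequence, "")[[1L]]), sort(expected))
  }
  expect_error(central_insert("ACDEF", strrep("A", 10)), "multiple")
  expect_error(central_insert(strrep("A", 20), "ACD"), "10")
})

test_that("the dual acceptance rule is boundary-inclusive", {
  params <- fixture_params
  # at the smoothness boundary, accurate mean
  expect_true(accept_sequence(c(0.575, 0.575 + 0.15), 0.65, params))
  # just over the smoothness boundary
  expect_false(accept_sequence(rep(c(0.5, 0.651), 5), 0.575, params))
  # at the accuracy boundary, flat profile
  expect_true(accept_sequence(rep(0.575, 10), 0.60, params))
  # just over the accuracy boundary
  expect_false(accept_sequence(rep(0.574, 10), 0.60, params))
})

test_that("trimming removes residues from the worse-scoring extremity", {
  s <- "ACDE"
  # C-terminal score deviates more: trim the C-terminus
  expect_equal(trim_to_length(s, c(0.58, 0.6, 0.6, 0.70), 3L, 0.60), "ACD")
  # N-terminal deviates more
  expect_equal(trim_to_length(s, c(0.70, 0.6, 0.6, 0.58), 3L, 0.60), "CDE")
  # tie: trim the N-terminus
  expect_equal(trim_to_length(s, c(0.65, 0.6, 0.6, 0.65), 3L, 0.60), "CDE")
  # identity when already at length
  expect_equal(trim_to_length(s, rep(0.6, 4), 4L, 0.60), s)
  # greedy over several removals follows the frozen profile
  expect_equal(trim_to_length("ACDEF", c(0.61, 0.6, 0.6, 0.6, 0.70), 3L, 0.60),
               "CDE")
})

test_that("a design runs j insertions, is reproducible, and replays", {
  d <- design_sequence(50L, 0.70, fixture_library, fixture_model, seed = 17L)
  expect_s3_class(d, "designed_sequence")
  expect_equal(nchar(d$sequence), 50L)
  expect_length(d$provenance$inserted_blocks, 4L)  # j = 50/10 - 1
  expect_length(d$provenance$rejections, 4L)
  d2 <- design_sequence(50L, 0.70, fixture_library, fixture_model, seed = 17L)
  expect_identical(d2$sequence, d$sequence)
  expect_identical(d2$provenance, d$provenance)
  # provenance replay without RNG reproduces the sequence
  expect_identical(replay_design(d, fixture_model), d$sequence)
  # the gate held at assembly length
  expect_lte(d$achieved_delta, 0.15)
  expect_lte(abs(0.70 - d$achieved_mean), 0.025)
})

test_that("an insertion step gives up after exactly the rejection cap", {
  calls <- 0L
  always_fail <- function(sequence) {
    calls <<- calls + 1L
    rep(0.05, nchar(sequence))  # mean criterion can never hold
  }
  params <- design_params(max_restarts = 1L)
  expect_error(
    design_sequence(50L, 0.70, fixture_library, always_fail, params,
                    seed = 1L),
    "discarded")
  # two whole-sequence attempts, each aborted after exactly 200 candidates
  expect_equal(calls, 400L)
})

test_that("batches carry ranks, enforce bounds, and derive per-design seeds", {
  batch <- design_batch(3L, 62L, 0.80, fixture_library, fixture_model,
                        seed = 99L)
  expect_length(batch, 3L)
  ranks <- vapply(batch, function(d) parse_sequence_name(d$name)$rank,
                  integer(1))
  expect_equal(ranks, 1:3)
  expect_true(all(vapply(batch, function(d) nchar(d$sequence), integer(1))
                  == 62L))
  # ranks beyond the first reproduce individually from the derived seed
  d2 <- design_sequence(62L, 0.80, fixture_library, fixture_model,
                        seed = (99 + 10007 * 2) %% .Machine$integer.max,
                        rank = 2L)
  expect_identical(d2$sequence, batch[[2L]]$sequence)
  expect_error(design_batch(0L, 62L, 0.80, fixture_library, fixture_model),
               "between")
  expect_error(design_batch(11L, 62L, 0.80, fixture_library, fixture_model),
               "between")
  # optional tryptophan for A280 quantification
  w <- design_batch(1L, 50L, 0.80, fixture_library, fixture_model,
                    seed = 1L, add_tryptophan = TRUE)
  expect_equal(nchar(w[[1L]]$sequence), 51L)
  expect_equal(substr(w[[1L]]$sequence, 51, 51), "W")
})

test_that("designed sequences draw on several distinct source blocks", {
  d <- design_sequence(100L, 0.75, fixture_library, fixture_model,
                       seed = 23L)
  canon <- function(s) paste(sort(strsplit(s, "")[[1L]]), collapse = "")
  sources <- unique(vapply(c(d$provenance$init_block,
                             d$provenance$inserted_blocks), canon, ""))
  expect_gte(length(sources), 3L)
})
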