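test_that("proposed blocks are uniform draws from the 18-letter alphabet", {
  set.seed(202)
  blocks <- replicate(10000, propose_block())
  letters <- unlist(strsplit(blocks, "", fixed = TRUE))
  expect_false(any(letters %in% c("W", "C")))
  expect_setequal(unique(letters), AA_BLOCK)
  # each residue frequency within 3 sigma of 1/18 (binomial)
  n <- length(letters)
  p <- 1 / 18
  sigma <- sqrt(p * (1 - p) / n)
  freq <- table(factor(letters, levels = AA_BLOCK)) / n
  expect_true(all(abs(freq - p) <= 3 * sigma))
  # seeded determinism
  set.seed(9); a <- propose_block()
  set.seed(9); b <- propose_block()
  expect_identical(a, b)
})

test_that("block filing follows the smoothness and nearest-family rules", {
  # constant-profile stubs pin the (mean, delta) seen by the filing logic
  ev <- evaluate_block(strrep("A", 10), constant_scorer(0.71))
  expect_true(ev$accepted)
  expect_equal(ev$family, 0.70)

  # delta above threshold: alternating profile with range 0.16
  wavy <- function(sequence) rep(c(0.60, 0.76), length.out = nchar(sequence))
  ev <- evaluate_block(strrep("A", 10), wavy)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "delta")

  # equidistant mean between 0.70 and 0.75 files to the lower family
  ev <- evaluate_block(strrep("A", 10), constant_scorer(0.725))
  expect_true(ev$accepted)
  expect_equal(ev$family, 0.70)

  # mean far outside the grid is rejected even with a flat profile
  ev <- evaluate_block(strrep("A", 10), constant_scorer(0.40))
  expect_false(ev$accepted)
  expect_equal(ev$reason, "mean")
})

test_that("a completed library has nine full families of valid blocks", {
  lib <- fixture_library
  expect_length(lib$families, 9L)
  sizes <- vapply(lib$families, nrow, integer(1))
  expect_equal(min(sizes), 50L)
  expect_equal(max(sizes), 50L)
  for (lab in names(lib$families)) {
    f <- lib$families[[lab]]
    expect_true(all(nchar(f$sequence) == 10L))
    letters <- unlist(strsplit(f$sequence, "", fixed = TRUE))
    expect_true(all(letters %in% AA_BLOCK))
    expect_true(all(f$delta <= fixture_params$delta_threshold))
    expect_true(all(abs(as.numeric(lab) - f$mean) <=
                      fixture_params$mean_threshold))
  }
})

test_that("library construction is a pure function of the seed", {
  lib2 <- build_block_library(fixture_model, fixture_params, seed = 101L)
  expect_equal(lib2, fixture_library)
})

test_that("acceptance fraction grows monotonically with the delta threshold", {
  sw <- sweep_delta_threshold(fixture_model,
                              thresholds = c(0.10, 0.15, 0.20),
                              n_proposals = 600L, seed = 5L)
  # vacuous threshold accepts everything
  inf <- sweep_delta_threshold(fixture_model, thresholds = Inf,
                               n_proposals = 100L, seed = 5L)
  expect_true(all(inf$table$accepted_fraction[!is.na(inf$table$accepted_fraction)] == 1))
  for (dt in unique(sw$table$family)) {
    sub <- sw$table[sw$table$family == dt, ]
    sub <- sub[order(sub$threshold), ]
    fr <- sub$accepted_fraction[!is.na(sub$accepted_fraction)]
    expect_true(all(diff(fr) >= 0))
  }
  # recount oracle from the raw per-proposal log
  for (r in seq_len(nrow(sw$table))) {
    row <- sw$table[r, ]
    sel <- abs(sw$proposals$family - row$family) < 1e-9
    expect_equal(row$n, sum(sel))
    if (row$n > 0)
      expect_equal(row$accepted_fraction,
                   mean(sw$proposals$delta[sel] <= row$threshold))
  }
})

test_that("residue usage is a normalized recount of the family sequences", {
  usage <- residue_usage(fixture_library)
  expect_equal(dim(usage), c(9L, 18L))
  expect_equal(unname(rowSums(usage)), rep(1, 9), tolerance = 1e-12)
  expect_false(any(c("W", "C") %in% colnames(usage)))
  # counting oracle on one family
  lab <- "0.75"
  letters <- unlist(strsplit(fixture_library$families[[lab]]$sequence, "",
                             fixed = TRUE))
  for (aa in colnames(usage))
    expect_equal(usage[lab, aa], sum(letters == aa) / length(letters))
})

test_that("library serialization round-trips and is validated on read", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_block_library(fixture_library, path, fixture_model)
  back <- read_block_library(path)
  expect_equal(back$grid, fixture_library$grid)
  expect_equal(back$families, fixture_library$families)
  expect_equal(back$seed, fixture_library$seed)

  # a tampered record (delta over threshold) must be refused
  lines <- readLines(path)
  lines[1] <- sub("delta=[0-9.e-]+", "delta=0.9", lines[1])
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(lines, bad)
  expect_error(read_block_library(bad), "delta")
})
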