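test_that("seed shapes validate their mask", {
  sh <- seed_shape("1101011")
  expect_equal(sh$weight, 5L)
  expect_equal(sh$span, 7L)
  expect_error(seed_shape("0111"), "care position")
  expect_error(seed_shape("1110"), "care position")
})

test_that("seed enumeration yields one key per window from care positions", {
  sh <- seed_shape("11111")
  s <- random_aa(60)
  seeds <- enumerate_seeds(s, sh)
  expect_equal(nrow(seeds), 60 - 5 + 1)
  expect_equal(seeds$pos, 1:56)
  expect_equal(nrow(enumerate_seeds(random_aa(4), sh)), 0L)

  # care-position extraction: spaced key equals the contiguous key of the
  # extracted residues
  spaced <- enumerate_seeds("ACDE", seed_shape("1101"))
  packed <- enumerate_seeds("ACE", seed_shape("111"))
  expect_equal(spaced$key, packed$key)

  # shared exact substring implies at least one shared key
  core <- random_aa(12)
  a <- paste0(random_aa(20), core, random_aa(7))
  b <- paste0(random_aa(5), core, random_aa(30))
  sh7 <- seed_shape("1111111")
  expect_gt(length(intersect(enumerate_seeds(a, sh7)$key,
                             enumerate_seeds(b, sh7)$key)), 0)
})

test_that("minimizer sampling matches a brute-force window scan", {
  sh <- seed_shape("1101011")
  w <- 12L
  set.seed(5)
  for (k in 1:10) {
    s <- random_aa(300)
    keys <- enumerate_seeds(s, sh)
    got <- sample_minimizers(s, sh, w)
    # oracle: leftmost minimum of every window of w consecutive positions
    picks <- integer()
    for (st in 1:(nrow(keys) - w + 1)) {
      win <- keys$key[st:(st + w - 1)]
      picks <- c(picks, st + which.min(win) - 1L)
    }
    picks <- unique(picks)
    expect_equal(got$pos, keys$pos[picks])
    expect_equal(got$key, keys$key[picks])
  }
})

test_that("minimizer edge cases: homopolymers, degenerate and short inputs", {
  sh <- seed_shape("11111")
  homo <- strrep("A", 100)
  mz <- sample_minimizers(homo, sh, 12)
  expect_equal(length(unique(mz$key)), 1L)
  expect_equal(mz$pos[1], 1L)  # leftmost tie-break in every window
  expect_true(all(diff(mz$pos) > 0))

  exact <- random_aa(5)
  mz2 <- sample_minimizers(exact, sh, 12)
  expect_equal(nrow(mz2), 1L)
  expect_equal(mz2$pos, 1L)

  # shorter than span + w - 1 but >= span: the single minimal seed
  short <- random_aa(10)
  mz3 <- sample_minimizers(short, sh, 12)
  expect_equal(nrow(mz3), 1L)
  expect_equal(mz3$key, min(enumerate_seeds(short, sh)$key))

  expect_equal(nrow(sample_minimizers(random_aa(3), sh, 12)), 0L)

  # subset property and determinism
  s <- random_aa(200)
  expect_true(all(sample_minimizers(s, sh)$key %in% enumerate_seeds(s, sh)$key))
  expect_identical(sample_minimizers(s, sh), sample_minimizers(s, sh))
})

test_that("shape hits require a gap-free window matching all care positions", {
  s <- random_aa(30)
  self_aln <- list(qaln = s, taln = s)
  expect_true(shape_hits_alignment(seed_shape("1101011"), self_aln))

  gappy <- list(qaln = "MKTV-AK-LE-QW-MT", taln = "MKTVWAKQLEFQWRMT")
  expect_false(shape_hits_alignment(seed_shape("11111"), gappy))

  # exhaustive offset oracle on random alignments
  set.seed(9)
  shapes <- list(seed_shape("1111"), seed_shape("11011"), seed_shape("101011"))
  for (k in 1:20) {
    codes <- sample(c(0L, 1L, 1L, 2L), 40, replace = TRUE)
    for (sh in shapes) {
      oracle <- FALSE
      for (o in 1:(40 - sh$span + 1)) {
        win <- codes[o:(o + sh$span - 1)]
        if (all(win != 2L) && all(win[sh$pattern] == 1L)) oracle <- TRUE
      }
      expect_identical(shape_hits_alignment(sh, codes), oracle)
    }
  }
})

test_that("shape learning greedily covers the alignment collection", {
  # collection hit only by the contiguous shape: a single 4-match block in a
  # sea of mismatches, so every spaced weight-4 window covers a mismatch
  mk <- function() c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  res <- learn_shapes(replicate(10, mk(), simplify = FALSE),
                      weight = 4, max_span = 5, count = 30)
  expect_equal(res$shapes[[1]]$string, "1111")

  # early stop: collection fully covered by fewer shapes than requested
  aln <- simulate_alignment_collection(50, identity = c(0.85, 0.95), seed = 2)
  res2 <- learn_shapes(aln, weight = 4, max_span = 7, count = 30)
  expect_lt(length(res2$shapes), 30)
  expect_equal(sum(res2$hits), 50)  # everything covered

  # greedy progress: newly covered counts are positive, remaining decreases
  expect_true(all(res2$hits > 0))

  # learned shapes have the required weight and care ends
  aln3 <- simulate_alignment_collection(40, identity = c(0.5, 0.8), seed = 3)
  res3 <- learn_shapes(aln3, weight = 4, max_span = 7, count = 5)
  for (sh in res3$shapes) {
    expect_equal(sh$weight, 4L)
    expect_true(sh$pattern[1] && sh$pattern[sh$span])
  }

  expect_error(learn_shapes(aln3, weight = 8, max_span = 7), "exceeds")
  expect_error(learn_shapes(list(), weight = 4, max_span = 7), "empty")
})

test_that("first greedy pick matches exhaustive shape enumeration", {
  set.seed(13)
  aln <- simulate_alignment_collection(100, identity = c(0.55, 0.9),
                                       length = c(60, 120), seed = 13)
  codes <- lapply(aln, function(a) alignment_codes(a$qaln, a$taln))
  # independent exhaustive oracle over all weight-4 shapes of span <= 7
  best_hits <- -1L
  for (span in 4:7) {
    for (cmb in asplit(combn(span - 2, 2), 2)) {
      pat <- rep(FALSE, span); pat[c(1, span)] <- TRUE; pat[cmb + 1] <- TRUE
      if (sum(pat) != 4) next
      hits <- sum(vapply(codes, function(cd) {
        any(vapply(seq_len(length(cd) - span + 1), function(o) {
          win <- cd[o:(o + span - 1)]
          all(win != 2L) && all(win[pat] == 1L)
        }, logical(1)))
      }, logical(1)))
      if (hits > best_hits) best_hits <- hits
    }
  }
  res <- learn_shapes(aln, weight = 4, max_span = 7, count = 1)
  expect_equal(res$hits[1], best_hits)
})
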