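test_that("LZ76 conventions and hand-parsed words", {
  expect_identical(lz76Complexity(""), 0L)
  expect_identical(lz76Complexity(character(0)), 0L)
  expect_identical(lz76Complexity("A"), 1L)
  expect_identical(lz76Complexity("AAAA"), 2L) # A | AAA
  expect_identical(lz76Complexity("ABABABAB"), 3L) # A | B | ABABAB
  expect_identical(lz76Complexity(strrep("AB", 25)), 3L)
  # works on arbitrary alphabets
  expect_identical(lz76Complexity(c(5L, 5L, 5L, 5L)), 2L)
  expect_identical(lz76Complexity(factor(c("x", "y", "x", "y"))), 3L)
})

test_that("LZ76 agrees with the brute-force parser on random strings", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(2:40, 1)
    k <- sample(2:4, 1)
    s <- sample.int(k, n, replace = TRUE)
    expect_identical(lz76Complexity(s), lz76Oracle(s))
  }
})

test_that("LZ76 is non-decreasing under extension", {
  set.seed(24)
  for (i in 1:10) {
    s <- sample.int(3, 60, replace = TRUE)
    cs <- vapply(seq_along(s), function(j) lz76Complexity(s[seq_len(j)]), 0L)
    expect_true(all(diff(cs) >= 0))
  }
})

test_that("microstate LZC separates periodic from random transitioning", {
  periodic <- rep(1:4, 25)
  cPeriodic <- microstateLZC(periodic, collapseRuns = TRUE)
  set.seed(25)
  wins <- 0L
  for (i in 1:50) {
    r <- rle(sample.int(4, 200, replace = TRUE))$values[1:100]
    if (microstateLZC(r, collapseRuns = TRUE) > cPeriodic) wins <- wins + 1L
  }
  expect_gt(wins, 25) # majority over 50 seeds

  # relabeling classes by a permutation leaves C unchanged
  s <- rle(sample.int(4, 300, replace = TRUE))$values
  perm <- c(3L, 1L, 4L, 2L)
  expect_identical(microstateLZC(perm[s]), microstateLZC(s))
})

test_that("run collapsing and the degenerate single-class case", {
  s <- LabelSequence(c(1, 1, 2, 2, 2, 1, 1), fs = 100, k = 2)
  expect_equal(as.numeric(microstateLZC(s, collapseRuns = TRUE)),
               as.numeric(lz76Complexity(c(1L, 2L, 1L))))
  mono <- LabelSequence(rep(1L, 40), fs = 100, k = 2)
  C <- microstateLZC(mono, collapseRuns = TRUE)
  expect_equal(as.numeric(C), 1)
  expect_true(isTRUE(attr(C, "degenerate")))
})

test_that("normalized LZC of uniform random sequences is near 1", {
  set.seed(26)
  for (k in c(2, 4)) {
    s <- sample.int(k, 5000, replace = TRUE)
    cn <- microstateLZC(s, collapseRuns = FALSE, normalize = TRUE)
    expect_gt(as.numeric(cn), 0.7)
    expect_lt(as.numeric(cn), 1.3)
  }
})

test_that("AD-like cohorts (slower, more repetitive transitions) have lower C", {
  cyc <- matrix(0.05, 4, 4) # strongly cyclic 1->2->3->4->1
  diag(cyc) <- 0
  cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cHOA <- cAD <- numeric(10)
  for (i in 1:10) {
    hoa <- syntheticSpec(nChannels = 8, kTrue = 4, fs = 250, durationS = 20,
                         dwellMeanMs = 50, seed = 100 + i)
    ad <- syntheticSpec(nChannels = 8, kTrue = 4, fs = 250, durationS = 20,
                        dwellMeanMs = 90, transitionWeights = cyc,
                        seed = 200 + i)
    cHOA[i] <- microstateLZC(generateSequence(hoa))
    cAD[i] <- microstateLZC(generateSequence(ad))
  }
  expect_lt(median(cAD), median(cHOA))
})

test_that("time-series LZC behaves like the classical binarized measure", {
  n <- 512
  const <- EEGRecording(matrix(c(rep(1, n), rnorm(n)), 2, byrow = TRUE),
                        fs = 256)
  # constant channel binarizes to all zeros: word count 2
  perChannelConst <- 2 * log2(n) / n
  set.seed(27)
  sq <- EEGRecording(matrix(rep(sign(sin(2 * pi * (1:2048) / 100)), 3),
                            3, byrow = TRUE), fs = 256)
  noise <- whiteNoiseRecording(3, 2048, fs = 256, seed = 27)
  expect_lt(timeseriesLZC(sq), timeseriesLZC(noise))

  scaled <- EEGRecording(eegData(noise) * 10^(1:3), fs = 256)
  expect_equal(timeseriesLZC(scaled), timeseriesLZC(noise))

  both <- timeseriesLZC(const)
  expect_equal(both, (perChannelConst + lz76Complexity(
    as.integer(eegData(const)[2, ] > median(eegData(const)[2, ]))
  ) * log2(n) / n) / 2)
})

test_that("Omega-complexity counts independent spatial components", {
  maps <- generateMaps(10, 3, seed = 28)
  # rank 1: one map modulated in time
  rec1 <- mapDrivenRecording(maps, rep(1L, 500), sin(1:500 / 7))
  expect_lt(abs(omegaComplexity(rec1) - 1), 1e-6)

  # exactly two equal nonzero eigenvalues: quadrature pair over full periods
  t <- (0:999) / 1000
  z <- rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t), 0 * t, 0 * t)
  expect_lt(abs(omegaComplexity(EEGRecording(z, fs = 1000)) - 2), 1e-6)

  # i.i.d. equal-variance channels approach Omega = N
  big <- whiteNoiseRecording(10, 100000, fs = 1000, seed = 29)
  expect_gte(omegaComplexity(big), 8)

  expect_error(omegaComplexity(EEGRecording(matrix(0, 4, 100), fs = 100)),
    "rank-0"
  )
})

test_that("complexityProfile bundles all measures with finite values", {
  gt <- generateEEG(syntheticSpec(nChannels = 16, durationS = 5, seed = 30))
  model <- modifiedKMeans(
    t(eegData(gt$recording))[gfpCurve(gt$recording)$peaks, ], 4,
    nInit = 5, seed = 1
  )
  seq <- backfit(gt$recording, model)
  cx <- complexityProfile(gt$recording, seq)
  expect_true(all(is.finite(c(cx$C, cx$CNorm, cx$omega, cx$tsLZC))))
  expect_gte(cx$C, 1)
  expect_gte(cx$omega, 1)
  expect_lte(cx$omega, 16)
})
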