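test_that("GFP is the spatial standard deviation with its local maxima", {
  rec <- EEGRecording(matrix(c(1, -1), 2, 1), fs = 10)
  expect_equal(gfpCurve(rec)$gfp, 1)
  const <- EEGRecording(matrix(0, 4, 5), fs = 10)
  expect_equal(gfpCurve(const)$gfp, rep(0, 5))

  set.seed(1)
  rec <- averageReference(whiteNoiseRecording(8, 100, fs = 100, seed = 1))
  g1 <- gfpCurve(rec)
  neg <- EEGRecording(-eegData(rec), fs = 100)
  expect_equal(gfpCurve(neg)$gfp, g1$gfp)
  # peaks are strict interior local maxima
  gfp <- g1$gfp
  expect_true(all(gfp[g1$peaks] > gfp[g1$peaks - 1] &
                    gfp[g1$peaks] > gfp[g1$peaks + 1]))
})

test_that("a non-referenced recording triggers a warning and re-reference", {
  rec <- EEGRecording(matrix(rnorm(40) + 5, 4, 10), fs = 10)
  expect_warning(gfpCurve(rec), "re-referencing")
})

test_that("modified k-means exactly recovers orthogonal noise-free maps", {
  set.seed(2)
  k <- 4
  nch <- 16
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(nch * k), nch, k))))[, 2:(k + 1)]
  maps <- t(Q) # orthogonal, zero-mean, unit-norm
  amps <- rep(c(1.5, -2, 0.7, 3), 50)
  obs <- maps[rep(1:k, 50), ] * amps
  m <- modifiedKMeans(obs, k, nInit = 5, seed = 1)
  al <- alignModels(MicrostateModel(maps), m)
  expect_gt(min(al$alignedR), 1 - 1e-9)
  expect_gt(gev(m), 1 - 1e-9)
})

test_that("clustering is polarity invariant and seed-reproducible", {
  spec <- syntheticSpec(nChannels = 32, kTrue = 3, fs = 250, durationS = 8,
                        seed = 21)
  gt <- generateEEG(spec)
  obs <- t(eegData(gt$recording))[gfpCurve(gt$recording)$peaks, ]
  m1 <- modifiedKMeans(obs, 3, nInit = 10, seed = 7)
  m2 <- modifiedKMeans(-obs, 3, nInit = 10, seed = 7)
  al <- alignModels(m1, m2)
  expect_gt(min(al$alignedR), 1 - 1e-9)

  expect_identical(
    microstateMaps(modifiedKMeans(obs, 3, nInit = 10, seed = 7)),
    microstateMaps(m1)
  )
  expect_error(modifiedKMeans(obs[1:2, ], 3), "parameter error")
})

test_that("GEV is non-decreasing in k on the same data", {
  spec <- syntheticSpec(nChannels = 32, kTrue = 4, fs = 250, durationS = 10,
                        seed = 22)
  gt <- generateEEG(spec)
  obs <- t(eegData(gt$recording))[gfpCurve(gt$recording)$peaks, ]
  gevs <- vapply(2:6, function(k) {
    gev(modifiedKMeans(obs, k, nInit = 10, seed = 3))
  }, 0)
  expect_true(all(diff(gevs) > -1e-6))
})

test_that("synthetic parameter recovery at SNR 5 is nearly perfect", {
  spec <- syntheticSpec(seed = 31) # 64 ch, k 4, 20 s @ 250 Hz, snr 5
  gt <- generateEEG(spec)
  obs <- t(eegData(gt$recording))[gfpCurve(gt$recording)$peaks, ]
  m <- modifiedKMeans(obs, 4, nInit = 20, seed = 1)
  al <- alignModels(MicrostateModel(gt$maps), m)
  expect_gte(mean(al$alignedR), 0.95)

  # and the recovered label sequence reproduces the transition structure
  seq <- backfit(gt$recording, m)
  st <- sequenceStats(seq)
  stTrue <- sequenceStats(gt$stateSequence)
  expect_gte(st$nTransitions, 300)
  perm <- al$permutation
  reordered <- st$transitionMatrix[perm, perm]
  expect_lte(max(abs(reordered - stTrue$transitionMatrix)), 0.1)
})

test_that("Krzanowski-Lai selection finds the true number of maps", {
  spec2 <- syntheticSpec(nChannels = 32, kTrue = 2, fs = 250, durationS = 15,
                         seed = 41)
  gt2 <- generateEEG(spec2)
  obs2 <- t(eegData(gt2$recording))[gfpCurve(gt2$recording)$peaks, ]
  kl2 <- selectKKL(obs2, kRange = 2:6, nInit = 10, seed = 1)
  expect_identical(optimalK(kl2), 2L)
  # dispersion decreases with k
  expect_true(all(diff(kl2@W) < 0))

  expect_error(selectKKL(obs2, kRange = 2:3), "parameter error")
})

test_that("cohort clustering pools subject maps faithfully", {
  maps <- generateMaps(24, 3, seed = 5)
  base <- MicrostateModel(maps, channelNames = paste0("c", 1:24))
  # identical subjects: cohort maps equal subject maps up to sign/permutation
  coh <- fitCohort(list(base, base, base), nInit = 5, seed = 1)
  expect_identical(coh@level, "cohort")
  al <- alignModels(base, coh)
  expect_gt(min(al$alignedR), 1 - 1e-9)

  # noisy subjects: cohort maps recover the common truth
  set.seed(6)
  noisy <- lapply(1:8, function(i) {
    nm <- maps + matrix(rnorm(length(maps), sd = 0.05), nrow(maps))
    nm <- nm - rowMeans(nm)
    MicrostateModel(nm / sqrt(rowSums(nm^2)))
  })
  cohN <- fitCohort(noisy, nInit = 10, seed = 2)
  expect_gte(min(alignModels(MicrostateModel(maps), cohN)$alignedR), 0.99)

  # single subject: cohort model equals that subject up to sign
  coh1 <- fitCohort(list(base), nInit = 5, seed = 3)
  expect_gt(min(alignModels(base, coh1)$alignedR), 1 - 1e-9)

  small <- MicrostateModel(generateMaps(10, 3, seed = 7))
  expect_error(fitCohort(list(base, small)), "metadata error")
})

test_that("model alignment matches exhaustive search and handles flips", {
  maps <- generateMaps(20, 4, seed = 8)
  a <- MicrostateModel(maps)
  flipped <- maps[4:1, ] * c(-1, 1, -1, 1)
  b <- MicrostateModel(flipped)
  al <- alignModels(a, b)
  expect_identical(al$permutation, c(4L, 3L, 2L, 1L))
  # b_j = s_j * a_(5-j) with s = (-1, 1, -1, 1), so the sign matched to a_i
  # is s_(5-i); applying it makes every aligned pair correlate at +1
  expect_equal(unname(al$signs), c(1, -1, 1, -1))
  expect_equal(unname(al$alignedR), rep(1, 4), tolerance = 1e-12)

  expect_identical(alignModels(a, a)$permutation, 1:4)

  # random case against an independently generated exhaustive search
  set.seed(9)
  r1 <- matrix(rnorm(4 * 20), 4)
  r2 <- matrix(rnorm(4 * 20), 4)
  r1 <- (r1 - rowMeans(r1)) / sqrt(rowSums((r1 - rowMeans(r1))^2))
  r2 <- (r2 - rowMeans(r2)) / sqrt(rowSums((r2 - rowMeans(r2))^2))
  al <- alignModels(MicrostateModel(r1), MicrostateModel(r2))
  R <- abs(r1 %*% t(r2))
  perms <- allPermsOracle(4)
  scores <- apply(perms, 1, function(p) sum(R[cbind(1:4, p)]))
  expect_equal(sum(al$alignedR), max(scores))
})

test_that("backfitting labels by best squared correlation", {
  maps <- generateMaps(12, 3, seed = 10)
  amp <- sin(seq(0.1, 6, length.out = 40))
  amp[abs(amp) < 0.05] <- 0.05
  rec <- mapDrivenRecording(maps, rep(2L, 40), amp)
  model <- MicrostateModel(maps)
  expect_true(all(stateLabels(backfit(rec, model)) == 2L))

  negRec <- EEGRecording(-eegData(rec), fs = samplingRate(rec))
  expect_identical(
    stateLabels(backfit(negRec, model)),
    stateLabels(backfit(rec, model))
  )
})

test_that("minimum-duration smoothing absorbs glitch segments", {
  maps <- generateMaps(12, 2, seed = 12)
  labels <- c(rep(1L, 30), 2L, rep(1L, 30)) # a 1-sample glitch
  rec <- mapDrivenRecording(maps, labels, rep(1, 61), fs = 100)
  model <- MicrostateModel(maps)
  raw <- backfit(rec, model)
  expect_identical(stateLabels(raw), labels)
  sm <- backfit(rec, model, minDurationMs = 30)
  expect_true(all(stateLabels(sm) == 1L))
})

test_that("canonical template naming identifies planted classes", {
  templates <- read.csv(system.file("extdata", "templates_synthetic_ad.csv",
    package = "EEGmicrostates"
  ))
  tm <- t(as.matrix(templates[, -1]))
  tm <- tm - rowMeans(tm)
  tm <- tm / sqrt(rowSums(tm^2))
  # model = templates in scrambled order with sign flips
  scramble <- c(3L, 1L, 4L, 2L)
  model <- MicrostateModel(tm[scramble, ] * c(1, -1, 1, -1),
    channelNames = templates$channel
  )
  out <- labelCanonicalClasses(model)
  expect_identical(out$classNames, c("C", "A", "D", "B"))
  expect_gt(min(out$alignedR), 1 - 1e-9)
})
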