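test_that("sequence statistics match hand enumeration", {
  s <- LabelSequence(c(1, 1, 1, 1, 2, 2, 1, 1, 3, 3, 3, 3), fs = 250, k = 3)
  st <- sequenceStats(s)
  expect_equal(st$coverage, c(0.5, 2 / 12, 4 / 12))
  # transitions: 1->2, 2->1, 1->3, each 1/3
  expected <- matrix(0, 3, 3)
  expected[1, 2] <- expected[2, 1] <- expected[1, 3] <- 1 / 3
  expect_equal(st$transitionMatrix, expected)
  # interior runs: the 2-sample runs of classes 2 and 1 (8 ms at 250 Hz);
  # class 3 only has a boundary run
  expect_equal(st$meanDurationMs[1], 8)
  expect_equal(st$meanDurationMs[2], 8)
  expect_true(is.na(st$meanDurationMs[3]))
})

test_that("alternating labels give symmetric statistics", {
  s <- LabelSequence(c(rep(1:2, 50), 1L), fs = 100, k = 2) # 100 transitions
  st <- sequenceStats(s)
  expect_equal(st$coverage, c(51 / 101, 50 / 101))
  expect_equal(st$transitionMatrix[1, 2], 0.5)
  expect_equal(st$transitionMatrix[2, 1], 0.5)
})

test_that("coverage and transition normalization hold on random sequences", {
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    labels <- rle(sample.int(k, 400, replace = TRUE))$values
    if (length(labels) < 2) next
    st <- sequenceStats(LabelSequence(labels, fs = 100, k = k))
    expect_lt(abs(sum(st$coverage) - 1), 1e-9)
    expect_lt(abs(sum(st$transitionMatrix) - 1), 1e-9)
    expect_true(all(diag(st$transitionMatrix) == 0))
    expect_true(all(st$transitionMatrix >= 0))
  }
})

test_that("a single-run sequence has no defined statistics", {
  expect_error(
    sequenceStats(LabelSequence(rep(1L, 50), fs = 100, k = 2)),
    "single run"
  )
})

test_that("U = 381 at n = (26, 21) converts to z = 2.30", {
  zp <- uToZScore(381, 26, 21)
  expect_equal(round(zp$z, 2), 2.30)

  # and via the full test on constructed tie-free samples with exactly U = 381
  y <- 1:21
  # 14 x-values above all y, nine between y[7] and y[8], three between
  # y[8] and y[9]: U = 14*21 + 9*7 + 3*8 = 381
  x <- c(seq(22, 35), rep(7.5, 9) + seq(0, 0.4, length.out = 9),
         rep(8.5, 3) + c(0, 0.1, 0.2))
  res <- mannWhitneyZ(x, y)
  expect_equal(res$statistic, 381)
  expect_equal(round(res$z, 2), 2.30)
  expect_equal(res$effectDirection, 1)
})

test_that("identical pooled samples give U at its mean and z = 0", {
  res <- mannWhitneyZ(c(1, 2), c(1, 2))
  expect_equal(res$statistic, 2)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("normal approximation tracks exact enumeration for small samples", {
  # spec case: fully separated n = 3 vs 3 has exact two-sided p = 0.1
  ex <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(ex$p.value, 0.1)
  res <- mannWhitneyZ(c(1, 2, 3), c(4, 5, 6))
  expect_lt(abs(res$p - 0.1), 0.02)

  # exhaustive over every tie-free outcome for n1, n2 in 3..8: the
  # continuity-corrected approximation stays within 0.02 of the exact
  # two-sided p in the decision-relevant tail (p <= 0.2) and within the
  # enumerated global worst case of 0.04 elsewhere
  for (n1 in 3:8) {
    for (n2 in n1:8) {
      for (U in 0:(n1 * n2)) {
        exact <- min(1, 2 * min(
          pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2)
        ))
        approx <- uToZScore(U, n1, n2)$p
        expect_lt(abs(approx - exact), if (exact <= 0.2) 0.02 else 0.04)
      }
    }
  }
})

test_that("two-way ANOVA reproduces hand-computed balanced F ratios", {
  # balanced 2x2, cell means 0/2/1/5, sd 1 noise
  set.seed(16)
  n <- 25
  d <- expand.grid(group = c("g1", "g2"), class = c("c1", "c2"),
                   rep = seq_len(n))
  mu <- c("g1.c1" = 0, "g2.c1" = 2, "g1.c2" = 1, "g2.c2" = 5)
  d$value <- mu[paste(d$group, d$class, sep = ".")] + rnorm(nrow(d))
  out <- twoWayAnova(d)

  # oracle: direct sums of squares for the balanced design
  cellMean <- tapply(d$value, list(d$group, d$class), mean)
  gm <- mean(d$value)
  ssG <- 2 * n * sum((rowMeans(cellMean) - gm)^2)
  ssC <- 2 * n * sum((colMeans(cellMean) - gm)^2)
  ssI <- n * sum((sweep(sweep(cellMean, 1, rowMeans(cellMean)), 2,
                        colMeans(cellMean)) + gm)^2)
  ssE <- sum((d$value - cellMean[cbind(as.character(d$group),
                                       as.character(d$class))])^2)
  mse <- ssE / (4 * n - 4)
  expect_equal(out$F, c(ssG, ssC, ssI) / mse, tolerance = 1e-8)
})

test_that("Type II sums of squares match the model-comparison oracle", {
  set.seed(17)
  # unbalanced 2x2
  d <- data.frame(
    group = c(rep("a", 14), rep("b", 23)),
    class = sample(c("x", "y"), 37, replace = TRUE)
  )
  d$value <- rnorm(37) + (d$group == "b") * 1.2 + (d$class == "y") * 0.4
  out <- twoWayAnova(d)

  rss <- function(f) sum(resid(lm(f, data = d))^2)
  full <- rss(value ~ group * class)
  both <- rss(value ~ group + class)
  dfe <- nrow(d) - 4
  Fg <- ((rss(value ~ class) - both) / 1) / (full / dfe)
  Fc <- ((rss(value ~ group) - both) / 1) / (full / dfe)
  Fi <- ((both - full) / 1) / (full / dfe)
  expect_equal(out$F, c(Fg, Fc, Fi), tolerance = 1e-8)
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  d <- expand.grid(group = c("a", "b"), class = c("x", "y"), rep = 1:3)
  d$value <- 7
  out <- twoWayAnova(d)
  expect_true(all(out$F == 0) && all(out$p == 1))

  d2 <- d[!(d$group == "a" & d$class == "y"), ]
  d2$value <- rnorm(nrow(d2))
  expect_error(twoWayAnova(d2), "empty design cell")
})

test_that("TANOVA is exchangeable under the null and respects its floor", {
  maps <- generateMaps(19, 4, seed = 18)
  set.seed(18)
  subj <- maps[1, ] + matrix(rnorm(12 * 19, sd = 0.3), 12, 19, byrow = FALSE)
  # same subjects reshuffled into two groups: no real difference
  res <- tanova(subj[1:6, ], subj[7:12, ], nPerm = 499, seed = 1)
  expect_gt(res$p, 0.05)

  # groups around orthogonal templates: observed beats every permutation
  set.seed(19)
  a <- t(replicate(10, maps[1, ] + rnorm(19, sd = 0.05)))
  b <- t(replicate(10, maps[2, ] + rnorm(19, sd = 0.05)))
  sep <- tanova(a, b, nPerm = 999, seed = 2)
  expect_equal(sep$p, 0.001)

  # permuting subject order within a group leaves the statistic unchanged
  res2 <- tanova(subj[1:6, ][c(3, 1, 2, 6, 5, 4), ], subj[7:12, ],
                 nPerm = 9, seed = 3)
  expect_equal(res2$statistic, res$statistic)

  expect_error(tanova(subj[1, , drop = FALSE], subj[2:4, ]), "at least 2")
})

test_that("TANOVA p-values are uniform under the null", {
  maps <- generateMaps(19, 2, seed = 20)
  set.seed(20)
  hits <- 0L
  nrep <- 200
  for (i in seq_len(nrep)) {
    g <- maps[1, ] + matrix(rnorm(12 * 19, sd = 0.4), 12, 19, byrow = TRUE)
    p <- tanova(g[1:6, ], g[7:12, ], nPerm = 199)$p
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.01)
  expect_lte(hits / nrep, 0.10)
})
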