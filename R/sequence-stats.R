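## Microstate syntax statistics (duration, coverage, transition matrix) and
## the group comparison machinery: Mann-Whitney U with its normal
## approximation z-score, two-way ANOVA (Type II), and permutation TANOVA
## for topographic differences.

#' Microstate sequence statistics
#'
#' Computes per-class mean duration, coverage and the normalized transition
#' matrix of a backfitted label sequence. Durations are taken over maximal
#' constant runs and converted to milliseconds; runs touching either epoch
#' boundary are excluded from duration means by default, because their true
#' dwell time is censored (coverage always uses all samples). Transitions are
#' counted at label change points and normalized by the total number of
#' transitions.
#'
#' @param seq a [LabelSequence-class].
#' @param excludeTruncated drop boundary-touching runs from duration means
#'   (default `TRUE`).
#' @return A list of class `"SequenceStats"`: `meanDurationMs` (per class,
#'   `NA` where a class has no measurable run), `grandMeanDurationMs`,
#'   `coverage`, `transitionMatrix` (k x k, zero diagonal, sums to 1), and
#'   `nTransitions`.
#' @examples
#' s <- LabelSequence(c(1,1,1,1,2,2,1,1,3,3,3,3), fs = 250, k = 3)
#' sequenceStats(s)$coverage
#' @export
sequenceStats <- function(seq, excludeTruncated = TRUE) {
  stopifnot(is(seq, "LabelSequence"))
  labels <- stateLabels(seq)
  k <- nStates(seq)
  fs <- samplingRate(seq)
  r <- rle(labels)
  nRuns <- length(r$lengths)
  if (nRuns <= 1L) {
    stop("sequence has a single run: durations and transition matrix are undefined",
      call. = FALSE
    )
  }

  coverage <- tabulate(labels, nbins = k) / length(labels)

  keep <- seq_len(nRuns)
  if (excludeTruncated) keep <- keep[keep != 1L & keep != nRuns]
  durMs <- rep(NA_real_, k)
  if (length(keep)) {
    for (cl in seq_len(k)) {
      lens <- r$lengths[keep][r$values[keep] == cl]
      if (length(lens)) durMs[cl] <- mean(lens) / fs * 1000
    }
  }

  trans <- matrix(0, k, k)
  from <- r$values[-nRuns]
  to <- r$values[-1]
  for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  nTrans <- sum(trans)
  trans <- trans / nTrans

  structure(
    list(
      meanDurationMs = durMs,
      grandMeanDurationMs = mean(durMs, na.rm = TRUE),
      coverage = coverage,
      transitionMatrix = trans,
      nTransitions = nTrans
    ),
    class = "SequenceStats"
  )
}

#' Convert a Mann-Whitney U statistic to its normal-approximation z-score
#'
#' `z = (U - n1 n2 / 2 -/+ 0.5) / sigma`, with the continuity correction
#' applied toward the mean (and z clamped to 0 when |U - mu| <= 0.5), and
#' `sigma` optionally tie-corrected: `sigma^2 = n1 n2 / 12 * ((N + 1) -
#' sum(t^3 - t) / (N (N - 1)))` where `t` are tie-group sizes.
#'
#' @param U the U statistic.
#' @param n1,n2 group sizes.
#' @param tieSum `sum(t^3 - t)` over tie groups (0 when there are no ties).
#' @return list with `z` and the two-sided `p` from the standard normal.
#' @examples
#' uToZScore(381, 26, 21)$z # 2.30 to 2 decimals
#' @export
uToZScore <- function(U, n1, n2, tieSum = 0) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieSum / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(z = 0, p = 1))
  }
  num <- U - mu
  z <- if (abs(num) <= 0.5) 0 else (num - 0.5 * sign(num)) / sqrt(sigma2)
  list(z = z, p = zScorePValue(z))
}

#' Two-sided p-value of a standard-normal z-score
#'
#' @param z z-score.
#' @return `2 * pnorm(-|z|)`.
#' @export
zScorePValue <- function(z) 2 * stats::pnorm(-abs(z))

#' Mann-Whitney U test with normal-approximation z-score
#'
#' U is computed by midrank counting (ties contribute 1/2); the z-score uses
#' the continuity- and tie-corrected normal approximation of [uToZScore()],
#' which is reported alongside the p-value as an effect size.
#'
#' @param x,y numeric samples (each nonempty).
#' @return A list of class `"TestResult"`: `statistic` (U for `x`), `z`, `p`,
#'   `effectDirection` (sign of `U - n1 n2 / 2`).
#' @export
mannWhitneyZ <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be nonempty", call. = FALSE)
  all <- c(x, y)
  rk <- rank(all)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie <- table(all)
  tieSum <- sum(tie^3 - tie)
  zp <- uToZScore(U, n1, n2, tieSum = tieSum)
  structure(
    list(
      statistic = U, z = zp$z, p = zp$p,
      effectDirection = sign(U - n1 * n2 / 2)
    ),
    class = "TestResult"
  )
}

#' Two-way fixed-effects ANOVA with Type II sums of squares
#'
#' Fits `value ~ group * class` and reports F and p per term, using Type II
#' sums of squares so that unbalanced group sizes are handled sensibly.
#'
#' @param values data.frame with columns `group`, `class`, `value` (a
#'   `subject` column may be present and is ignored by the fit).
#' @return data.frame with one row per term (`group`, `class`,
#'   `group:class`) and columns `term`, `df`, `F`, `p`.
#' @export
twoWayAnova <- function(values) {
  stopifnot(all(c("group", "class", "value") %in% names(values)))
  values$group <- factor(values$group)
  values$class <- factor(values$class)
  if (nlevels(values$group) < 2 || nlevels(values$class) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cells <- table(values$group, values$class)
  if (any(cells == 0)) {
    stop("empty design cell; drop the offending factor level before testing",
      call. = FALSE
    )
  }
  if (stats::var(values$value) == 0) {
    terms <- c("group", "class", "group:class")
    return(data.frame(
      term = terms,
      df = c(nlevels(values$group) - 1L, nlevels(values$class) - 1L,
             (nlevels(values$group) - 1L) * (nlevels(values$class) - 1L)),
      F = 0, p = 1, stringsAsFactors = FALSE
    ))
  }
  fit <- stats::lm(value ~ group * class, data = values)
  tab <- car::Anova(fit, type = 2)
  rows <- match(c("group", "class", "group:class"), rownames(tab))
  data.frame(
    term = c("group", "class", "group:class"),
    df = tab$Df[rows],
    F = tab$`F value`[rows],
    p = tab$`Pr(>F)`[rows],
    stringsAsFactors = FALSE
  )
}

#' Topographic analysis of variance (TANOVA)
#'
#' Nonparametric permutation test for a topographic difference between two
#' groups of subject maps for one microstate class. Each subject contributes
#' one map; all maps are polarity-aligned to the pooled consensus (the
#' principal topography of both groups combined, so the alignment is
#' identical for the observed and every permuted relabelling), group means
#' are taken and renormalized, and the test statistic is
#' `1 - |r(mean_A, mean_B)|`. The null is built by permuting group labels;
#' with `nPerm = 999` the attainable minimum p is exactly 0.001.
#'
#' @param mapsA,mapsB subject x channel matrices (one row per subject).
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return A list of class `"TestResult"`: `statistic`, `p`, `nPerm`.
#' @export
tanova <- function(mapsA, mapsB, nPerm = 999, seed = NULL) {
  mapsA <- as.matrix(mapsA)
  mapsB <- as.matrix(mapsB)
  if (nrow(mapsA) < 2 || nrow(mapsB) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  A <- .normalizeRows(.centerRows(rbind(mapsA, mapsB)))
  nA <- nrow(mapsA)
  n <- nrow(A)
  # polarity alignment to the pooled consensus: permutation-invariant, so
  # the same aligned maps enter the observed and every permuted statistic
  s <- sign(A %*% .principalMap(A))
  s[s == 0] <- 1
  A <- A * as.vector(s)
  groupMean <- function(M) {
    m <- colMeans(M)
    m <- m - mean(m)
    m / sqrt(sum(m^2))
  }
  stat <- function(idxA) {
    1 - abs(sum(groupMean(A[idxA, , drop = FALSE]) *
                  groupMean(A[-idxA, , drop = FALSE])))
  }
  obs <- stat(seq_len(nA))
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    if (stat(sample.int(n, nA)) >= obs) exceed <- exceed + 1L
  }
  structure(
    list(statistic = obs, p = (exceed + 1) / (nPerm + 1), nPerm = nPerm),
    class = "TestResult"
  )
}
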