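## Polarity-invariant ("modified") k-means for microstate topographies,
## Krzanowski-Lai selection of k, cohort-level pooling, map alignment and
## backfitting. The distance between two topographies u, v is 1 - r(u,v)^2
## with r the spatial Pearson correlation, so a map and its sign-flip are
## identical; centroids are the first principal eigenvector of the assigned
## observations' outer-product sum.

.centerRows <- function(X) X - rowMeans(X)

.normalizeRows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

#' Global field power curve and its peaks
#'
#' GFP at time t is the spatial standard deviation of the average-referenced
#' voltages across channels; its strict local maxima are the moments of
#' highest topographic signal-to-noise, conventionally used as the
#' observations for microstate clustering.
#'
#' @param rec an [EEGRecording-class]. If not average-referenced a warning is
#'   issued and the reference is applied.
#' @return A list with `gfp` (per-sample nonnegative vector) and `peaks`
#'   (sample indices of strict local maxima).
#' @export
gfpCurve <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  data <- rec@data
  if (!.isAverageReferenced(data)) {
    warning("recording is not average-referenced; re-referencing")
    data <- sweep(data, 2, colMeans(data))
  }
  gfp <- sqrt(colMeans(data^2)) # population SD: channel means are 0
  n <- length(gfp)
  peaks <- integer(0)
  if (n >= 3) {
    core <- gfp[2:(n - 1)]
    peaks <- which(core > gfp[1:(n - 2)] & core > gfp[3:n]) + 1L
  }
  list(gfp = gfp, peaks = peaks)
}

## first principal eigenvector of t(X) %*% X (X: members x channels)
.principalMap <- function(X) {
  C <- crossprod(X)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

## k-means++ seeding on the 1 - r^2 metric
.kppInit <- function(A, k) {
  n <- nrow(A)
  centers <- matrix(0, k, ncol(A))
  idx <- sample.int(n, 1L)
  centers[1, ] <- A[idx, ]
  if (k > 1) {
    d <- 1 - (A %*% centers[1, ])^2
    for (j in 2:k) {
      d[d < 0] <- 0
      p <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = p)
      centers[j, ] <- A[idx, ]
      if (j < k) d <- pmin(d, 1 - (A %*% centers[j, ])^2)
    }
  }
  centers
}

.kmeansOnce <- function(X, A, gfp, k, maxIter = 200, tol = 1e-7) {
  n <- nrow(A)
  M <- .kppInit(A, k)
  assign <- integer(n)
  lastGev <- -Inf
  for (iter in seq_len(maxIter)) {
    R <- A %*% t(M) # spatial correlations (rows unit norm, zero mean)
    R2 <- R^2
    newAssign <- max.col(R2, ties.method = "first")
    # empty clusters: reseed from the worst-fit observation
    repeat {
      counts <- tabulate(newAssign, nbins = k)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      best <- R2[cbind(seq_len(n), newAssign)]
      worst <- which.min(best)
      M[empty[1], ] <- A[worst, ]
      R2[, empty[1]] <- (A %*% M[empty[1], ])^2
      newAssign <- max.col(R2, ties.method = "first")
    }
    for (j in seq_len(k)) {
      M[j, ] <- .principalMap(X[newAssign == j, , drop = FALSE])
    }
    R <- A %*% t(M)
    r <- R[cbind(seq_len(n), newAssign)]
    gev <- sum((gfp * r)^2) / sum(gfp^2)
    if (identical(newAssign, assign) || abs(gev - lastGev) < tol) {
      assign <- newAssign
      lastGev <- gev
      break
    }
    assign <- newAssign
    lastGev <- gev
  }
  list(maps = M, assign = assign, gev = lastGev)
}

#' Polarity-invariant modified k-means
#'
#' Clusters scalp topographies into `k` microstate maps under the
#' polarity-invariant distance `1 - r^2`. Initialization is k-means++
#' (adapted to this metric) with `nInit` independent restarts; the restart
#' with the highest global explained variance (GEV) wins. GEV weights each
#' observation's squared correlation with its assigned map by its GFP:
#' `GEV = sum_t (gfp_t r_t)^2 / sum_t gfp_t^2`.
#'
#' @param obs numeric matrix, observations x channels (e.g. topographies at
#'   GFP peaks). Rows are centered internally.
#' @param k number of microstate classes.
#' @param nInit number of restarts (default 20).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param channelNames optional channel names for the model.
#' @param maxIter iteration cap per restart.
#' @return A [MicrostateModel-class]; the winning assignment is attached as
#'   attribute `"assign"` and per-k dispersion as `"W"`.
#' @examples
#' maps <- generateMaps(16, 3, seed = 2)
#' obs <- maps[rep(1:3, each = 40), ] * rnorm(120) # amplitude-modulated
#' m <- modifiedKMeans(obs, k = 3, seed = 1)
#' gev(m)
#' @export
modifiedKMeans <- function(obs, k, nInit = 20, seed = NULL,
                           channelNames = character(), maxIter = 200) {
  obs <- as.matrix(obs)
  if (k > nrow(obs)) {
    stop("parameter error: k exceeds the number of observations",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  X <- .centerRows(obs)
  gfp <- sqrt(rowMeans(X^2))
  A <- .normalizeRows(X)
  best <- NULL
  for (i in seq_len(nInit)) {
    fit <- .kmeansOnce(X, A, gfp, k, maxIter = maxIter)
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  # canonical sign: largest-|value| channel positive
  M <- best$maps
  for (j in seq_len(k)) {
    s <- sign(M[j, which.max(abs(M[j, ]))])
    if (s < 0) M[j, ] <- -M[j, ]
  }
  R2 <- (A %*% t(M))^2
  W <- sum(1 - R2[cbind(seq_len(nrow(A)), best$assign)])
  model <- MicrostateModel(M, gev = best$gev, level = "subject",
                           channelNames = channelNames)
  attr(model, "assign") <- best$assign
  attr(model, "W") <- W
  model
}

#' Krzanowski-Lai selection of the number of microstates
#'
#' For each `k` in `kRange`, fits [modifiedKMeans()] and records the
#' within-cluster dispersion `W(k) = sum(1 - r^2(member, centroid))`. The
#' criterion penalizes dispersion by dimensionality `p` (number of
#' channels): `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` and
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|`; the optimum is the `k` maximizing KL
#' over the values where both neighbours are defined. `W` is additionally
#' evaluated at `min(kRange) - 1` (down to the single principal map at
#' k = 1) so that the lowest tested k is selectable.
#'
#' @param obs observations x channels matrix.
#' @param kRange contiguous integer range with at least 3 values, minimum 2.
#' @param nInit restarts per k.
#' @param seed RNG seed.
#' @return A [KLCurve-class].
#' @export
selectKKL <- function(obs, kRange = 2:8, nInit = 20, seed = NULL) {
  kRange <- as.integer(kRange)
  if (length(kRange) < 3 || min(kRange) < 2 ||
      !all(diff(kRange) == 1L)) {
    stop("parameter error: kRange must be a contiguous range of >= 3 values starting at >= 2",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(obs)
  # dispersion is also needed at kmin - 1 so that DIFF and KL are defined at
  # the low end of the range; k = 1 is the single principal map
  kExt <- c(min(kRange) - 1L, kRange)
  WExt <- vapply(kExt, function(k) {
    if (k == 1L) {
      X <- .centerRows(as.matrix(obs))
      A <- .normalizeRows(X)
      m <- .principalMap(X)
      sum(1 - (A %*% m)^2)
    } else {
      attr(modifiedKMeans(obs, k, nInit = nInit), "W")
    }
  }, 0)
  DIFFExt <- rep(NA_real_, length(kExt))
  for (i in 2:length(kExt)) {
    km <- kExt[i]
    DIFFExt[i] <- (km - 1)^(2 / p) * WExt[i - 1] - km^(2 / p) * WExt[i]
  }
  KLExt <- rep(NA_real_, length(kExt))
  for (i in 2:(length(kExt) - 1)) {
    KLExt[i] <- abs(DIFFExt[i]) / abs(DIFFExt[i + 1])
  }
  keep <- match(kRange, kExt)
  W <- WExt[keep]
  DIFF <- DIFFExt[keep]
  KL <- KLExt[keep]
  candidates <- which(!is.na(KL))
  kOpt <- kRange[candidates[which.max(KL[candidates])]]
  new("KLCurve", kValues = kRange, W = W, DIFF = DIFF, KL = KL,
      kOpt = as.integer(kOpt))
}

#' Cohort-level clustering of subject maps
#'
#' Pools the maps of all subject-level models (n_subjects x k observations)
#' and reclusters them with [modifiedKMeans()] to obtain one set of k
#' cohort-level maps, following the two-stage global clustering approach.
#'
#' @param subjectModels list of [MicrostateModel-class] objects with equal k
#'   and channel count.
#' @param k number of cohort maps; defaults to the subject models' k.
#' @param nInit,seed passed to [modifiedKMeans()].
#' @return A cohort-level [MicrostateModel-class].
#' @export
fitCohort <- function(subjectModels, k = NULL, nInit = 20, seed = NULL) {
  stopifnot(length(subjectModels) >= 1)
  nch <- vapply(subjectModels, function(m) ncol(microstateMaps(m)), 0L)
  if (length(unique(nch)) != 1L) {
    stop("metadata error: subject models have heterogeneous channel counts",
      call. = FALSE
    )
  }
  if (is.null(k)) k <- nStates(subjectModels[[1]])
  pool <- do.call(rbind, lapply(subjectModels, microstateMaps))
  model <- modifiedKMeans(pool, k, nInit = nInit, seed = seed,
                          channelNames = channelNames(subjectModels[[1]]))
  model@level <- "cohort"
  model
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Align two microstate models
#'
#' Finds the one-to-one assignment of `modelB`'s maps to `modelA`'s that
#' maximizes the summed absolute spatial correlation (exhaustive over all
#' permutations for k <= 8), and the sign flips that make each aligned pair
#' correlate positively. The full |r| table is returned for visual
#' inspection.
#'
#' @param modelA,modelB [MicrostateModel-class] objects with equal k over the
#'   same channels.
#' @return A list with `permutation` (index into `modelB` maps for each map
#'   of `modelA`), `signs`, `correlations` (signed k x k table), and
#'   `alignedR` (per-pair |r| after alignment).
#' @export
alignModels <- function(modelA, modelB) {
  MA <- .normalizeRows(.centerRows(microstateMaps(modelA)))
  MB <- .normalizeRows(.centerRows(microstateMaps(modelB)))
  if (nrow(MA) != nrow(MB) || ncol(MA) != ncol(MB)) {
    stop("models must share k and channel set", call. = FALSE)
  }
  k <- nrow(MA)
  R <- MA %*% t(MB)
  absR <- abs(R)
  if (k <= 8) {
    perms <- .permutations(k)
    tot <- vapply(seq_len(nrow(perms)), function(i) {
      sum(absR[cbind(seq_len(k), perms[i, ])])
    }, 0)
    perm <- perms[which.max(tot), ]
  } else {
    # greedy fallback for large k
    perm <- integer(k)
    free <- seq_len(k)
    for (i in order(-apply(absR, 1, max))) {
      j <- free[which.max(absR[i, free])]
      perm[i] <- j
      free <- setdiff(free, j)
    }
  }
  signs <- sign(R[cbind(seq_len(k), perm)])
  signs[signs == 0] <- 1
  list(
    permutation = as.integer(perm), signs = signs, correlations = R,
    alignedR = absR[cbind(seq_len(k), perm)]
  )
}

#' Backfit microstate labels to a recording
#'
#' Labels every sample with the class whose map it best matches by squared
#' spatial correlation (ties broken toward the lowest class index). With
#' `minDurationMs > 0`, segments shorter than the minimum are iteratively
#' absorbed into whichever neighboring class correlates better with their
#' samples.
#'
#' @param rec an [EEGRecording-class].
#' @param model a [MicrostateModel-class] over the same channels.
#' @param minDurationMs minimum segment duration (default 0 = no smoothing).
#' @return A [LabelSequence-class].
#' @export
backfit <- function(rec, model, minDurationMs = 0) {
  stopifnot(is(rec, "EEGRecording"), is(model, "MicrostateModel"))
  if (ncol(microstateMaps(model)) != nChannels(rec)) {
    stop("channel sets of recording and model differ", call. = FALSE)
  }
  X <- .centerRows(t(rec@data)) # samples x channels
  A <- .normalizeRows(X)
  M <- .normalizeRows(.centerRows(microstateMaps(model)))
  R2 <- (A %*% t(M))^2
  labels <- max.col(R2, ties.method = "first")
  k <- nrow(M)

  if (minDurationMs > 0) {
    minLen <- max(1L, as.integer(round(minDurationMs / 1000 * rec@fs)))
    repeat {
      r <- rle(labels)
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < minLen)
      if (!length(short)) break
      i <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      span <- starts[i]:ends[i]
      cand <- c(
        if (i > 1L) r$values[i - 1L],
        if (i < length(r$values)) r$values[i + 1L]
      )
      cand <- unique(cand)
      fit <- vapply(cand, function(cl) mean(R2[span, cl]), 0)
      labels[span] <- cand[which.max(fit)]
    }
  }
  LabelSequence(labels, fs = rec@fs, k = k)
}

#' Global explained variance of a labeling
#'
#' @param rec an [EEGRecording-class].
#' @param model a [MicrostateModel-class].
#' @param seq a [LabelSequence-class] (defaults to backfitting `model`).
#' @return GEV in `[0, 1]`.
#' @export
computeGEV <- function(rec, model, seq = NULL) {
  if (is.null(seq)) seq <- backfit(rec, model)
  X <- .centerRows(t(rec@data))
  gfp <- sqrt(rowMeans(X^2))
  A <- .normalizeRows(X)
  M <- .normalizeRows(.centerRows(microstateMaps(model)))
  r <- rowSums(A * M[stateLabels(seq), , drop = FALSE])
  sum((gfp * r)^2) / sum(gfp^2)
}

#' Name microstate classes after canonical templates
#'
#' Aligns cohort maps against a set of template topographies (by default the
#' synthetic approximations of the four classical resting classes A-D shipped
#' with the package, defined over the 19-channel 10-20 montage) and returns
#' the implied class names together with the alignment report for manual
#' inspection. Channels are matched by name; channels absent from either side
#' are dropped before correlation.
#'
#' @param model a [MicrostateModel-class] with channel names.
#' @param templates optional data.frame (channel column + one column per
#'   template class); default reads the shipped synthetic templates.
#' @return list with `classNames`, `alignedR` and the full correlation table.
#' @export
labelCanonicalClasses <- function(model, templates = NULL) {
  if (is.null(templates)) {
    templates <- utils::read.csv(system.file(
      "extdata", "templates_synthetic_ad.csv",
      package = "EEGmicrostates"
    ))
  }
  common <- intersect(channelNames(model), templates$channel)
  if (length(common) < 4) {
    stop("too few channels in common with the templates", call. = FALSE)
  }
  tm <- t(as.matrix(templates[match(common, templates$channel), -1]))
  mm <- microstateMaps(model)[, match(common, channelNames(model)), drop = FALSE]
  if (nrow(mm) != nrow(tm)) {
    stop("model k must match the number of template classes", call. = FALSE)
  }
  tmod <- MicrostateModel(.normalizeRows(.centerRows(tm)),
    level = "cohort", channelNames = common
  )
  mmod <- MicrostateModel(.normalizeRows(.centerRows(mm)),
    level = "cohort", channelNames = common
  )
  al <- alignModels(mmod, tmod)
  list(
    classNames = rownames(tm)[al$permutation],
    alignedR = al$alignedR,
    correlations = al$correlations
  )
}
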