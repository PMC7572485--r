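## Semi-Markov synthetic EEG with known microstate structure. The generator
## switches among a small set of fixed unit-norm topographies, each dwell
## lasting a gamma-distributed time, modulated by an alpha-band carrier with
## per-dwell random phase, plus i.i.d. Gaussian sensor noise at a requested
## signal-to-noise ratio.

#' Specification for the synthetic EEG generator
#'
#' Bundles all generator parameters. Defaults emulate a 20 s eyes-open
#' resting-state epoch with four underlying topographies, mean dwell 60 ms
#' (gamma shape 2, i.e. dwell times of tens to a few hundred ms), a 10 Hz
#' (alpha) amplitude carrier and an overall RMS signal-to-noise ratio of 5 on
#' a 64-channel montage sampled at 250 Hz.
#'
#' @param nChannels number of electrodes.
#' @param kTrue number of ground-truth microstate maps (>= 2).
#' @param fs sampling rate (Hz).
#' @param durationS epoch length (seconds).
#' @param dwellMeanMs mean dwell time per state (ms).
#' @param dwellShape gamma shape of the dwell distribution.
#' @param transitionWeights `kTrue x kTrue` nonnegative matrix with zero
#'   diagonal; rows are renormalized to successor probabilities. Default
#'   uniform over the other states.
#' @param snr RMS(signal) / RMS(noise); `Inf` for noise-free.
#' @param carrierHz frequency of the amplitude carrier (Hz).
#' @param seed integer RNG seed.
#' @return A list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nChannels = 64, kTrue = 4, fs = 250,
                          durationS = 20, dwellMeanMs = 60, dwellShape = 2,
                          transitionWeights = NULL, snr = 5,
                          carrierHz = 10, seed = 1) {
  if (kTrue < 2) stop("kTrue must be at least 2", call. = FALSE)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (is.null(transitionWeights)) {
    transitionWeights <- matrix(1, kTrue, kTrue)
    diag(transitionWeights) <- 0
  }
  transitionWeights <- as.matrix(transitionWeights)
  if (!all(dim(transitionWeights) == c(kTrue, kTrue))) {
    stop("transitionWeights must be kTrue x kTrue", call. = FALSE)
  }
  if (any(transitionWeights < 0) || any(diag(transitionWeights) != 0)) {
    stop("transitionWeights must be nonnegative with zero diagonal",
      call. = FALSE
    )
  }
  structure(
    list(
      nChannels = nChannels, kTrue = kTrue, fs = fs, durationS = durationS,
      dwellMeanMs = dwellMeanMs, dwellShape = dwellShape,
      transitionWeights = transitionWeights, snr = snr,
      carrierHz = carrierHz, seed = as.integer(seed)
    ),
    class = "SyntheticSpec"
  )
}

## Random smooth zero-mean orthogonal-ish topographies: orthonormalize
## against the constant vector, then lightly smooth along the channel index
## so maps are not exactly orthogonal (|corr| stays < 0.5).
.drawMaps <- function(nChannels, k) {
  X <- cbind(rep(1, nChannels), matrix(stats::rnorm(nChannels * k), nChannels, k))
  Q <- qr.Q(qr(X))[, 2:(k + 1), drop = FALSE]
  kern <- c(0.25, 0.5, 0.25)
  sm <- apply(Q, 2, function(v) {
    vv <- c(v[nChannels], v, v[1])
    stats::filter(vv, kern, sides = 2)[2:(nChannels + 1)]
  })
  sm <- sweep(sm, 2, colMeans(sm))
  sm <- sweep(sm, 2, sqrt(colSums(sm^2)), "/")
  t(sm) # k x channels
}

#' Generate ground-truth microstate topographies
#'
#' Draws `k` unit-norm, zero channel-mean maps that are mutually distinct by
#' construction (orthogonalization followed by light spatial smoothing keeps
#' pairwise |correlation| below 0.5).
#'
#' @param nChannels number of electrodes (must exceed `k`).
#' @param k number of maps.
#' @param seed RNG seed.
#' @return `k x nChannels` matrix, one map per row.
#' @export
generateMaps <- function(nChannels, k, seed = 1) {
  if (k >= nChannels) {
    stop("parameter error: k must be smaller than nChannels", call. = FALSE)
  }
  set.seed(seed)
  .drawMaps(nChannels, k)
}

.drawSequence <- function(spec) {
  W <- spec$transitionWeights
  if (any(rowSums(W) == 0)) {
    stop("parameter error: transitionWeights has an all-zero row",
      call. = FALSE
    )
  }
  P <- W / rowSums(W)
  n <- as.integer(round(spec$durationS * spec$fs))
  scale <- spec$dwellMeanMs / spec$dwellShape
  labels <- integer(n)
  pos <- 0L
  state <- sample.int(spec$kTrue, 1L)
  while (pos < n) {
    dwellMs <- stats::rgamma(1, shape = spec$dwellShape, scale = scale)
    len <- max(1L, as.integer(round(dwellMs / 1000 * spec$fs)))
    len <- min(len, n - pos)
    labels[(pos + 1L):(pos + len)] <- state
    pos <- pos + len
    state <- sample.int(spec$kTrue, 1L, prob = P[state, ])
  }
  labels
}

#' Generate a semi-Markov microstate state sequence
#'
#' Dwell times are gamma(`dwellShape`, scale = `dwellMeanMs / dwellShape`)
#' milliseconds, rounded to at least one sample; successors are drawn from
#' the renormalized rows of `transitionWeights`. A gamma (rather than
#' geometric) dwell distribution makes the sequence non-Markovian at the
#' sample level, which is exactly the structure the microstate complexity
#' measure is designed to be sensitive to.
#'
#' @param spec a [syntheticSpec()].
#' @return A [LabelSequence-class] of length `durationS * fs`.
#' @export
generateSequence <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  LabelSequence(.drawSequence(spec), fs = spec$fs, k = spec$kTrue)
}

.assembleEEG <- function(maps, labels, spec) {
  n <- length(labels)
  t <- (seq_len(n) - 1L) / spec$fs
  # per-dwell random carrier phase
  segStart <- c(1L, which(diff(labels) != 0L) + 1L)
  segId <- cumsum(seq_len(n) %in% segStart)
  phases <- stats::runif(length(segStart), 0, 2 * pi)
  a <- sin(2 * pi * spec$carrierHz * t + phases[segId])
  S <- t(maps[labels, , drop = FALSE]) * rep(a, each = ncol(maps))
  if (is.finite(spec$snr)) {
    N <- matrix(stats::rnorm(length(S)), nrow(S), ncol(S))
    sigma <- sqrt(mean(S^2)) / (spec$snr * sqrt(mean(N^2)))
    data <- S + sigma * N
  } else {
    data <- S
  }
  data <- sweep(data, 2, colMeans(data))
  data
}

#' Generate synthetic EEG with known microstate ground truth
#'
#' Builds `recording(t) = a(t) * map[state(t)] + noise`, where `a(t)` is a
#' carrier sinusoid whose phase is re-randomized at every state switch, and
#' i.i.d. Gaussian sensor noise is scaled so that RMS(signal)/RMS(noise)
#' equals `spec$snr`. The output is average-referenced.
#'
#' @param spec a [syntheticSpec()].
#' @param maps optional `kTrue x nChannels` map matrix; drawn from
#'   [generateMaps()] machinery when `NULL`.
#' @param sequence optional [LabelSequence-class]; drawn when `NULL`.
#' @param subjectId,group metadata for the embedded recording.
#' @return A list of class `"SyntheticGroundTruth"` with elements `maps`,
#'   `stateSequence` (a [LabelSequence-class]), `recording` (an
#'   [EEGRecording-class]) and `spec`.
#' @examples
#' gt <- generateEEG(syntheticSpec(nChannels = 16, durationS = 2, seed = 7))
#' gt$recording
#' @export
generateEEG <- function(spec, maps = NULL, sequence = NULL,
                        subjectId = "synthetic", group = "unknown") {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  if (is.null(maps)) {
    maps <- .drawMaps(spec$nChannels, spec$kTrue)
  }
  if (nrow(maps) != spec$kTrue) {
    stop("maps must have kTrue rows", call. = FALSE)
  }
  if (is.null(sequence)) {
    labels <- .drawSequence(spec)
  } else {
    labels <- stateLabels(sequence)
    if (any(labels > spec$kTrue)) {
      stop("sequence labels exceed kTrue", call. = FALSE)
    }
  }
  data <- .assembleEEG(maps, labels, spec)
  structure(
    list(
      maps = maps,
      stateSequence = LabelSequence(labels, fs = spec$fs, k = spec$kTrue),
      recording = EEGRecording(data, fs = spec$fs,
                               labels = paste0("ch", seq_len(spec$nChannels)),
                               subjectId = subjectId, group = group),
      spec = spec
    ),
    class = "SyntheticGroundTruth"
  )
}

#' Generate a synthetic two-feature cohort
#'
#' Draws Gaussian (theta relative power, microstate complexity) feature pairs
#' per diagnostic group, for exercising the classifier in isolation.
#'
#' @param nPerGroup named integer vector, subjects per group.
#' @param means list (one entry per group) of length-2 mean vectors
#'   `(thetaRP, C)`.
#' @param sds list of length-2 standard deviation vectors, all positive.
#' @param seed RNG seed.
#' @return A data.frame with columns `subject`, `group`, `thetaRP`, `C`.
#' @export
generateFeatureCohort <- function(nPerGroup, means, sds, seed = 1) {
  if (any(nPerGroup <= 0)) {
    stop("parameter error: group sizes must be positive", call. = FALSE)
  }
  if (any(unlist(sds) <= 0)) {
    stop("parameter error: sds must be positive", call. = FALSE)
  }
  groups <- names(nPerGroup)
  if (is.null(groups)) groups <- paste0("g", seq_along(nPerGroup))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(nPerGroup), function(i) {
    n <- nPerGroup[i]
    data.frame(
      subject = sprintf("%s_%02d", groups[i], seq_len(n)),
      group = groups[i],
      thetaRP = stats::rnorm(n, means[[i]][1], sds[[i]][1]),
      C = stats::rnorm(n, means[[i]][2], sds[[i]][2]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
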