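## Welch power spectral density and theta relative power -- the single
## spectral "slowing" feature combined with microstate complexity in the
## classifier.

## Welch PSD of one channel: Hamming-windowed segments, 50% overlap,
## one-sided density. Returns freq (Hz) and psd.
.welchPSD <- function(x, fs, segmentS = 2) {
  nper <- as.integer(round(segmentS * fs))
  nper <- min(nper, length(x))
  step <- max(1L, nper %/% 2L)
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))
  U <- sum(w^2)
  nf <- nper %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[1:nf]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nper %% 2L == 0L) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nper, psd = psd * dbl)
}

.bandPower <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (sum(sel) < 2) stop("band too narrow for the frequency resolution",
    call. = FALSE
  )
  pracma::trapz(freq[sel], psd[sel])
}

#' Theta relative power
#'
#' Welch power spectral density per channel (2 s Hamming segments, 50%
#' overlap), with relative theta power defined as the trapezoidal integral
#' of the PSD over the theta band divided by the integral over the total
#' band; the scalar feature is the mean over channels. Higher values index
#' spectral slowing of the EEG.
#'
#' @param rec an [EEGRecording-class] of at least `segmentS` seconds with
#'   `fs > 2 * total[2]`.
#' @param theta theta band edges in Hz (default 4-8).
#' @param total total band edges in Hz (default 1-30).
#' @param segmentS Welch segment length in seconds (default 2).
#' @return A list of class `"SpectralFeature"`: `thetaRP` (mean over
#'   channels, in `[0, 1]`), `perChannel`, `bandEdges`.
#' @examples
#' rec <- EEGRecording(matrix(rep(sin(2 * pi * 5 * seq(0, 8, by = 1/128)), 2),
#'                            2, byrow = TRUE), fs = 128)
#' thetaRelativePower(rec)$thetaRP # ~1: all power at 5 Hz
#' @export
thetaRelativePower <- function(rec, theta = c(4, 8), total = c(1, 30),
                               segmentS = 2) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (total[2] >= fs / 2) {
    stop("parameter error: total band extends to or beyond Nyquist",
      call. = FALSE
    )
  }
  if (theta[1] < total[1] || theta[2] > total[2]) {
    stop("theta band must lie within the total band", call. = FALSE)
  }
  if (nSamples(rec) < segmentS * fs) {
    stop("recording shorter than one Welch segment", call. = FALSE)
  }
  per <- apply(rec@data, 1, function(x) {
    sp <- .welchPSD(x, fs, segmentS = segmentS)
    tp <- .bandPower(sp$freq, sp$psd, total)
    if (tp <= 0) return(NA_real_)
    .bandPower(sp$freq, sp$psd, theta) / tp
  })
  structure(
    list(
      thetaRP = mean(per, na.rm = TRUE),
      perChannel = per,
      bandEdges = c(theta = theta, total = total)
    ),
    class = "SpectralFeature"
  )
}

#' Relative power in an arbitrary band
#'
#' Same estimator as [thetaRelativePower()] for any sub-band of the total
#' band (used e.g. to check that relative powers over a partition of the
#' total band sum to 1).
#'
#' @inheritParams thetaRelativePower
#' @param band band edges in Hz.
#' @return Mean relative power over channels.
#' @export
bandRelativePower <- function(rec, band, total = c(1, 30), segmentS = 2) {
  thetaRelativePower(rec, theta = band, total = total,
                     segmentS = segmentS)$thetaRP
}
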