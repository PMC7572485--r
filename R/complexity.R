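## Lempel-Ziv (LZ76) complexity of microstate transition sequences -- the
## package's central measure -- plus the two classical comparison measures:
## Omega-complexity (effective number of independent spatial components) and
## binarized time-series LZC.

#' Lempel-Ziv 1976 complexity of a symbol sequence
#'
#' Counts the number of words in the exhaustive left-to-right parsing of the
#' sequence: the current word is extended while it is reproducible from the
#' prior history (self-overlapping copies allowed); when extension fails the
#' word is closed (including the innovating symbol) and a new word starts.
#' The terminal word counts even if it is still reproducible. Conventions:
#' the empty sequence has complexity 0 and a single symbol has complexity 1.
#'
#' @param symbols an atomic vector over any alphabet, or a single character
#'   string (parsed per character).
#' @return Integer word count.
#' @examples
#' lz76Complexity("AAAA")     # 2: A | AAA
#' lz76Complexity("ABABABAB") # 3: A | B | ABABAB
#' @export
lz76Complexity <- function(symbols) {
  if (is.character(symbols) && length(symbols) == 1L && nchar(symbols) != 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  if (length(symbols) == 0L) return(0L)
  codes <- match(symbols, unique(symbols))
  .lz76_count(as.integer(codes))
}

#' Microstate sequence complexity (C)
#'
#' The complexity of microstate transitioning: by default each maximal
#' constant run of the label sequence is collapsed to a single symbol (the
#' transition sequence), and the LZ76 word count of that symbol stream is
#' returned. Because the measure makes no Markovian or stationarity
#' assumption, it is sensitive to higher-order and time-varying transition
#' structure that a transition-matrix (syntax) analysis cannot see:
#' repetitive transitioning gives low C, rich transitioning gives high C.
#'
#' @param seq a [LabelSequence-class] (or plain integer vector of labels).
#' @param collapseRuns collapse maximal constant runs before parsing
#'   (default `TRUE`).
#' @param normalize multiply by `log_k(n) / n` with `n` the parsed symbol
#'   count and `k` the observed alphabet size, making the expected value for
#'   a uniform random sequence approach 1 (default `FALSE`: raw word count).
#' @return Numeric complexity. A collapsed single-class sequence is
#'   degenerate: C = 1 with attribute `degenerate = TRUE` (and `NA` when
#'   normalization is requested, since the alphabet has one symbol).
#' @export
microstateLZC <- function(seq, collapseRuns = TRUE, normalize = FALSE) {
  labels <- if (is(seq, "LabelSequence")) stateLabels(seq) else as.integer(seq)
  if (length(labels) == 0L) stop("empty sequence", call. = FALSE)
  symbols <- if (collapseRuns) rle(labels)$values else labels
  C <- as.numeric(.lz76_count(as.integer(match(symbols, unique(symbols)))))
  k <- length(unique(symbols))
  degenerate <- k < 2L
  if (normalize) {
    n <- length(symbols)
    C <- if (degenerate) NA_real_ else C * (log(n) / log(k)) / n
  }
  if (degenerate) attr(C, "degenerate") <- TRUE
  C
}

#' Binarized time-series Lempel-Ziv complexity
#'
#' The classical univariate EEG complexity measure: each channel is
#' binarized at its median (value > median maps to 1), the LZ76 word count
#' of the binary string is normalized by `n / log2(n)`, and the result is
#' averaged over channels. Median binarization makes the measure invariant
#' to channel scaling; a constant channel degenerates to the all-zeros
#' string (complexity 2).
#'
#' @param rec an [EEGRecording-class] with at least 2 samples.
#' @return Mean normalized LZC over channels.
#' @export
timeseriesLZC <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  n <- nSamples(rec)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  vals <- apply(rec@data, 1, function(x) {
    b <- as.integer(x > stats::median(x))
    .lz76_count(b) * log2(n) / n
  })
  mean(vals)
}

#' Omega-complexity of a multichannel recording
#'
#' The exponential of the entropy of the normalized eigenvalue spectrum of
#' the channel covariance matrix: an effective count of independent spatial
#' components, ranging from 1 (a single spatial pattern modulated in time)
#' to the number of channels (spatially white data).
#'
#' @param rec an average-referenced [EEGRecording-class] with more samples
#'   than channels.
#' @return Omega, in `[1, nChannels]`.
#' @export
omegaComplexity <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nSamples(rec) <= nChannels(rec)) {
    stop("need more samples than channels", call. = FALSE)
  }
  C <- stats::cov(t(rec@data))
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  tot <- sum(lam)
  if (tot <= 0) stop("rank-0 data: all channels constant", call. = FALSE)
  lam <- lam / tot
  lam <- lam[lam > 0]
  exp(-sum(lam * log(lam)))
}

#' All complexity measures for one subject
#'
#' Convenience wrapper computing the microstate complexity `C` (raw and
#' normalized) of a label sequence along with the classical comparison
#' measures on the underlying recording.
#'
#' @param rec an [EEGRecording-class].
#' @param seq the backfitted [LabelSequence-class] for `rec`.
#' @param collapseRuns,normalize passed to [microstateLZC()]; `normalize`
#'   selects which variant is reported as `C`.
#' @return A list of class `"ComplexityResult"`: `C`, `CNorm`, `omega`,
#'   `tsLZC`, and the configuration used.
#' @export
complexityProfile <- function(rec, seq, collapseRuns = TRUE,
                              normalize = FALSE) {
  raw <- microstateLZC(seq, collapseRuns = collapseRuns, normalize = FALSE)
  nrm <- microstateLZC(seq, collapseRuns = collapseRuns, normalize = TRUE)
  structure(
    list(
      C = if (normalize) as.numeric(nrm) else as.numeric(raw),
      CRaw = as.numeric(raw),
      CNorm = as.numeric(nrm),
      omega = omegaComplexity(rec),
      tsLZC = timeseriesLZC(rec),
      config = list(collapseRuns = collapseRuns, normalize = normalize)
    ),
    class = "ComplexityResult"
  )
}
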