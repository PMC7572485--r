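# Independent oracles and small fixture builders used across the suite.

# Brute-force LZ76 parser straight from the definition: extend the current
# word while it occurs as a substring of the history up to the previous
# position (self-overlap allowed); close it (including the innovating
# symbol) when it does not; the terminal word always counts.
lz76Oracle <- function(symbols) {
  if (is.character(symbols) && length(symbols) == 1L && nchar(symbols) > 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  n <- length(symbols)
  if (n == 0L) return(0L)
  isSub <- function(pat, txt) {
    lp <- length(pat)
    lt <- length(txt)
    if (lp > lt) return(FALSE)
    for (st in seq_len(lt - lp + 1L)) {
      if (all(txt[st:(st + lp - 1L)] == pat)) return(TRUE)
    }
    FALSE
  }
  count <- 0L
  w <- 1L
  while (w <= n) {
    j <- w
    repeat {
      Q <- symbols[w:j]
      if (!isSub(Q, symbols[seq_len(j - 1L)])) {
        count <- count + 1L
        w <- j + 1L
        break
      }
      if (j == n) {
        count <- count + 1L
        w <- n + 1L
        break
      }
      j <- j + 1L
    }
  }
  count
}

# All permutations of 1..n, built by insertion (independent of the package's
# recursive generator).
allPermsOracle <- function(n) {
  out <- list(1L)
  if (n > 1) {
    for (m in 2:n) {
      nxt <- list()
      for (p in out) {
        for (pos in 0:(m - 1L)) {
          nxt[[length(nxt) + 1L]] <- append(p, m, after = pos)
        }
      }
      out <- nxt
    }
  }
  do.call(rbind, out)
}

# A recording whose every sample is a scaled copy of one of the given maps.
mapDrivenRecording <- function(maps, labels, amplitudes, fs = 250) {
  data <- t(maps[labels, , drop = FALSE]) * rep(amplitudes, each = ncol(maps))
  EEGRecording(data, fs = fs)
}

whiteNoiseRecording <- function(nch, n, fs, seed = 1) {
  set.seed(seed)
  EEGRecording(matrix(rnorm(nch * n), nch, n), fs = fs)
}
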