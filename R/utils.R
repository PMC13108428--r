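#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor fft kmeans median predict quantile rnorm runif
#'   sd spline var complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

# Derive a reproducible child seed from a parent seed and a stream counter.
# Keeps every stage of the pipeline on its own deterministic RNG stream while
# all randomness flows from a single user-facing seed.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in seq_len(stream %% 7 + 1)) s <- (s * 48271) %% 2147483647
  as.integer((s + 2654435761 * (as.double(stream) %% 1024)) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged-periodogram PSD with Hann-windowed, 50\%-overlapping segments.
#' Used to quantify heart-rate oscillation power in the VLF/LF/HF bands; the
#' segment length is shrunk (with a warning) when the record is shorter than
#' one segment.
#'
#' @param x numeric vector, evenly sampled.
#' @param fs_hz sampling rate in Hz.
#' @param seg_len_s segment length in seconds (default 60).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq_hz` and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs_hz, seg_len_s = 60, overlap = 0.5) {
  check_number(fs_hz, "fs_hz", lower = 1e-9)
  n <- length(x)
  if (n < 8) stopf("welch_psd: need at least 8 samples, got %d", n)
  nseg <- round(seg_len_s * fs_hz)
  if (nseg > n) {
    warnf("welch_psd: record (%d samples) shorter than one %g-s segment; using full record", n, seg_len_s)
    nseg <- n
  }
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    sp <- abs(fft(seg))^2 / (fs_hz * u)
    p <- sp[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when nseg is even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq_hz = (seq_len(nf) - 1) * fs_hz / nseg, psd = acc / length(starts))
}

# Trapezoidal integral of a PSD over [lo, hi] Hz.
band_power <- function(freq, psd, lo, hi) {
  keep <- freq >= lo & freq <= hi
  if (!any(keep)) return(0)
  if (sum(keep) == 1) {
    # single resolvable bin (short record): rectangle approximation
    df <- if (length(freq) > 1) freq[2] - freq[1] else hi - lo
    return(psd[keep] * min(df, hi - lo))
  }
  f <- freq[keep]; p <- psd[keep]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
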