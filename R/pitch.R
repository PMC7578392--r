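#' Pitch search range for a speaker class
#'
#' Floor/ceiling of the f0 search band, per register class: 100-450 Hz for
#' children, 100-400 Hz for teenage girls, 50-350 Hz for teenage boys.
#' Adult partners default to the nearest stated class band (females
#' 100-400 Hz, males 50-350 Hz) and can be overridden.
#'
#' @param speaker_class One of [speaker_classes()].
#' @param floor,ceiling Optional overrides in Hz (0 < floor < ceiling).
#' @return List with `speaker_class`, `floor`, `ceiling`.
#' @export
speaker_class_range <- function(speaker_class, floor = NULL, ceiling = NULL) {
  defaults <- list(
    child        = c(100, 450),
    teen_girl    = c(100, 400),
    teen_boy     = c(50, 350),
    adult_female = c(100, 400),
    adult_male   = c(50, 350)
  )
  speaker_class <- match.arg(speaker_class, names(defaults))
  band <- defaults[[speaker_class]]
  if (!is.null(floor)) band[1L] <- floor
  if (!is.null(ceiling)) band[2L] <- ceiling
  if (!(band[1L] > 0 && band[1L] < band[2L])) stop("need 0 < floor < ceiling")
  list(speaker_class = speaker_class, floor = band[1L], ceiling = band[2L])
}

#' Estimate frame-wise f0 by short-time autocorrelation
#'
#' A windowed, FFT-based normalised-autocorrelation pitch tracker: every
#' `step` seconds a window of about three periods of the band floor is
#' mean-removed, its autocorrelation is computed, and the lag of the highest
#' peak inside `[rate/ceiling, rate/floor]` gives the f0 candidate (with
#' parabolic peak interpolation). Frames whose peak normalised
#' autocorrelation falls below `voicing_threshold`, or with negligible
#' energy, are marked unvoiced.
#'
#' @param samples Numeric vector of mono PCM samples.
#' @param rate Sampling rate in Hz; must be at least twice the band ceiling.
#' @param range A [speaker_class_range()] (or list with `floor`/`ceiling`).
#' @param step Hop in seconds (default 0.010).
#' @param voicing_threshold Minimum normalised autocorrelation peak for a
#'   frame to count as voiced (default 0.45).
#' @return An [f0_track()].
#' @export
estimate_f0 <- function(samples, rate, range, step = 0.010,
                        voicing_threshold = 0.45) {
  if (rate < 2 * range$ceiling) {
    stop("sampling rate ", rate, " Hz is below twice the ceiling (",
         2 * range$ceiling, " Hz)")
  }
  samples <- as.numeric(samples)
  win <- ceiling(3 / range$floor * rate)       # ~3 periods of the floor
  if (length(samples) < win) {
    return(f0_track("speaker", numeric(0), numeric(0), logical(0), step = step))
  }
  # exact time grid; frame start samples are rounded onto it so the track
  # keeps a strictly regular step for any sampling rate
  nframes <- floor(((length(samples) - win) / rate) / step) + 1L
  times <- (seq_len(nframes) - 1L) * step
  starts <- pmin(round(times * rate) + 1L, length(samples) - win + 1L)
  lag_min <- max(2L, floor(rate / range$ceiling))
  lag_max <- ceiling(rate / range$floor)
  nfft <- 2^ceiling(log2(2L * win))
  # frame matrix: one column per frame, mean-removed
  idx <- outer(seq_len(win) - 1L, starts, `+`)
  fm <- matrix(samples[idx], nrow = win)
  fm <- sweep(fm, 2L, colMeans(fm))
  spec <- stats::mvfft(rbind(fm, matrix(0, nfft - win, nframes)))
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  f0 <- numeric(nframes)
  voiced <- logical(nframes)
  lags <- lag_min:min(lag_max, win - 1L)
  for (i in seq_len(nframes)) {
    if (r0[i] <= .Machine$double.eps * win) next
    r <- ac[lags + 1L, i] / r0[i]
    j <- which.max(r)
    peak <- r[j]
    if (peak < voicing_threshold) next
    lag <- lags[j]
    # parabolic interpolation around the peak
    if (j > 1L && j < length(lags)) {
      num <- r[j - 1L] - r[j + 1L]
      den <- r[j - 1L] - 2 * r[j] + r[j + 1L]
      if (abs(den) > 0) lag <- lag + 0.5 * num / den
    }
    cand <- rate / lag
    if (cand >= range$floor && cand <= range$ceiling) {
      f0[i] <- cand
      voiced[i] <- TRUE
    }
  }
  f0_track("speaker", times, f0, voiced, step = step)
}

#' Render a pitch track as a harmonic waveform
#'
#' Synthesises a phase-continuous sum of three harmonics (amplitudes 1,
#' 0.5, 0.25) following the track's frame-wise f0; unvoiced frames are
#' silent. Intended for end-to-end tests of the pitch estimator.
#'
#' @param track An [f0_track()].
#' @param rate Output sampling rate in Hz.
#' @return List with `samples` and `rate`.
#' @export
render_waveform <- function(track, rate = 22050) {
  stopifnot(inherits(track, "f0_track"))
  n_per <- round(track$step * rate)
  inst_f0 <- rep(ifelse(track$voiced, track$f0, 0), each = n_per)
  phase <- 2 * pi * cumsum(inst_f0) / rate
  gate <- as.numeric(inst_f0 > 0)
  samples <- gate * (sin(phase) + 0.5 * sin(2 * phase) + 0.25 * sin(3 * phase))
  list(samples = samples, rate = rate)
}
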