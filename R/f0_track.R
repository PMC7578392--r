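#' Frame-wise fundamental-frequency track
#'
#' A regular 10 ms (by default) grid of f0 estimates for one speaker, with a
#' per-frame voicing mask. `f0` must be positive wherever `voiced` is
#' `TRUE`; frame times must be equally spaced at `step` (to 1e-6 s).
#'
#' @param speaker_id Character scalar.
#' @param times Frame times in seconds, monotonically increasing.
#' @param f0 f0 in Hz per frame (any value where unvoiced; > 0 where voiced).
#' @param voiced Logical voicing mask per frame.
#' @param step Frame step in seconds (default 0.010).
#' @return An object of class `f0_track`.
#' @export
f0_track <- function(speaker_id, times, f0, voiced, step = 0.010) {
  stopifnot(is.character(speaker_id), length(speaker_id) == 1L)
  times <- as.numeric(times); f0 <- as.numeric(f0); voiced <- as.logical(voiced)
  n <- length(times)
  if (length(f0) != n || length(voiced) != n) {
    stop("times, f0 and voiced must have equal length")
  }
  if (n > 1L) {
    d <- diff(times)
    if (any(d <= 0)) stop("frame times must be strictly increasing")
    if (any(abs(d - step) > 1e-6)) {
      stop("frame times must be equally spaced at step = ", step,
           " (tolerance 1e-6 s)")
    }
  }
  if (any(voiced & !(is.finite(f0) & f0 > 0))) {
    stop("f0 must be finite and > 0 on every voiced frame")
  }
  structure(
    list(speaker_id = speaker_id, step = step, times = times,
         f0 = f0, voiced = voiced),
    class = "f0_track"
  )
}

#' @export
print.f0_track <- function(x, ...) {
  cat(sprintf("<f0_track> %s: %d frames @ %.3f s step, %d voiced\n",
              x$speaker_id, length(x$times), x$step, sum(x$voiced)))
  invisible(x)
}

#' Read a pitch track from CSV or Praat PitchTier text
#'
#' CSV input needs columns `time`, `f0` and `voiced`; rows where `f0` is 0,
#' empty or `NA` are treated as unvoiced regardless of the `voiced` column.
#' Lines starting with `#` are skipped. A Praat text PitchTier (which lists
#' only voiced points) is resampled onto a regular grid at `step`.
#'
#' @param path File path (CSV or PitchTier; sniffed from the header line).
#' @param speaker_id Speaker identifier for the returned track.
#' @param step Expected frame step in seconds.
#' @return An [f0_track()].
#' @export
read_f0_track <- function(path, speaker_id = tools::file_path_sans_ext(basename(path)),
                          step = 0.010) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("ooTextFile", first)) {
    return(read_pitchtier(path, speaker_id = speaker_id, step = step))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("time", "f0", "voiced")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("pitch-track CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(f0_track(speaker_id, numeric(0), numeric(0), logical(0), step = step))
  }
  if (is.unsorted(df$time, strictly = TRUE)) stop("pitch-track times must be sorted and unique")
  f0 <- suppressWarnings(as.numeric(df$f0))
  voiced <- as.logical(df$voiced) & !is.na(f0) & f0 > 0
  f0[is.na(f0)] <- 0
  if (any(as.logical(df$voiced) & !is.na(f0) & f0 < 0)) {
    stop("negative f0 on a voiced frame")
  }
  f0_track(speaker_id, df$time, f0, voiced, step = step)
}

#' Read a Praat text PitchTier onto a regular frame grid
#'
#' PitchTier files store (time, f0) points for voiced frames only. Points
#' are snapped to the nearest frame of a regular grid covering
#' `[xmin, xmax)`; frames with no point are unvoiced.
#'
#' @inheritParams read_f0_track
#' @return An [f0_track()].
#' @export
read_pitchtier <- function(path, speaker_id = tools::file_path_sans_ext(basename(path)),
                           step = 0.010) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("PitchTier", lines[1:3]))) {
    stop("not a PitchTier file: ", path)
  }
  nums <- function(key) {
    hits <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    as.numeric(sub(".*=\\s*", "", hits))
  }
  if (any(grepl("^\\s*points\\s*\\[", lines))) {
    # long format
    xmin <- nums("xmin")[1L]; xmax <- nums("xmax")[1L]
    t_pts <- nums("number"); f_pts <- nums("value")
  } else {
    body <- trimws(lines[-(1:2)])
    body <- suppressWarnings(as.numeric(body[nzchar(body)]))
    body <- body[!is.na(body)]
    xmin <- body[1L]; xmax <- body[2L]
    n <- as.integer(body[3L])
    rest <- body[-(1:3)]
    t_pts <- rest[seq(1L, by = 2L, length.out = n)]
    f_pts <- rest[seq(2L, by = 2L, length.out = n)]
  }
  times <- seq(xmin, xmax - step / 2, by = step)
  f0 <- numeric(length(times))
  voiced <- logical(length(times))
  if (length(t_pts) > 0L) {
    idx <- pmin(pmax(round((t_pts - xmin) / step) + 1L, 1L), length(times))
    f0[idx] <- f_pts
    voiced[idx] <- f_pts > 0
  }
  f0_track(speaker_id, times, f0, voiced, step = step)
}

#' Write a pitch track as CSV
#'
#' Columns `time`, `f0`, `voiced`; an optional `#`-prefixed header records
#' provenance (e.g. a simulation seed) and is skipped on reading.
#'
#' @param track An [f0_track()].
#' @param path Output path.
#' @param header Optional character vector of comment lines (without `#`).
#' @export
write_f0_track <- function(track, path, header = NULL) {
  stopifnot(inherits(track, "f0_track"))
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("time,f0,voiced", con)
  writeLines(sprintf("%.6f,%.6f,%d", track$times, track$f0,
                     as.integer(track$voiced)), con)
  invisible(path)
}

# frame membership in a set of [start, end) intervals, 1e-9 s tolerance
frames_in_intervals <- function(times, starts, ends) {
  inside <- logical(length(times))
  for (i in seq_along(starts)) {
    inside <- inside | (times >= starts[i] - 1e-9 & times < ends[i] - 1e-9)
  }
  inside
}

#' Restrict a pitch track to linguistically meaningful speech
#'
#' Unvoices every frame whose time falls outside the union of the tier's
#' `is_linguistic` intervals, so that laughter, humming, vocal stereotypy
#' and silence never contribute to the entrainment features. Membership is
#' half-open `[start, end)`: a frame exactly at an interval's end belongs to
#' whatever follows, never to the interval itself. Idempotent, and never
#' increases the number of voiced frames.
#'
#' @param track An [f0_track()].
#' @param tier The same speaker's [speaker_tier()].
#' @return A filtered [f0_track()].
#' @export
filter_linguistic <- function(track, tier) {
  stopifnot(inherits(track, "f0_track"), inherits(tier, "speaker_tier"))
  iv <- tier$intervals[tier$intervals$is_linguistic, , drop = FALSE]
  keep <- frames_in_intervals(track$times, iv$start, iv$end)
  track$voiced <- track$voiced & keep
  track
}
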