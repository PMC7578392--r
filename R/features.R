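#' Partition a conversation timeline into first and last thirds
#'
#' The analysis compares f0 summaries from the first third of elapsed
#' conversation time against the last third; the middle third is unused.
#' Windows are half-open: first = `[0, D/3)`, last = `[2D/3, D)`.
#'
#' @param duration Conversation duration in seconds (> 0).
#' @return List of two windows, each `list(label, start, end)`.
#' @export
partition_thirds <- function(duration) {
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0) {
    stop("duration must be a single positive number")
  }
  list(
    first = list(label = "first", start = 0, end = duration / 3),
    last  = list(label = "last", start = 2 * duration / 3, end = duration)
  )
}

#' Summarise voiced f0 within a time window
#'
#' Computes the arithmetic mean and interquartile range (Q3 - Q1, linear
#' interpolation quantiles) of the voiced frames falling in `[start, end)`.
#' When fewer than `min_frames` voiced frames are available the result is
#' flagged unusable instead of raising an error: a sparse third cannot
#' support a stable mean or IQR.
#'
#' @param track A linguistically filtered [f0_track()].
#' @param window One element of [partition_thirds()].
#' @param min_frames Minimum voiced frames for a usable summary (default
#'   50, i.e. 0.5 s of voicing at a 10 ms step).
#' @return List with `mean_f0`, `iqr_f0`, `n_frames`, `usable`.
#' @export
third_features <- function(track, window, min_frames = 50) {
  stopifnot(inherits(track, "f0_track"))
  sel <- track$voiced & frames_in_intervals(track$times, window$start, window$end)
  x <- track$f0[sel]
  n <- length(x)
  if (n < min_frames) {
    return(list(mean_f0 = NA_real_, iqr_f0 = NA_real_, n_frames = n,
                usable = FALSE))
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  list(mean_f0 = mean(x), iqr_f0 = q[2L] - q[1L], n_frames = n, usable = TRUE)
}

#' Build the dyad's start/end feature points
#'
#' For each feature k (k = 1 mean f0, k = 2 f0 IQR) this composes
#' [partition_thirds()] and [third_features()] into the two points the
#' entrainment geometry works on: the start point
#' `S = (participant, partner)` from the first third and the end point
#' `E = (participant, partner)` from the last third, all in Hz. The
#' participant is always axis 1 and the partner axis 2. A feature is
#' usable only if all four of its window summaries are.
#'
#' @param track_participant,track_partner Linguistically filtered
#'   [f0_track()]s of the two speakers.
#' @param duration Conversation duration in seconds.
#' @param min_frames Passed to [third_features()].
#' @return An object of class `dyad_features`: for each of `mean_f0` and
#'   `iqr_f0`, a list with points `S`, `E`, per-window frame counts and a
#'   `usable` flag.
#' @export
build_dyad_features <- function(track_participant, track_partner, duration,
                                min_frames = 50) {
  windows <- partition_thirds(duration)
  summarise <- function(track) {
    lapply(windows, function(w) third_features(track, w, min_frames = min_frames))
  }
  p <- summarise(track_participant)
  q <- summarise(track_partner)
  one_k <- function(field) {
    usable <- p$first$usable && p$last$usable && q$first$usable && q$last$usable
    list(
      S = c(p$first[[field]], q$first[[field]]),
      E = c(p$last[[field]], q$last[[field]]),
      n_frames = c(participant_first = p$first$n_frames,
                   participant_last = p$last$n_frames,
                   partner_first = q$first$n_frames,
                   partner_last = q$last$n_frames),
      usable = usable
    )
  }
  structure(
    list(mean_f0 = one_k("mean_f0"), iqr_f0 = one_k("iqr_f0"),
         duration = duration,
         speakers = c(track_participant$speaker_id, track_partner$speaker_id)),
    class = "dyad_features"
  )
}

#' @export
print.dyad_features <- function(x, ...) {
  cat("<dyad_features> participant =", x$speakers[1L],
      ", partner =", x$speakers[2L], "\n")
  for (k in c("mean_f0", "iqr_f0")) {
    f <- x[[k]]
    if (f$usable) {
      cat(sprintf("  %-7s S = (%.2f, %.2f)  E = (%.2f, %.2f) Hz\n",
                  k, f$S[1L], f$S[2L], f$E[1L], f$E[2L]))
    } else {
      cat(sprintf("  %-7s unusable (insufficient voiced frames)\n", k))
    }
  }
  invisible(x)
}
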