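#' Reference line in the joint f0 plane
#'
#' Entrainment is scored against a line through the origin of the
#' (participant, partner) f0 plane: the matching line l1 (slope 1, both
#' speakers at the same f0) or the half-matching line l2 (slope 1/2, one
#' speaker an octave below the other). For l2 the speaker with the lower
#' register must sit on the axis whose values are halved; `swap_axes`
#' records when that speaker is the participant (axis 1), in which case
#' points are swapped internally before the distance formula is applied.
#'
#' @param slope Positive line slope; 1 for l1, 0.5 for l2.
#' @param swap_axes Swap point coordinates before measuring (used to place
#'   the lower-register speaker on the halved axis).
#' @param selection_reason Free-text record of why the line was chosen.
#' @return An object of class `reference_line`.
#' @export
reference_line <- function(slope, swap_axes = FALSE, selection_reason = "") {
  stopifnot(is.numeric(slope), length(slope) == 1L, slope > 0)
  structure(list(slope = slope, swap_axes = isTRUE(swap_axes),
                 selection_reason = selection_reason),
            class = "reference_line")
}

# dyads pairing these two classes use the octave (half-matching) line
uses_half_matching <- function(class_a, class_b) {
  setequal(c(class_a, class_b), c("teen_boy", "adult_female"))
}

#' Choose the dyad's reference line from the speaker classes
#'
#' The half-matching line l2 (slope 1/2) is used only when an adult female
#' partner converses with a teenage boy — the pairing whose registers sit
#' about an octave apart; every other pairing, including children with
#' adult females, uses the matching line l1 (slope 1). The lower-register
#' speaker (the teen boy) is placed on the halved axis regardless of
#' whether he is the participant or the partner.
#'
#' @param class_participant,class_partner Speaker classes
#'   (see [speaker_classes()]).
#' @param override Optional slope that wins over the class rule.
#' @return A [reference_line()].
#' @export
select_reference_line <- function(class_participant, class_partner,
                                  override = NULL) {
  if (!is.null(override)) {
    return(reference_line(override, selection_reason = "override"))
  }
  if (uses_half_matching(class_participant, class_partner)) {
    reference_line(0.5, swap_axes = (class_participant == "teen_boy"),
                   selection_reason = "adult_female/teen_boy dyad: half-matching line l2")
  } else {
    reference_line(1.0,
                   selection_reason = "matching line l1")
  }
}

#' Perpendicular distance from a point to a reference line
#'
#' Minimum Euclidean distance from `(x, y)` to the line `y = m x` through
#' the origin: `|m x - y| / sqrt(m^2 + 1)`, after any internal axis swap
#' the line carries.
#'
#' @param point Numeric length-2 vector `(axis1, axis2)` in Hz.
#' @param line A [reference_line()].
#' @return Distance in Hz (>= 0).
#' @export
point_to_line_distance <- function(point, line) {
  stopifnot(inherits(line, "reference_line"), length(point) == 2L,
            all(is.finite(point)))
  if (line$swap_axes) point <- rev(point)
  m <- line$slope
  abs(m * point[1L] - point[2L]) / sqrt(m^2 + 1)
}

feature_points <- function(feat, k) {
  k <- match.arg(k, c("mean_f0", "iqr_f0"))
  f <- feat[[k]]
  if (!isTRUE(f$usable)) {
    stop("feature '", k, "' is unusable for this dyad (insufficient voiced frames)")
  }
  f
}

#' Change in entrainment between conversation thirds
#'
#' `delta_ent = d1 - d2`, where d1 and d2 are the perpendicular distances
#' from the dyad's start and end feature points to the reference line.
#' Positive values mean the speakers moved closer to the line
#' (convergence); negative values mean divergence.
#'
#' @param feat A [build_dyad_features()] result.
#' @param line A [reference_line()].
#' @param k Feature: `"mean_f0"` or `"iqr_f0"`.
#' @param min_over_lines Sensitivity option: measure each point against the
#'   nearer of l1 and l2 instead of the single selected line.
#' @return Delta entrainment in Hz.
#' @export
delta_entrainment <- function(feat, line, k = "mean_f0",
                              min_over_lines = FALSE) {
  f <- feature_points(feat, k)
  dist <- function(p) {
    if (min_over_lines) {
      min(point_to_line_distance(p, line),
          point_to_line_distance(p, reference_line(
            if (line$slope == 1) 0.5 else 1, swap_axes = line$swap_axes)))
    } else {
      point_to_line_distance(p, line)
    }
  }
  dist(f$S) - dist(f$E)
}

#' Per-speaker share of the dyad's total f0 change
#'
#' Responsibility splits the total along-axis change between the two
#' speakers: `resp1 = d3 / (d3 + d4)` and `resp2 = d4 / (d3 + d4)`, where
#' `d3 = |S1e - S1s|` and `d4 = |S2e - S2s|` are each speaker's absolute
#' change in the feature between the first and last thirds. When neither
#' speaker moved at all (`d3 + d4 = 0`) the split is declared degenerate
#' and reported as an even (0.5, 0.5).
#'
#' @param d3,d4 Absolute per-speaker feature changes in Hz (>= 0). Either
#'   pass these directly, or pass a `dyad_features` object as `d3` together
#'   with `k` to have them measured from the feature points.
#' @param k Feature name, used when `d3` is a `dyad_features` object.
#' @return List with `resp1`, `resp2`, `d3`, `d4`, `degenerate`.
#' @export
speaker_responsibility <- function(d3, d4 = NULL, k = "mean_f0") {
  if (inherits(d3, "dyad_features")) {
    f <- feature_points(d3, k)
    d3 <- abs(f$E[1L] - f$S[1L])
    d4 <- abs(f$E[2L] - f$S[2L])
  }
  stopifnot(is.numeric(d3), is.numeric(d4), d3 >= 0, d4 >= 0)
  total <- d3 + d4
  if (total == 0) {
    return(list(resp1 = 0.5, resp2 = 0.5, d3 = d3, d4 = d4, degenerate = TRUE))
  }
  list(resp1 = d3 / total, resp2 = d4 / total, d3 = d3, d4 = d4,
       degenerate = FALSE)
}

#' Signed entrainment contribution
#'
#' A speaker's responsibility carrying the direction of the dyad's change:
#' `sign(delta_ent) * resp`. A speaker responsible for 0.4 of the change in
#' a converging dyad scores +0.4; the same share of a diverging dyad scores
#' -0.4; exactly zero change scores 0.
#'
#' @param delta_ent Dyad-level entrainment change in Hz.
#' @param resp Speaker responsibility in `[0, 1]`.
#' @return Signed fraction in `[-1, 1]`.
#' @export
signed_contribution <- function(delta_ent, resp) {
  stopifnot(resp >= 0, resp <= 1)
  sign(delta_ent) * resp
}

#' Entrainment contribution adjusted for conversation-level magnitude
#'
#' `delta_ent * resp`, in Hz: a speaker's share of the dyad's entrainment
#' change scaled by how much change there actually was, so a large share of
#' a negligible change stays small. The two speakers' adjusted
#' contributions always sum to `delta_ent`.
#'
#' @inheritParams signed_contribution
#' @return Adjusted contribution in Hz.
#' @export
adjusted_contribution <- function(delta_ent, resp) {
  stopifnot(resp >= 0, resp <= 1)
  delta_ent * resp
}

#' Classify a dyad's entrainment change
#'
#' Changes of 1 Hz or less in magnitude (the maintenance band) count as
#' maintenance; larger positive changes as convergence; larger negative
#' changes as divergence. The band is inclusive on both sides.
#'
#' @param delta_ent Entrainment change(s) in Hz (vectorised).
#' @param maintenance_band Half-width of the maintenance band in Hz.
#' @return Character vector in `{"convergence", "maintenance", "divergence"}`.
#' @export
classify_entrainment <- function(delta_ent, maintenance_band = 1.0) {
  stopifnot(all(is.finite(delta_ent)), maintenance_band >= 0)
  out <- rep("maintenance", length(delta_ent))
  out[delta_ent > maintenance_band] <- "convergence"
  out[delta_ent < -maintenance_band] <- "divergence"
  out
}

#' Count converging conversations
#'
#' Counts dyads whose entrainment change strictly exceeds the convergence
#' threshold (default: more than 2 Hz).
#'
#' @param delta_ent Vector of dyad-level entrainment changes in Hz.
#' @param threshold Convergence threshold in Hz (strict).
#' @return List with `count` and `proportion`.
#' @export
count_converging <- function(delta_ent, threshold = 2.0) {
  if (length(delta_ent) == 0L) stop("need at least one dyad")
  n <- sum(delta_ent > threshold)
  list(count = n, proportion = n / length(delta_ent))
}

#' Full entrainment result for one dyad and one feature
#'
#' Composes the geometric measures into the complete per-dyad record: the
#' start/end distances d1 and d2 and their difference `delta_ent`; each
#' speaker's along-axis change d3/d4, responsibility, signed contribution
#' and adjusted contribution; the classification; and an auxiliary raw-gap
#' change `delta_gap = |S1s - S2s| - |S1e - S2e|` (the change in plain f0
#' separation, exported alongside the perpendicular-distance measure).
#'
#' @param feat A [build_dyad_features()] result.
#' @param line A [reference_line()].
#' @param k Feature: `"mean_f0"` or `"iqr_f0"`.
#' @param maintenance_band Passed to [classify_entrainment()].
#' @param min_over_lines Passed to [delta_entrainment()].
#' @return A one-row [tibble::tibble()] with all measures.
#' @export
dyad_entrainment <- function(feat, line, k = "mean_f0",
                             maintenance_band = 1.0,
                             min_over_lines = FALSE) {
  f <- feature_points(feat, k)
  dist <- function(p) {
    d <- point_to_line_distance(p, line)
    if (!min_over_lines) return(d)
    min(d, point_to_line_distance(p, reference_line(
      if (line$slope == 1) 0.5 else 1, swap_axes = line$swap_axes)))
  }
  d1 <- dist(f$S)
  d2 <- dist(f$E)
  delta <- d1 - d2
  resp <- speaker_responsibility(abs(f$E[1L] - f$S[1L]), abs(f$E[2L] - f$S[2L]))
  tibble::tibble(
    k = k,
    d1 = d1, d2 = d2, delta_ent = delta,
    d3 = resp$d3, d4 = resp$d4,
    resp1 = resp$resp1, resp2 = resp$resp2,
    resp_degenerate = resp$degenerate,
    contribution1 = signed_contribution(delta, resp$resp1),
    contribution2 = signed_contribution(delta, resp$resp2),
    adjusted1 = adjusted_contribution(delta, resp$resp1),
    adjusted2 = adjusted_contribution(delta, resp$resp2),
    classification = classify_entrainment(delta, maintenance_band),
    delta_gap = abs(f$S[1L] - f$S[2L]) - abs(f$E[1L] - f$E[2L]),
    line_slope = line$slope
  )
}
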