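# shared fixtures and independent oracles

# a minimal two-tier long-format TextGrid
make_textgrid_text <- function(intervals_p = list(c(0, 1, "hello")),
                               intervals_q = list(c(1, 2, "hi there")),
                               duration = 10) {
  fmt_iv <- function(ivs) {
    out <- character(0)
    for (i in seq_along(ivs)) {
      iv <- ivs[[i]]
      out <- c(out,
        sprintf("        intervals [%d]:", i),
        sprintf("            xmin = %s", iv[1]),
        sprintf("            xmax = %s", iv[2]),
        sprintf("            text = \"%s\"", iv[3]))
    }
    out
  }
  tier <- function(j, name, ivs) {
    c(sprintf("    item [%d]:", j),
      "        class = \"IntervalTier\"",
      sprintf("        name = \"%s\"", name),
      "        xmin = 0",
      sprintf("        xmax = %s", duration),
      sprintf("        intervals: size = %d", length(ivs)),
      fmt_iv(ivs))
  }
  paste(c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "xmin = 0",
    sprintf("xmax = %s", duration),
    "tiers? <exists>",
    "size = 2",
    "item []:",
    tier(1, "P1", ivs = intervals_p),
    tier(2, "P2", ivs = intervals_q)
  ), collapse = "\n")
}

# the same annotation in the short dialect
make_textgrid_short <- function(duration = 10) {
  paste(c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "0", as.character(duration), "<exists>", "2",
    "\"IntervalTier\"", "\"P1\"", "0", as.character(duration), "1",
    "0", "1", "\"hello\"",
    "\"IntervalTier\"", "\"P2\"", "0", as.character(duration), "1",
    "1", "2", "\"hi there\""
  ), collapse = "\n")
}

# regular-grid track with given f0 values, all voiced
make_track <- function(f0, step = 0.01, speaker = "spk") {
  f0_track(speaker, (seq_along(f0) - 1L) * step, f0, rep(TRUE, length(f0)),
           step = step)
}

# a tier with one linguistic interval per row of `lims`
make_tier <- function(lims, speaker = "spk", linguistic = TRUE) {
  n <- nrow(lims)
  speaker_tier(speaker, data.frame(
    start = lims[, 1], end = lims[, 2],
    label = rep("utt", n), is_linguistic = rep(linguistic, n)
  ))
}

# oracle: minimum distance to the line y = m x by dense sampling of line
# points, independent of the closed form under test
brute_line_distance <- function(point, m, n = 1e5, span = 2000) {
  x <- seq(-span, span, length.out = n)
  min(sqrt((x - point[1])^2 + (m * x - point[2])^2))
}

# oracle: dense-sampling minimisation with successive grid refinement,
# accurate to ~1e-9 Hz while remaining a pure sampling search
brute_line_distance_refined <- function(point, m, n = 1e4) {
  lo <- -1000; hi <- 2000
  for (stage in 1:3) {
    x <- seq(lo, hi, length.out = n)
    d <- sqrt((x - point[1])^2 + (m * x - point[2])^2)
    i <- which.min(d)
    w <- (hi - lo) / n
    lo <- x[i] - w; hi <- x[i] + w
  }
  min(d)
}

# oracle: least squares through explicitly built normal equations,
# independent of stats::lm
brute_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# a dyad_features object with prescribed start/end points for mean f0
feat_from_points <- function(S, E) {
  structure(list(
    mean_f0 = list(S = S, E = E, n_frames = rep(100L, 4L), usable = TRUE),
    iqr_f0 = list(S = c(10, 10), E = c(10, 10), n_frames = rep(100L, 4L),
                  usable = TRUE),
    duration = 600, speakers = c("p", "q")
  ), class = "dyad_features")
}

# fast small simulation settings used across tests
quick_cfg <- function(...) {
  sim_config(duration = 120, n_per_group = 3, ...)
}
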