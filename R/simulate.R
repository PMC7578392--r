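#' Simulation configuration
#'
#' Parameters of the synthetic dyad generator. Defaults describe a
#' plausible study-like cohort: 600 s conversations, speaker registers of
#' 230 Hz (children), 220 Hz (teenage girls), 140 Hz (teenage boys) and
#' 200 Hz (adult female partners), 5 Hz frame noise, alternating 1-5 s
#' utterances separated by 0.5-2 s pauses, and covariate distributions
#' matching the study groups (CELF 88/109, non-verbal IQ 107/110, age
#' uniform on 9-15). `drift_delta` is the programmed per-group change in
#' perpendicular distance to the dyad's reference line (Hz, positive =
#' convergence); `responsibility_split` is the fraction of the along-axis
#' movement assigned to the participant; `celf_effect` shifts the
#' participant's movement by that many Hz per CELF point above the group
#' mean. ASD participants additionally produce non-linguistic vocalisation
#' intervals (`nonspeech_rate` per minute) whose frames carry
#' out-of-register f0, so an unfiltered analysis is measurably biased.
#'
#' @param n_per_group Dyads per group.
#' @param duration Conversation duration in seconds.
#' @param step Frame step in seconds.
#' @param registers Named mean-f0 register per speaker class (Hz).
#' @param register_sd Between-dyad SD of the drawn registers (Hz).
#' @param frame_noise_sd Within-utterance frame noise SD (Hz).
#' @param utterance_range,pause_range Uniform ranges for utterance and
#'   pause durations (s).
#' @param drift_delta Named per-group programmed delta entrainment (Hz).
#' @param responsibility_split Participant's share of the along-axis
#'   movement, in `[0, 1]`.
#' @param celf_effect Hz of extra participant movement per CELF point
#'   above the group mean (negative: better language, less convergence).
#' @param iqr_drift Named per-group IQR drift knob (Hz); 0 keeps the IQR
#'   feature flat, mirroring a null f0-range effect.
#' @param nonspeech_rate Expected non-linguistic intervals per minute for
#'   ASD participants.
#' @param celf,nonverbal_iq,composite_iq Named lists of `c(mean, sd)` per
#'   group for the covariate draws.
#' @param age_range Uniform age range in years.
#' @param seed Cohort-level random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 12,
                       duration = 600,
                       step = 0.010,
                       registers = c(child = 230, teen_girl = 220,
                                     teen_boy = 140, adult_female = 200,
                                     adult_male = 120),
                       register_sd = 10,
                       frame_noise_sd = 5,
                       utterance_range = c(1, 5),
                       pause_range = c(0.5, 2),
                       drift_delta = c(ASD = 0, NT = 0),
                       responsibility_split = 0.5,
                       celf_effect = -0.1,
                       iqr_drift = c(ASD = 0, NT = 0),
                       nonspeech_rate = 0.5,
                       celf = list(ASD = c(88, 12.43), NT = c(109, 11.56)),
                       nonverbal_iq = list(ASD = c(107, 9.8), NT = c(110, 9.05)),
                       composite_iq = list(ASD = c(99, 16.76), NT = c(112, 12.57)),
                       age_range = c(9, 15),
                       seed = 1) {
  stopifnot(n_per_group >= 1, duration > 0, step > 0,
            register_sd >= 0, frame_noise_sd >= 0,
            responsibility_split >= 0, responsibility_split <= 1,
            nonspeech_rate >= 0)
  structure(
    list(n_per_group = n_per_group, duration = duration, step = step,
         registers = registers, register_sd = register_sd,
         frame_noise_sd = frame_noise_sd,
         utterance_range = utterance_range, pause_range = pause_range,
         drift_delta = drift_delta,
         responsibility_split = responsibility_split,
         celf_effect = celf_effect, iqr_drift = iqr_drift,
         nonspeech_rate = nonspeech_rate,
         celf = celf, nonverbal_iq = nonverbal_iq,
         composite_iq = composite_iq, age_range = age_range, seed = seed),
    class = "sim_config"
  )
}

#' Study-calibrated simulation preset
#'
#' The generator configured to the reported study conditions: 12 dyads per
#' group, programmed mean-f0 drift of -6 Hz (dis-entrainment) for ASD
#' dyads and +4 Hz (convergence) for NT dyads, flat IQR, and covariate
#' distributions matching the group summaries (CELF 88 +/- 12.43 vs
#' 109 +/- 11.56; non-verbal IQ 107 +/- 9.8 vs 110 +/- 9.05; age 9-15).
#'
#' @param n_per_group Dyads per group (default 12).
#' @param seed Cohort seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
paper_preset <- function(n_per_group = 12, seed = 1, ...) {
  sim_config(n_per_group = n_per_group,
             drift_delta = c(ASD = -6, NT = 4),
             seed = seed, ...)
}

# effective line slope in (participant, partner) coordinates; identical to
# the analysis-side reference line after its internal axis swap
effective_slope <- function(class_participant, class_partner) {
  if (!uses_half_matching(class_participant, class_partner)) return(1)
  if (class_participant == "teen_boy") 2 else 0.5
}

# alternating utterance/pause turn structure for both speakers
build_turns <- function(cfg, duration) {
  utt <- list(participant = NULL, partner = NULL)
  t <- stats::runif(1, 0, cfg$pause_range[2L])   # staggered start
  who <- sample(c("participant", "partner"), 1L)
  while (t < duration - cfg$utterance_range[1L]) {
    len <- stats::runif(1, cfg$utterance_range[1L], cfg$utterance_range[2L])
    end <- min(t + len, duration)
    utt[[who]] <- rbind(utt[[who]], c(t, end))
    t <- end + stats::runif(1, cfg$pause_range[1L], cfg$pause_range[2L])
    who <- if (who == "participant") "partner" else "participant"
  }
  utt
}

# place n non-overlapping non-speech intervals in a speaker's silent gaps
place_nonspeech <- function(utterances, duration, n) {
  if (n == 0L) return(NULL)
  bounds <- rbind(c(0, 0), utterances, c(duration, duration))
  gaps <- cbind(bounds[-nrow(bounds), 2L], bounds[-1L, 1L])
  gaps <- gaps[gaps[, 2L] - gaps[, 1L] > 1.8, , drop = FALSE]
  if (nrow(gaps) == 0L) return(NULL)
  pick <- sample(seq_len(nrow(gaps)), min(n, nrow(gaps)))
  out <- t(vapply(pick, function(i) {
    len <- stats::runif(1, 0.5, 1.5)
    start <- stats::runif(1, gaps[i, 1L] + 0.05,
                          gaps[i, 2L] - len - 0.05)
    c(start, start + len)
  }, numeric(2L)))
  out[order(out[, 1L]), , drop = FALSE]
}

# tile [0, duration] with explicit silence intervals around the labelled ones
gap_fill_intervals <- function(iv, duration) {
  iv <- iv[order(iv$start), , drop = FALSE]
  edges <- c(0, as.vector(t(cbind(iv$start, iv$end))), duration)
  out <- NULL
  for (i in seq_len(nrow(iv) + 1L)) {
    lo <- edges[2L * i - 1L]; hi <- edges[2L * i]
    if (hi - lo > 1e-9) {
      out <- rbind(out, data.frame(start = lo, end = hi, label = "",
                                   is_linguistic = FALSE))
    }
    if (i <= nrow(iv)) out <- rbind(out, iv[i, ])
  }
  out
}

#' Simulate one annotated dyadic conversation with exact ground truth
#'
#' Draws the two speakers' registers, places the dyad's start point in the
#' joint f0 plane, and moves it by exactly the programmed perpendicular
#' drift toward (or away from) the dyad's reference line, splitting the
#' along-axis movement between the speakers per the responsibility split.
#' The third-wise mean targets are then rendered to a frame-wise f0 track
#' (target + Gaussian noise inside utterances), and the turn structure to
#' a two-tier annotation. ASD participants receive occasional
#' non-linguistic vocalisation intervals whose frames sit at twice the
#' register, flagged non-linguistic in the annotation. At zero noise the
#' pipeline recovers the programmed delta entrainment and responsibility
#' split exactly; registers are redrawn when a drawn start point cannot
#' geometrically accommodate the programmed drift, and an error is raised
#' if no feasible draw exists (e.g. targets pushed below the pitch floor).
#'
#' @param cfg A [sim_config()].
#' @param group `"ASD"` or `"NT"`.
#' @param seed Dyad-level seed (byte-identical outputs for equal seeds).
#' @param dyad_id Identifier used for conversation and file naming.
#' @param gender `"F"` or `"M"`; with age, determines the speaker class.
#' @param partner_id Conversation-partner identifier.
#' @return List with `conversation` ([annotated_conversation()]),
#'   `track_participant` and `track_partner` (raw, unfiltered
#'   [f0_track()]s), `metadata` (one-row tibble) and `ground_truth`
#'   (two-row tibble, one per speaker role).
#' @export
simulate_dyad <- function(cfg, group = c("ASD", "NT"), seed = 1,
                          dyad_id = paste0(group, "01"), gender = "M",
                          partner_id = "RA1") {
  group <- match.arg(group)
  set.seed(seed)
  draw2 <- function(ms) stats::rnorm(1, ms[1L], ms[2L])
  age <- round(stats::runif(1, cfg$age_range[1L], cfg$age_range[2L]), 2)
  celf <- round(max(40, draw2(cfg$celf[[group]])))
  nviq <- round(max(85, draw2(cfg$nonverbal_iq[[group]])))
  ciq <- round(max(76, draw2(cfg$composite_iq[[group]])))
  class_p <- if (age < 12) "child" else if (gender == "F") "teen_girl" else "teen_boy"
  class_q <- "adult_female"
  m <- effective_slope(class_p, class_q)
  s <- sqrt(m^2 + 1)
  w <- cfg$responsibility_split
  r <- unname(cfg$drift_delta[group])
  # split the along-axis movement so the perpendicular change is exactly r
  t_total <- abs(r) * s / (m * w + (1 - w))
  a <- w * t_total            # participant along-axis magnitude
  b <- (1 - w) * t_total      # partner along-axis magnitude
  # CELF modulation of the participant's movement, oriented so that a
  # higher language score always means less convergence (lower delta)
  a <- max(0, a + cfg$celf_effect * (celf - cfg$celf[[group]][1L]) * sign(r))
  band_p <- speaker_class_range(class_p)
  band_q <- speaker_class_range(class_q)
  feasible <- FALSE
  for (try in 1:200) {
    p0 <- stats::rnorm(1, cfg$registers[[class_p]], cfg$register_sd)
    q0 <- stats::rnorm(1, cfg$registers[[class_q]], cfg$register_sd)
    g <- m * p0 - q0
    dir <- sign(g) * sign(r)
    dp <- -dir * a
    dq <- dir * b
    p1 <- p0 + dp; q1 <- q0 + dq
    ok_cross <- r <= 0 || (m * a + b) <= abs(g) - 1
    ok_band <- p0 > band_p$floor + 10 && p1 > band_p$floor + 10 &&
      p0 < band_p$ceiling - 10 && p1 < band_p$ceiling - 10 &&
      q0 > band_q$floor + 10 && q1 > band_q$floor + 10 &&
      q0 < band_q$ceiling - 10 && q1 < band_q$ceiling - 10
    if (ok_cross && ok_band) { feasible <- TRUE; break }
  }
  if (!feasible) {
    stop("infeasible drift for dyad ", dyad_id,
         ": no register draw keeps the programmed movement inside the pitch band")
  }
  # exact ground truth from the target means
  d1 <- abs(m * p0 - q0) / s
  d2 <- abs(m * p1 - q1) / s
  delta_true <- d1 - d2
  resp <- speaker_responsibility(abs(dp), abs(dq))

  turns <- build_turns(cfg, cfg$duration)
  n_ns <- stats::rpois(1, if (group == "ASD") cfg$nonspeech_rate * cfg$duration / 60 else 0)
  ns <- place_nonspeech(turns$participant, cfg$duration, n_ns)

  make_tier <- function(id, class, utterances, nonspeech = NULL) {
    iv <- data.frame(start = utterances[, 1L], end = utterances[, 2L],
                     label = "utt", is_linguistic = TRUE)
    if (!is.null(nonspeech)) {
      iv <- rbind(iv, data.frame(start = nonspeech[, 1L], end = nonspeech[, 2L],
                                 label = "stereotypy", is_linguistic = FALSE))
    }
    speaker_tier(id, gap_fill_intervals(iv, cfg$duration), speaker_class = class)
  }
  id_p <- paste0(dyad_id, "_participant")
  id_q <- paste0(dyad_id, "_partner")
  conv <- annotated_conversation(
    dyad_id, cfg$duration,
    list(make_tier(id_p, class_p, turns$participant, ns),
         make_tier(id_q, class_q, turns$partner))
  )

  nframes <- floor(cfg$duration / cfg$step)
  times <- (seq_len(nframes) - 1L) * cfg$step
  # third membership uses the same half-open window convention (and
  # tolerance) as the analysis, so targets and measured windows agree
  in_first <- frames_in_intervals(times, 0, cfg$duration / 3)
  in_last <- frames_in_intervals(times, 2 * cfg$duration / 3, cfg$duration)
  noise_sd <- rep(cfg$frame_noise_sd, nframes)
  noise_sd[in_last] <- max(0, cfg$frame_noise_sd +
                             unname(cfg$iqr_drift[group]) / 1.349)
  make_track <- function(id, start_mean, end_mean, utterances, nonspeech = NULL,
                         register) {
    target <- rep((start_mean + end_mean) / 2, nframes)
    target[in_first] <- start_mean
    target[in_last] <- end_mean
    voiced <- frames_in_intervals(times, utterances[, 1L], utterances[, 2L])
    f0 <- numeric(nframes)
    f0[voiced] <- target[voiced] + stats::rnorm(sum(voiced), 0, noise_sd[voiced])
    if (!is.null(nonspeech)) {
      in_ns <- frames_in_intervals(times, nonspeech[, 1L], nonspeech[, 2L])
      f0[in_ns] <- 2 * register + stats::rnorm(sum(in_ns), 0, cfg$frame_noise_sd)
      voiced <- voiced | in_ns
    }
    f0[voiced] <- pmax(f0[voiced], 1)
    f0_track(id, times, f0, voiced, step = cfg$step)
  }
  track_p <- make_track(id_p, p0, p1, turns$participant, ns,
                        cfg$registers[[class_p]])
  track_q <- make_track(id_q, q0, q1, turns$partner, NULL,
                        cfg$registers[[class_q]])

  metadata <- tibble::tibble(
    dyad_id = dyad_id, participant_id = id_p, partner_id = partner_id,
    group = group, age = age, gender = gender,
    celf_core = celf, nonverbal_iq = nviq, composite_iq = ciq,
    speaker_class_participant = class_p, speaker_class_partner = class_q
  )
  ground_truth <- tibble::tibble(
    dyad_id = dyad_id,
    role = c("participant", "partner"),
    programmed_delta = r,
    true_delta = delta_true,
    true_resp = c(resp$resp1, resp$resp2),
    true_contribution = sign(delta_true) * c(resp$resp1, resp$resp2),
    true_adjusted = delta_true * c(resp$resp1, resp$resp2),
    S_participant = p0, S_partner = q0,
    E_participant = p1, E_partner = q1,
    line_slope_effective = m,
    seed = seed
  )
  list(conversation = conv, track_participant = track_p,
       track_partner = track_q, metadata = metadata,
       ground_truth = ground_truth)
}

#' Simulate a full study cohort
#'
#' Generates `n_per_group` dyads per group with covariates drawn per the
#' configuration. Genders are allocated 1 female to 3 males (the study
#' ratio); conversation partners are drawn from a pool of nine assistants.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_cohort`: list with `dyads` (list of
#'   [simulate_dyad()] results), `metadata`, `ground_truth` and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_per_group
  groups <- rep(c("ASD", "NT"), each = n)
  n_f <- round(n / 4)
  genders <- rep(c(rep("F", n_f), rep("M", n - n_f)), 2L)
  dyad_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  partner_ids <- sample(paste0("RA", 1:9), 2L * n, replace = TRUE)
  dyad_ids <- paste0(groups, sprintf("%02d", c(seq_len(n), seq_len(n))))
  dyads <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    dyads[[i]] <- simulate_dyad(cfg, groups[i], seed = dyad_seeds[i],
                                dyad_id = dyad_ids[i], gender = genders[i],
                                partner_id = partner_ids[i])
  }
  structure(
    list(
      dyads = dyads,
      metadata = do.call(rbind, lapply(dyads, `[[`, "metadata")),
      ground_truth = do.call(rbind, lapply(dyads, `[[`, "ground_truth")),
      config = cfg
    ),
    class = "sim_cohort"
  )
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' One TextGrid and two pitch-track CSVs per dyad, plus `metadata.csv` and
#' `ground_truth.csv`. Every CSV records the generating seed in a `#`
#' header comment (TextGrid has no comment syntax).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in cohort$dyads) {
    id <- d$conversation$conversation_id
    seed <- d$ground_truth$seed[1L]
    # TextGrid has no comment syntax; the seed lives in the CSV headers
    write_textgrid(d$conversation, file.path(dir, paste0(id, ".TextGrid")))
    write_f0_track(d$track_participant,
                   file.path(dir, paste0(id, "_participant.csv")),
                   header = paste("seed:", seed))
    write_f0_track(d$track_partner,
                   file.path(dir, paste0(id, "_partner.csv")),
                   header = paste("seed:", seed))
  }
  meta_path <- file.path(dir, "metadata.csv")
  writeLines(paste0("# seed: ", cohort$config$seed), meta_path)
  suppressWarnings(utils::write.table(cohort$metadata, meta_path, sep = ",",
                                      row.names = FALSE, append = TRUE,
                                      quote = FALSE))
  gt_path <- file.path(dir, "ground_truth.csv")
  writeLines(paste0("# seed: ", cohort$config$seed), gt_path)
  suppressWarnings(utils::write.table(cohort$ground_truth, gt_path, sep = ",",
                                      row.names = FALSE, append = TRUE,
                                      quote = FALSE))
  invisible(dir)
}
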