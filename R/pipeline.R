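#' Read a participant metadata table
#'
#' CSV with columns `dyad_id`, `participant_id`, `partner_id`, `group`
#' (ASD/NT), `age`, `gender` (F/M), `celf_core`, `nonverbal_iq`, optional
#' `composite_iq`, `speaker_class_participant`, `speaker_class_partner`.
#' Lines starting with `#` are skipped.
#'
#' @param path CSV path.
#' @param age_range Plausible age range; ages outside it are an error.
#' @return A tibble.
#' @export
read_metadata <- function(path, age_range = c(2, 100)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("dyad_id", "participant_id", "partner_id", "group", "age",
                "gender", "celf_core", "nonverbal_iq",
                "speaker_class_participant", "speaker_class_partner")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(df$group %in% c("ASD", "NT"))) stop("group must be ASD or NT")
  if (any(df$age < age_range[1L] | df$age > age_range[2L])) {
    stop("age outside the plausible range [", age_range[1L], ", ",
         age_range[2L], "]")
  }
  scores <- c("celf_core", "nonverbal_iq",
              intersect("composite_iq", names(df)))
  for (col in scores) {
    if (any(!is.na(df[[col]]) & df[[col]] <= 0)) stop(col, " must be positive")
  }
  tibble::as_tibble(df)
}

#' Default pipeline analysis options
#'
#' @param min_frames Minimum voiced frames per third per speaker.
#' @param maintenance_band Maintenance half-width in Hz.
#' @param converge_threshold Convergence-count threshold in Hz.
#' @param min_over_lines Score each point against the nearer of l1/l2.
#' @param line_override Optional fixed reference-line slope.
#' @param apply_filter Restrict tracks to linguistic intervals (the study
#'   rule; disable only for sensitivity analysis).
#' @param model_families Model families fitted by the stats stage.
#' @return Named list of options.
#' @export
pipeline_options <- function(min_frames = 50,
                             maintenance_band = 1.0,
                             converge_threshold = 2.0,
                             min_over_lines = FALSE,
                             line_override = NULL,
                             apply_filter = TRUE,
                             model_families = c("conversation_level",
                                                "contribution_level",
                                                "adjusted_level")) {
  list(min_frames = min_frames, maintenance_band = maintenance_band,
       converge_threshold = converge_threshold,
       min_over_lines = min_over_lines, line_override = line_override,
       apply_filter = apply_filter, model_families = model_families)
}

# analyse one dyad bundle (conversation + raw tracks + metadata row);
# returns NULL with an attached reason when the dyad is unusable
analyze_dyad <- function(dyad, opts) {
  conv <- dyad$conversation
  meta <- dyad$metadata
  tiers <- conv$tiers
  tp <- dyad$track_participant
  tq <- dyad$track_partner
  if (isTRUE(opts$apply_filter)) {
    tp <- filter_linguistic(tp, tiers[[1L]])
    tq <- filter_linguistic(tq, tiers[[2L]])
  }
  feat <- build_dyad_features(tp, tq, conv$duration,
                              min_frames = opts$min_frames)
  line <- select_reference_line(meta$speaker_class_participant,
                                meta$speaker_class_partner,
                                override = opts$line_override)
  features <- do.call(rbind, lapply(c("mean_f0", "iqr_f0"), function(k) {
    f <- feat[[k]]
    tibble::tibble(
      dyad_id = meta$dyad_id,
      speaker = rep(c("participant", "partner"), each = 2L),
      k = k,
      window = rep(c("first", "last"), 2L),
      value = c(f$S[1L], f$E[1L], f$S[2L], f$E[2L]),
      n_frames = unname(f$n_frames[c(1L, 2L, 3L, 4L)])
    )
  }))
  rows <- NULL
  skipped <- character(0)
  for (k in c("mean_f0", "iqr_f0")) {
    if (!feat[[k]]$usable) {
      skipped <- c(skipped, k)
      next
    }
    row <- dyad_entrainment(feat, line, k,
                            maintenance_band = opts$maintenance_band,
                            min_over_lines = opts$min_over_lines)
    row <- cbind(tibble::tibble(dyad_id = meta$dyad_id), row)
    rows <- rbind(rows, row)
  }
  list(features = features, entrainment = rows, skipped_k = skipped)
}

#' Run the entrainment analysis over a set of dyads
#'
#' The in-memory core of the pipeline: filters each dyad's pitch tracks to
#' linguistic speech, builds third-wise features, selects the dyad's
#' reference line from the speaker classes, and scores entrainment.
#' Dyads (or single features) with insufficient voiced speech are excluded
#' and logged, never silently dropped.
#'
#' @param dyads List of dyad bundles, each with `conversation`,
#'   `track_participant`, `track_partner` and a one-row `metadata`; a
#'   [simulate_cohort()] result is accepted directly.
#' @param opts [pipeline_options()].
#' @return List with `features` (long tibble), `entrainment` (one row per
#'   dyad and feature, joined to metadata) and `log` (character vector of
#'   exclusions).
#' @export
analyze_dyads <- function(dyads, opts = pipeline_options()) {
  if (inherits(dyads, "sim_cohort")) dyads <- dyads$dyads
  features <- NULL; entrainment <- NULL; log <- character(0)
  for (dyad in dyads) {
    res <- analyze_dyad(dyad, opts)
    features <- rbind(features, res$features)
    entrainment <- rbind(entrainment, res$entrainment)
    for (k in res$skipped_k) {
      log <- c(log, paste0("excluded dyad ", dyad$metadata$dyad_id,
                           " feature ", k,
                           ": fewer than ", opts$min_frames,
                           " voiced frames in a third"))
    }
  }
  if (!is.null(entrainment)) {
    meta <- do.call(rbind, lapply(dyads, `[[`, "metadata"))
    entrainment <- tibble::as_tibble(merge(entrainment, meta,
                                           by = "dyad_id", sort = TRUE))
  }
  list(features = features, entrainment = entrainment, log = log)
}

# participant-level analysis rows for the contribution model families
participant_rows <- function(entrainment, k = "mean_f0") {
  rows <- entrainment[entrainment$k == k, , drop = FALSE]
  rows$contribution <- rows$contribution1
  rows$adjusted <- rows$adjusted1
  rows
}

#' Load dyads from TextGrid/CSV files on disk
#'
#' Expects `<dyad_id>.TextGrid`, `<dyad_id>_participant.csv` and
#' `<dyad_id>_partner.csv` in `dir` for every metadata row; dyads with
#' missing files, and files with no metadata row, are skipped with a log
#' message.
#'
#' @param dir Directory holding the annotation and track files.
#' @param metadata Metadata tibble (see [read_metadata()]).
#' @return List with `dyads` and `log`.
#' @export
load_dyads <- function(dir, metadata) {
  dyads <- list(); log <- character(0)
  tg_ids <- sub("\\.TextGrid$", "",
                list.files(dir, pattern = "\\.TextGrid$"))
  orphans <- setdiff(tg_ids, metadata$dyad_id)
  for (id in orphans) {
    log <- c(log, paste0("excluded dyad ", id, ": no metadata row"))
  }
  for (i in seq_len(nrow(metadata))) {
    id <- metadata$dyad_id[i]
    tg <- file.path(dir, paste0(id, ".TextGrid"))
    fp <- file.path(dir, paste0(id, "_participant.csv"))
    fq <- file.path(dir, paste0(id, "_partner.csv"))
    if (!all(file.exists(tg, fp, fq))) {
      log <- c(log, paste0("excluded dyad ", id, ": missing input file(s)"))
      next
    }
    conv <- read_textgrid(tg, conversation_id = id)
    dyads[[id]] <- list(
      conversation = conv,
      track_participant = read_f0_track(fp),
      track_partner = read_f0_track(fq),
      metadata = metadata[i, , drop = FALSE]
    )
  }
  list(dyads = dyads, log = log)
}

#' Run the full pipeline from a config
#'
#' Orchestrates simulate/extract/entrain/stats/report from one
#' configuration: either a `simulate` block ([sim_config()] parameters) or
#' an `inputs` block (`dir` with TextGrids and pitch tracks plus a
#' `metadata` CSV), analysis `options` ([pipeline_options()] fields), and
#' a `seed`. Writes `features.csv`, `entrainment.csv`, `models/*.csv`,
#' `summary.txt` and `log.txt` into `out_dir`. Reruns with the same config
#' and seed produce identical files.
#'
#' @param config A list, or path to a YAML file with the same structure.
#' @param out_dir Output directory (created; overrides `config$out_dir`).
#' @param seed Seed overriding `config$seed`.
#' @param stage One of `"run"` (everything), `"simulate"`, `"extract"`,
#'   `"entrain"`, `"stats"`; earlier stages always run as prerequisites,
#'   later ones are skipped.
#' @return Invisibly, a list with the analysis tables, model results,
#'   summary lines and log.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         stage = c("run", "simulate", "extract", "entrain",
                                   "stats")) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory: set out_dir or config$out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% config$seed %||% 1L
  opts <- do.call(pipeline_options, config$options %||% list())
  log <- character(0)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    if (!is.null(sim_args$drift_delta)) {
      sim_args$drift_delta <- unlist(sim_args$drift_delta)
    }
    cfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cfg)
    if (isTRUE(config$write_simulated)) {
      write_dataset(cohort, file.path(out_dir, "simulated"))
    }
    dyads <- cohort$dyads
    gt_path <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(cohort$ground_truth, gt_path, row.names = FALSE)
  } else if (!is.null(config$inputs)) {
    if (is.null(config$inputs$dir) || !dir.exists(config$inputs$dir)) {
      stop("config error: inputs$dir missing or not a directory")
    }
    if (is.null(config$inputs$metadata) || !file.exists(config$inputs$metadata)) {
      stop("config error: inputs$metadata missing")
    }
    metadata <- read_metadata(config$inputs$metadata)
    loaded <- load_dyads(config$inputs$dir, metadata)
    dyads <- loaded$dyads
    log <- c(log, loaded$log)
  } else {
    stop("config error: need a 'simulate' or an 'inputs' block")
  }
  if (stage == "simulate") {
    writeLines(log, file.path(out_dir, "log.txt"))
    return(invisible(list(dyads = dyads, log = log)))
  }

  res <- analyze_dyads(dyads, opts)
  log <- c(log, res$log)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  if (stage == "extract") {
    writeLines(log, file.path(out_dir, "log.txt"))
    return(invisible(c(res, list(log = log))))
  }
  utils::write.csv(res$entrainment, file.path(out_dir, "entrainment.csv"),
                   row.names = FALSE)

  models <- NULL
  if (stage %in% c("stats", "run") && !is.null(res$entrainment)) {
    models <- list()
    dyad_rows <- res$entrainment[res$entrainment$k == "mean_f0", , drop = FALSE]
    part_rows <- participant_rows(res$entrainment, "mean_f0")
    iqr_rows <- res$entrainment[res$entrainment$k == "iqr_f0", , drop = FALSE]
    fam_data <- list(conversation_level = dyad_rows,
                     contribution_level = part_rows,
                     adjusted_level = part_rows,
                     f0_range_family = iqr_rows)
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    for (fam in opts$model_families) {
      fit <- withCallingHandlers(
        tryCatch(run_model_family(fam_data[[fam]], fam),
                 error = function(e) {
                   log <<- c(log, paste0("model family ", fam,
                                         " not fitted: ",
                                         conditionMessage(e)))
                   NULL
                 }),
        warning = function(w) {
          log <<- c(log, paste0("model family ", fam, ": ",
                                conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (is.null(fit)) next
      models[[fam]] <- fit
      utils::write.csv(tidy_models(fit),
                       file.path(out_dir, "models", paste0(fam, ".csv")),
                       row.names = FALSE)
    }
  }

  summary_lines <- pipeline_summary(res$entrainment, opts, seed)
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(list(features = res$features, entrainment = res$entrainment,
                 models = models, summary = summary_lines, log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-text run report: settings echo, group means, convergence counts
pipeline_summary <- function(entrainment, opts, seed) {
  lines <- c(
    "f0 entrainment pipeline summary",
    paste0("seed = ", seed),
    paste0("min_frames = ", opts$min_frames,
           ", maintenance_band = ", opts$maintenance_band, " Hz",
           ", converge_threshold = ", opts$converge_threshold, " Hz",
           ", min_over_lines = ", opts$min_over_lines,
           ", linguistic_filter = ", opts$apply_filter),
    ""
  )
  if (is.null(entrainment) || nrow(entrainment) == 0L) {
    return(c(lines, "no usable dyads"))
  }
  for (k in unique(entrainment$k)) {
    rows <- entrainment[entrainment$k == k, , drop = FALSE]
    lines <- c(lines, paste0("feature: ", k))
    for (g in c("ASD", "NT")) {
      sel <- rows[rows$group == g, , drop = FALSE]
      if (nrow(sel) == 0L) next
      conv <- count_converging(sel$delta_ent, opts$converge_threshold)
      cls <- table(factor(sel$classification,
                          levels = c("convergence", "maintenance", "divergence")))
      lines <- c(lines, sprintf(
        "  %s: n = %d, mean delta_ent = %.3f Hz, converging (> %g Hz) = %d (%.0f%%), conv/maint/div = %d/%d/%d",
        g, nrow(sel), mean(sel$delta_ent), opts$converge_threshold,
        conv$count, 100 * conv$proportion, cls[1L], cls[2L], cls[3L]))
    }
    both <- vapply(c("ASD", "NT"), function(g) {
      mean(rows$delta_ent[rows$group == g])
    }, numeric(1L))
    if (all(is.finite(both))) {
      lines <- c(lines, sprintf(
        "  group difference (NT - ASD) in mean delta_ent = %.3f Hz",
        both["NT"] - both["ASD"]))
    }
    lines <- c(lines, "")
  }
  lines
}
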