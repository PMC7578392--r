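#' Speaker interval tier
#'
#' One speaker's time-aligned utterance annotation: a set of labelled,
#' non-overlapping intervals, each flagged as linguistically meaningful or
#' not. The flag is assigned once, when the annotation is read or built;
#' downstream analysis code only ever consults the flag, never the label
#' text.
#'
#' @param speaker_id Character scalar identifying the speaker.
#' @param intervals Data frame with columns `start`, `end` (seconds),
#'   `label` (character) and `is_linguistic` (logical). Intervals must be
#'   time-ordered and non-overlapping, with `start < end`.
#' @param speaker_class One of `"child"`, `"teen_girl"`, `"teen_boy"`,
#'   `"adult_female"`, `"adult_male"`, or `NA` if not yet known (it can be
#'   attached later from a metadata table).
#' @return An object of class `speaker_tier`.
#' @export
speaker_tier <- function(speaker_id, intervals, speaker_class = NA_character_) {
  stopifnot(is.character(speaker_id), length(speaker_id) == 1L)
  intervals <- tibble::as_tibble(intervals)
  required <- c("start", "end", "label", "is_linguistic")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols) > 0L) {
    stop("intervals is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  intervals <- intervals[required]
  if (nrow(intervals) > 0L) {
    if (any(intervals$start >= intervals$end)) {
      stop("every interval must satisfy start < end")
    }
    if (is.unsorted(intervals$start)) {
      stop("intervals must be time-ordered")
    }
    if (nrow(intervals) > 1L &&
        any(intervals$start[-1L] < intervals$end[-nrow(intervals)] - 1e-9)) {
      stop("intervals within a tier must not overlap")
    }
  }
  if (!is.na(speaker_class)) speaker_class <- match.arg(speaker_class, speaker_classes())
  structure(
    list(speaker_id = speaker_id, speaker_class = speaker_class,
         intervals = intervals),
    class = "speaker_tier"
  )
}

#' Recognised speaker classes
#'
#' The pitch-register classes used to choose pitch-analysis ranges and the
#' dyad's reference line.
#' @return Character vector of class names.
#' @export
speaker_classes <- function() {
  c("child", "teen_girl", "teen_boy", "adult_female", "adult_male")
}

#' Annotated two-speaker conversation
#'
#' @param conversation_id Character scalar.
#' @param duration Total conversation duration in seconds (> 0).
#' @param tiers List of exactly two [speaker_tier()] objects: the
#'   participant first, the conversation partner second. Tiers from
#'   different speakers may overlap in time (simultaneous speech); intervals
#'   within one tier may not.
#' @return An object of class `annotated_conversation`.
#' @export
annotated_conversation <- function(conversation_id, duration, tiers) {
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.list(tiers) || length(tiers) != 2L ||
      !all(vapply(tiers, inherits, logical(1L), "speaker_tier"))) {
    stop("tiers must be a list of exactly two speaker_tier objects")
  }
  for (tier in tiers) {
    iv <- tier$intervals
    if (nrow(iv) > 0L && (min(iv$start) < -1e-9 || max(iv$end) > duration + 1e-6)) {
      stop("tier '", tier$speaker_id, "' has intervals outside [0, duration]")
    }
  }
  ids <- vapply(tiers, `[[`, character(1L), "speaker_id")
  names(tiers) <- ids
  structure(
    list(conversation_id = as.character(conversation_id),
         duration = duration, tiers = tiers),
    class = "annotated_conversation"
  )
}

#' @export
print.annotated_conversation <- function(x, ...) {
  cat("<annotated_conversation> ", x$conversation_id,
      sprintf(" (%.2f s)\n", x$duration), sep = "")
  for (tier in x$tiers) {
    n_ling <- sum(tier$intervals$is_linguistic)
    cat(sprintf("  tier %-12s [%s] %d intervals (%d linguistic)\n",
                tier$speaker_id,
                ifelse(is.na(tier$speaker_class), "?", tier$speaker_class),
                nrow(tier$intervals), n_ling))
  }
  invisible(x)
}

#' Default non-linguistic label set
#'
#' Interval labels treated as non-linguistic vocalisation or silence when a
#' TextGrid is read: laughter, humming, vocal stereotypy, noise, and the
#' conventional silence markers. Matching is case-insensitive on the
#' whitespace-trimmed label.
#' @return Character vector of excluded labels.
#' @export
default_nonlinguistic_labels <- function() {
  c("laughter", "hum", "humming", "stereotypy", "noise", "sil", "sp", "")
}

classify_labels <- function(labels, exclude_labels) {
  !(tolower(trimws(labels)) %in% tolower(exclude_labels))
}

# --- TextGrid reading ---------------------------------------------------

#' Read a TextGrid file with encoding detection
#'
#' Praat emits TextGrids in UTF-8 or UTF-16; the BOM is used to pick the
#' decoding, falling back to UTF-8.
#'
#' @param path File path.
#' @param ... Passed to [parse_textgrid()].
#' @return An [annotated_conversation()].
#' @export
read_textgrid <- function(path, ...) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) >= 2L &&
      ((raw[1L] == as.raw(0xFE) && raw[2L] == as.raw(0xFF)) ||
       (raw[1L] == as.raw(0xFF) && raw[2L] == as.raw(0xFE)))) {
    enc <- if (raw[1L] == as.raw(0xFE)) "UTF-16BE" else "UTF-16LE"
    text <- iconv(list(raw[-(1:2)]), from = enc, to = "UTF-8")
  } else {
    text <- rawToChar(raw)
    Encoding(text) <- "UTF-8"
    # strip UTF-8 BOM if present
    text <- sub("^﻿", "", text)
  }
  conv <- parse_textgrid(text, ...)
  if (conv$conversation_id == "conversation") {
    conv$conversation_id <- tools::file_path_sans_ext(basename(path))
  }
  conv
}

#' Parse TextGrid text into an annotated conversation
#'
#' Accepts both the long ("text") and short TextGrid dialects. Only
#' IntervalTier tiers are kept; at least two are required (participant and
#' partner, in file order). Each interval's `is_linguistic` flag is set at
#' parse time: a non-empty label not in `exclude_labels` is linguistic.
#'
#' @param text A single string holding the whole file contents.
#' @param exclude_labels Labels classified as non-linguistic (see
#'   [default_nonlinguistic_labels()]).
#' @param linguistic_rule Optional function `label -> logical` replacing the
#'   exclusion-set rule entirely.
#' @param conversation_id Identifier for the conversation.
#' @return An [annotated_conversation()].
#' @export
parse_textgrid <- function(text,
                           exclude_labels = default_nonlinguistic_labels(),
                           linguistic_rule = NULL,
                           conversation_id = "conversation") {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\r\n|\r|\n")[[1L]]
  if (length(lines) < 3L) stop("TextGrid parse error at line 1: file too short")
  header <- paste(lines[1:2], collapse = " ")
  if (!grepl("ooTextFile", header) || !grepl("TextGrid", header)) {
    stop("TextGrid parse error at line 1: not a TextGrid ooTextFile header")
  }
  is_long <- any(grepl("^\\s*xmin\\s*=", lines))
  tiers_raw <- if (is_long) parse_textgrid_long(lines) else parse_textgrid_short(lines)
  xmax <- attr(tiers_raw, "xmax")
  tiers_raw <- Filter(function(t) t$class == "IntervalTier", tiers_raw)
  if (length(tiers_raw) < 2L) {
    stop("TextGrid structure error: need at least 2 interval tiers, found ",
         length(tiers_raw))
  }
  rule <- if (is.null(linguistic_rule)) {
    function(lab) classify_labels(lab, exclude_labels)
  } else {
    linguistic_rule
  }
  tiers <- lapply(tiers_raw[1:2], function(t) {
    iv <- tibble::tibble(start = t$xmin, end = t$xmax_iv, label = t$label)
    iv$is_linguistic <- if (nrow(iv)) as.logical(rule(iv$label)) else logical(0)
    speaker_tier(t$name, iv)
  })
  annotated_conversation(conversation_id, xmax, tiers)
}

# long-format: attribute lines "key = value", headers "item [i]:" etc.
parse_textgrid_long <- function(lines) {
  num_at <- function(i, key) {
    m <- regmatches(lines[i], regexec(paste0(key, "\\s*=\\s*([-0-9.eE+]+)"), lines[i]))[[1L]]
    if (length(m) < 2L) stop("TextGrid parse error at line ", i, ": expected '", key, " = <number>'")
    as.numeric(m[2L])
  }
  str_at <- function(i, key) {
    m <- regmatches(lines[i], regexec(paste0(key, "\\s*=\\s*\"(.*)\"\\s*$"), lines[i]))[[1L]]
    if (length(m) < 2L) stop("TextGrid parse error at line ", i, ": expected '", key, " = \"...\"'")
    gsub("\"\"", "\"", m[2L])
  }
  find_next <- function(pattern, from) {
    hits <- grep(pattern, lines)
    hits <- hits[hits >= from]
    if (length(hits) == 0L) NA_integer_ else hits[1L]
  }
  i_xmax <- find_next("^\\s*xmax\\s*=", 1L)
  if (is.na(i_xmax)) stop("TextGrid parse error at line ", length(lines), ": global xmax not found")
  xmax <- num_at(i_xmax, "xmax")
  item_lines <- grep("^\\s*item\\s*\\[[0-9]+\\]\\s*:?", lines)
  tiers <- list()
  for (j in seq_along(item_lines)) {
    i0 <- item_lines[j]
    i1 <- if (j < length(item_lines)) item_lines[j + 1L] - 1L else length(lines)
    block <- i0:i1
    i_class <- find_next("^\\s*class\\s*=", i0)
    if (is.na(i_class) || i_class > i1) next
    klass <- str_at(i_class, "class")
    i_name <- find_next("^\\s*name\\s*=", i_class)
    name <- if (!is.na(i_name) && i_name <= i1) str_at(i_name, "name") else paste0("tier", j)
    if (klass != "IntervalTier") {
      tiers[[length(tiers) + 1L]] <- list(class = klass, name = name)
      next
    }
    iv_lines <- grep("^\\s*intervals\\s*\\[[0-9]+\\]\\s*:?", lines)
    iv_lines <- iv_lines[iv_lines >= i0 & iv_lines <= i1]
    xmin <- xmax_iv <- numeric(length(iv_lines))
    label <- character(length(iv_lines))
    for (k in seq_along(iv_lines)) {
      ik <- iv_lines[k]
      xmin[k] <- num_at(find_next("^\\s*xmin\\s*=", ik + 1L), "xmin")
      xmax_iv[k] <- num_at(find_next("^\\s*xmax\\s*=", ik + 1L), "xmax")
      label[k] <- str_at(find_next("^\\s*text\\s*=", ik + 1L), "text")
    }
    tiers[[length(tiers) + 1L]] <- list(class = "IntervalTier", name = name,
                                        xmin = xmin, xmax_iv = xmax_iv, label = label)
  }
  attr(tiers, "xmax") <- xmax
  tiers
}

# short-format: bare values in fixed order
parse_textgrid_short <- function(lines) {
  vals <- trimws(lines)
  vals <- vals[nzchar(vals)]
  # drop the two header lines and the <exists> marker
  body <- vals[-(1:2)]
  unquote <- function(x) {
    if (grepl("^\".*\"$", x)) gsub("\"\"", "\"", sub("^\"", "", sub("\"$", "", x))) else x
  }
  num <- function(x, pos) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("TextGrid parse error at line ", pos, ": expected a number, got '", x, "'")
    v
  }
  p <- 1L
  take <- function() {
    if (p > length(body)) stop("TextGrid parse error at line ", length(lines), ": unexpected end of file")
    v <- body[p]
    p <<- p + 1L
    v
  }
  num(take(), p)                 # global xmin
  xmax <- num(take(), p)         # global xmax
  take()                         # <exists>
  n_tiers <- as.integer(num(take(), p))
  tiers <- vector("list", n_tiers)
  for (j in seq_len(n_tiers)) {
    klass <- unquote(take())
    name <- unquote(take())
    num(take(), p); num(take(), p)   # tier xmin, xmax
    n_iv <- as.integer(num(take(), p))
    if (klass == "IntervalTier") {
      xmin <- xmax_iv <- numeric(n_iv)
      label <- character(n_iv)
      for (k in seq_len(n_iv)) {
        xmin[k] <- num(take(), p)
        xmax_iv[k] <- num(take(), p)
        label[k] <- unquote(take())
      }
      tiers[[j]] <- list(class = klass, name = name, xmin = xmin,
                         xmax_iv = xmax_iv, label = label)
    } else {
      # point tiers carry (time, mark) pairs
      for (k in seq_len(n_iv)) { take(); take() }
      tiers[[j]] <- list(class = klass, name = name)
    }
  }
  attr(tiers, "xmax") <- xmax
  tiers
}

# --- TextGrid writing ---------------------------------------------------

#' Serialise an annotated conversation to long-format TextGrid text
#'
#' Times are printed with six decimal digits, so a write/parse round trip
#' preserves interval times to 1e-6 s. Tier order is preserved. Intervals
#' are written exactly as stored; tiers with explicit silence intervals
#' (empty labels) round-trip unchanged.
#'
#' @param conv An [annotated_conversation()].
#' @param path Optional file path; when given, the text is also written
#'   there (UTF-8).
#' @return The TextGrid text, invisibly when `path` is given.
#' @export
write_textgrid <- function(conv, path = NULL) {
  stopifnot(inherits(conv, "annotated_conversation"))
  q <- function(x) paste0("\"", gsub("\"", "\"\"", x), "\"")
  tm <- function(x) sprintf("%.6f", x)
  out <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    paste0("xmin = ", tm(0)),
    paste0("xmax = ", tm(conv$duration)),
    "tiers? <exists>",
    paste0("size = ", length(conv$tiers)),
    "item []:"
  )
  for (j in seq_along(conv$tiers)) {
    tier <- conv$tiers[[j]]
    iv <- tier$intervals
    out <- c(out,
      sprintf("    item [%d]:", j),
      "        class = \"IntervalTier\"",
      paste0("        name = ", q(tier$speaker_id)),
      paste0("        xmin = ", tm(0)),
      paste0("        xmax = ", tm(conv$duration)),
      paste0("        intervals: size = ", nrow(iv))
    )
    for (k in seq_len(nrow(iv))) {
      out <- c(out,
        sprintf("        intervals [%d]:", k),
        paste0("            xmin = ", tm(iv$start[k])),
        paste0("            xmax = ", tm(iv$end[k])),
        paste0("            text = ", q(iv$label[k]))
      )
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}
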