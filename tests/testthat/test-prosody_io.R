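test_that("long-format TextGrid parsing reads tiers, intervals and labels", {
  conv <- parse_textgrid(make_textgrid_text())
  expect_s3_class(conv, "annotated_conversation")
  expect_equal(conv$duration, 10)
  expect_named(conv$tiers, c("P1", "P2"))
  iv <- conv$tiers$P1$intervals
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 1)
  expect_true(iv$is_linguistic)
})

test_that("short-format TextGrid parses to the same conversation", {
  long <- parse_textgrid(make_textgrid_text())
  short <- parse_textgrid(make_textgrid_short())
  expect_equal(short$duration, long$duration)
  expect_equal(short$tiers$P1$intervals, long$tiers$P1$intervals)
  expect_equal(short$tiers$P2$intervals, long$tiers$P2$intervals)
})

test_that("non-linguistic labels are kept but flagged at parse time", {
  txt <- make_textgrid_text(intervals_p = list(
    c(0, 1, "hello"), c(2, 3, "laughter"), c(4, 5, "Stereotypy"),
    c(6, 7, "")
  ))
  conv <- parse_textgrid(txt)
  iv <- conv$tiers$P1$intervals
  expect_equal(nrow(iv), 4L)
  expect_equal(iv$is_linguistic, c(TRUE, FALSE, FALSE, FALSE))
  # a custom rule wins over the exclusion set
  conv2 <- parse_textgrid(txt, linguistic_rule = function(lab) nzchar(lab))
  expect_equal(conv2$tiers$P1$intervals$is_linguistic,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("write/parse round trip is the identity to 1e-6 s", {
  txt <- make_textgrid_text(
    intervals_p = list(c("0.123456789", "1.987654321", "hello")),
    intervals_q = list(c(3, 4, "laughter"))
  )
  conv <- parse_textgrid(txt)
  conv2 <- parse_textgrid(write_textgrid(conv))
  expect_equal(conv2$duration, conv$duration, tolerance = 1e-9)
  for (tn in c("P1", "P2")) {
    expect_lt(max(abs(conv2$tiers[[tn]]$intervals$start -
                        conv$tiers[[tn]]$intervals$start)), 1e-6)
    expect_lt(max(abs(conv2$tiers[[tn]]$intervals$end -
                        conv$tiers[[tn]]$intervals$end)), 1e-6)
    expect_equal(conv2$tiers[[tn]]$intervals$label,
                 conv$tiers[[tn]]$intervals$label)
    expect_equal(conv2$tiers[[tn]]$intervals$is_linguistic,
                 conv$tiers[[tn]]$intervals$is_linguistic)
  }
  expect_equal(abs(conv2$tiers$P1$intervals$start - 0.123456789) < 1e-6, TRUE)
  # a second round trip is byte-stable
  expect_identical(write_textgrid(conv2), write_textgrid(conv))
})

test_that("empty conversations serialise with the stated duration", {
  conv <- annotated_conversation("c", 10, list(
    speaker_tier("A", data.frame(start = numeric(0), end = numeric(0),
                                 label = character(0),
                                 is_linguistic = logical(0))),
    speaker_tier("B", data.frame(start = numeric(0), end = numeric(0),
                                 label = character(0),
                                 is_linguistic = logical(0)))
  ))
  txt <- write_textgrid(conv)
  expect_match(txt, "xmax = 10.000000", fixed = TRUE)
  back <- parse_textgrid(txt)
  expect_equal(back$duration, 10)
  expect_equal(nrow(back$tiers$A$intervals), 0L)
})

test_that("malformed and under-tiered files raise targeted errors", {
  expect_error(parse_textgrid("not a textgrid"), "line 1")
  bad <- sub("xmax = 10", "xmax = banana", make_textgrid_text())
  expect_error(parse_textgrid(bad), "parse error at line")
  one_tier <- paste(c(
    "File type = \"ooTextFile\"", "Object class = \"TextGrid\"", "",
    "xmin = 0", "xmax = 5", "tiers? <exists>", "size = 1", "item []:",
    "    item [1]:", "        class = \"IntervalTier\"",
    "        name = \"solo\"", "        xmin = 0", "        xmax = 5",
    "        intervals: size = 0"), collapse = "\n")
  expect_error(parse_textgrid(one_tier), "2 interval tiers")
})

test_that("pitch-track CSV reading enforces the grid invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,f0,voiced", "0.00,200,1", "0.01,210,1", "0.02,0,0"), path)
  tr <- read_f0_track(path)
  expect_equal(length(tr$times), 3L)
  expect_equal(tr$voiced, c(TRUE, TRUE, FALSE))
  expect_equal(tr$f0[1:2], c(200, 210))

  writeLines("time,f0,voiced", path)
  empty <- read_f0_track(path)
  expect_equal(length(empty$times), 0L)

  writeLines(c("time,f0,voiced", "0.00,200,1", "0.01,210,1", "0.03,220,1"), path)
  expect_error(read_f0_track(path), "equally spaced")

  writeLines(c("time,f0,voiced", "0.00,-5,1", "0.01,210,1"), path)
  expect_error(read_f0_track(path), "negative f0")
})

test_that("PitchTier text resamples onto the regular grid", {
  path <- withr::local_tempfile(fileext = ".PitchTier")
  writeLines(c(
    "File type = \"ooTextFile\"", "Object class = \"PitchTier\"", "",
    "0", "0.05", "3",
    "0.01", "200", "0.02", "210", "0.04", "215"
  ), path)
  tr <- read_f0_track(path)
  expect_equal(length(tr$times), 5L)
  expect_equal(tr$voiced, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(tr$f0[tr$voiced], c(200, 210, 215))
})

test_that("linguistic filtering applies the half-open window rule", {
  tr <- make_track(rep(200, 10))            # frames at 0.00 .. 0.09
  tier <- make_tier(rbind(c(0.03, 0.08)))
  out <- filter_linguistic(tr, tier)
  expect_equal(sum(out$voiced), 5L)
  expect_equal(out$times[out$voiced], c(0.03, 0.04, 0.05, 0.06, 0.07))
  # frame exactly at the interval end is outside
  expect_false(out$voiced[out$times == 0.08])
  # no linguistic intervals leaves nothing voiced
  none <- filter_linguistic(tr, make_tier(rbind(c(0.03, 0.08)),
                                          linguistic = FALSE))
  expect_equal(sum(none$voiced), 0L)
})

test_that("filtering is idempotent and never adds voiced frames", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    tr <- make_track(runif(n, 100, 300))
    tr$voiced <- runif(n) < 0.8
    k <- sample(1:4, 1)
    cuts <- sort(runif(2 * k, 0, n * 0.01))
    tier <- make_tier(cbind(cuts[seq(1, 2 * k, 2)], cuts[seq(2, 2 * k, 2)]))
    once <- filter_linguistic(tr, tier)
    twice <- filter_linguistic(once, tier)
    expect_lte(sum(once$voiced), sum(tr$voiced))
    expect_identical(twice$voiced, once$voiced)
    # no frame inside a non-linguistic interval survives filtering
    bad_tier <- tier
    bad_tier$intervals$is_linguistic <- FALSE
    expect_equal(sum(filter_linguistic(tr, bad_tier)$voiced), 0L)
  }
})

test_that("metadata reading validates groups, ages and scores", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- "dyad_id,participant_id,partner_id,group,age,gender,celf_core,nonverbal_iq,speaker_class_participant,speaker_class_partner"
  writeLines(c("# seed: 5", hdr,
               "d1,p1,RA1,ASD,12.5,M,88,107,teen_boy,adult_female"), path)
  meta <- read_metadata(path)
  expect_equal(meta$group, "ASD")
  expect_equal(meta$age, 12.5)
  writeLines(c(hdr, "d1,p1,RA1,XX,12.5,M,88,107,teen_boy,adult_female"), path)
  expect_error(read_metadata(path), "ASD or NT")
  writeLines(c(hdr, "d1,p1,RA1,ASD,150,M,88,107,teen_boy,adult_female"), path)
  expect_error(read_metadata(path), "plausible range")
  writeLines(c(hdr, "d1,p1,RA1,ASD,12.5,M,-3,107,teen_boy,adult_female"), path)
  expect_error(read_metadata(path), "positive")
})
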