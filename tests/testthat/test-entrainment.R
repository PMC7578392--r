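test_that("reference line selection follows the register-pairing rule", {
  expect_equal(select_reference_line("child", "adult_female")$slope, 1.0)
  expect_equal(select_reference_line("teen_girl", "adult_female")$slope, 1.0)
  expect_equal(select_reference_line("child", "adult_male")$slope, 1.0)
  l <- select_reference_line("teen_boy", "adult_female")
  expect_equal(l$slope, 0.5)
  expect_true(l$swap_axes)        # the boy (axis 1) goes on the halved axis
  l2 <- select_reference_line("adult_female", "teen_boy")
  expect_equal(l2$slope, 0.5)
  expect_false(l2$swap_axes)
  expect_equal(select_reference_line("teen_boy", "adult_male")$slope, 1.0)
  expect_equal(select_reference_line("child", "adult_female",
                                     override = 0.5)$slope, 0.5)
})

test_that("perpendicular distance matches examples and the sampling oracle", {
  expect_equal(point_to_line_distance(c(150, 150), reference_line(1)), 0)
  expect_equal(point_to_line_distance(c(200, 100), reference_line(0.5)), 0)
  expect_equal(point_to_line_distance(c(120, 100), reference_line(1)),
               14.1421, tolerance = 1e-4)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(2, 0, 500)
    m <- sample(c(0.5, 1, 2), 1)
    closed <- point_to_line_distance(p, reference_line(m))
    expect_equal(closed, brute_line_distance(p, m), tolerance = 1e-4)
  }
})

test_that("axis swap with reciprocal slope leaves distances unchanged", {
  set.seed(12)
  for (i in 1:50) {
    p <- runif(2, 50, 450)
    d_half <- point_to_line_distance(p, reference_line(0.5))
    d_two <- point_to_line_distance(rev(p), reference_line(2))
    expect_equal(d_half, d_two, tolerance = 1e-12)
    # the stored swap flag implements exactly that identity
    expect_equal(point_to_line_distance(p, reference_line(0.5, swap_axes = TRUE)),
                 point_to_line_distance(rev(p), reference_line(0.5)))
  }
})

test_that("delta entrainment reproduces the worked geometry", {
  feat <- feat_from_points(S = c(120, 100), E = c(110, 100))
  l1 <- reference_line(1)
  expect_equal(delta_entrainment(feat, l1), 7.0711, tolerance = 1e-4)
  expect_equal(delta_entrainment(feat_from_points(c(120, 100), c(120, 100)), l1), 0)
  # time reversal flips the sign
  rev_feat <- feat_from_points(S = c(110, 100), E = c(120, 100))
  expect_equal(delta_entrainment(rev_feat, l1), -7.0711, tolerance = 1e-4)
})

test_that("delta entrainment is translation invariant along the line", {
  set.seed(13)
  for (i in 1:30) {
    S <- runif(2, 80, 300); E <- runif(2, 80, 300)
    m <- sample(c(0.5, 1), 1)
    line <- reference_line(m)
    base <- delta_entrainment(feat_from_points(S, E), line)
    t <- runif(1, -50, 50)
    shift <- c(t, m * t)
    expect_equal(delta_entrainment(feat_from_points(S + shift, E + shift), line),
                 base, tolerance = 1e-9)
    # antisymmetry under swapping start and end
    expect_equal(delta_entrainment(feat_from_points(E, S), line), -base)
  }
})

test_that("responsibility splits the along-axis change and sums to one", {
  r <- speaker_responsibility(4, 6)
  expect_equal(r$resp1, 0.4)
  expect_equal(r$resp2, 0.6)
  expect_false(r$degenerate)
  expect_equal(speaker_responsibility(5, 0)$resp1, 1.0)
  deg <- speaker_responsibility(0, 0)
  expect_equal(c(deg$resp1, deg$resp2), c(0.5, 0.5))
  expect_true(deg$degenerate)
  set.seed(14)
  for (i in 1:30) {
    r <- speaker_responsibility(runif(1, 0, 20), runif(1, 0, 20))
    expect_equal(r$resp1 + r$resp2, 1)
  }
  # measured from feature points: |110-120| = 10 vs |100-100| = 0
  feat <- feat_from_points(S = c(120, 100), E = c(110, 100))
  expect_equal(speaker_responsibility(feat, k = "mean_f0")$resp1, 1)
})

test_that("signed and adjusted contributions carry the dyad's direction", {
  expect_equal(signed_contribution(-10, 0.4), -0.4)
  expect_equal(signed_contribution(10, 0.4), 0.4)
  expect_equal(signed_contribution(0, 0.7), 0)
  expect_equal(adjusted_contribution(10, 0.4), 4)
  expect_equal(adjusted_contribution(-10, 0.4), -4)
  # adjusted contributions always reassemble the dyad-level change
  set.seed(15)
  for (i in 1:30) {
    delta <- runif(1, -20, 20)
    r <- speaker_responsibility(runif(1, 0, 9), runif(1, 0, 9))
    expect_equal(adjusted_contribution(delta, r$resp1) +
                   adjusted_contribution(delta, r$resp2), delta)
    expect_lte(abs(signed_contribution(delta, r$resp1)), 1)
  }
})

test_that("classification uses an inclusive 1 Hz maintenance band", {
  expect_equal(classify_entrainment(0.5), "maintenance")
  expect_equal(classify_entrainment(-6), "divergence")
  expect_equal(classify_entrainment(1.0), "maintenance")
  expect_equal(classify_entrainment(-1.0), "maintenance")
  expect_equal(classify_entrainment(1.0001), "convergence")
  expect_equal(classify_entrainment(c(3, -2, 0)),
               c("convergence", "divergence", "maintenance"))
  expect_equal(classify_entrainment(1.5, maintenance_band = 2), "maintenance")
})

test_that("convergence counting is strict at the threshold", {
  out <- count_converging(c(3, -6, 2.0, 2.1))
  expect_equal(out$count, 2L)
  expect_equal(count_converging(c(0, 0, 0))$count, 0L)
  out12 <- count_converging(c(rep(5, 3), rep(-3, 9)))
  expect_equal(out12$count, 3L)
  expect_equal(out12$proportion, 0.25)
  expect_error(count_converging(numeric(0)), "at least one")
})

test_that("the full dyad record satisfies its internal identities", {
  set.seed(16)
  for (i in 1:20) {
    S <- runif(2, 80, 300); E <- runif(2, 80, 300)
    feat <- feat_from_points(S, E)
    line <- reference_line(sample(c(0.5, 1), 1))
    row <- dyad_entrainment(feat, line)
    expect_equal(row$delta_ent, row$d1 - row$d2)
    expect_equal(row$resp1 + row$resp2, 1)
    expect_equal(row$adjusted1 + row$adjusted2, row$delta_ent)
    expect_equal(row$contribution1, sign(row$delta_ent) * row$resp1)
    expect_gte(min(row$d1, row$d2, row$d3, row$d4), 0)
    expect_equal(row$delta_gap,
                 abs(S[1] - S[2]) - abs(E[1] - E[2]))
  }
})

test_that("min-over-lines scoring never exceeds the single-line distance", {
  feat <- feat_from_points(S = c(200, 150), E = c(200, 180))
  line <- reference_line(1)
  d_single <- dyad_entrainment(feat, line)
  d_min <- dyad_entrainment(feat, line, min_over_lines = TRUE)
  expect_lte(d_min$d1, d_single$d1)
  expect_lte(d_min$d2, d_single$d2)
})
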