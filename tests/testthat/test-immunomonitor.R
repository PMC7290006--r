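test_that("spot normalization scales to 1e5 effectors and subtracts background", {
  plate <- make_plate(list(AG1 = c(30L, 40L, 50L)), control = c(0L, 0L, 0L))
  n <- normalize_spots(plate)
  expect_equal(n$value, 100)  # mean 40 at 4e4 cells -> 100 / 1e5
  expect_false(n$censored)

  # stimulated mean equal to background floors at zero
  plate2 <- make_plate(list(AG1 = c(10L, 10L, 10L)), control = c(10L, 10L, 10L))
  expect_equal(normalize_spots(plate2)$value, 0)

  # any replicate at the quantification limit flags censoring
  plate3 <- make_plate(list(AG1 = c(350L, 100L, 120L)), control = c(0L, 0L, 0L))
  expect_true(normalize_spots(plate3)$censored)

  # missing unstimulated control is an error
  plate4 <- plate[plate$antigen != "NONE", ]
  expect_error(normalize_spots(plate4), "control")
})

test_that("positivity rules have documented boundary behavior", {
  expect_true(call_positive(100, 0, rule = "excess"))
  expect_false(call_positive(0, 0, rule = "excess"))
  # fold rule at exactly 2x background: positive iff strict flag off
  expect_true(call_positive(20, 10, rule = "fold", fold = 2, strict = FALSE))
  expect_false(call_positive(20, 10, rule = "fold", fold = 2, strict = TRUE))
})

test_that("ELISPOT score adds magnitude and diversity", {
  s <- elispot_score(c(100, 200, 300, rep(0, 7)),
                     c(TRUE, TRUE, TRUE, rep(FALSE, 7)))
  expect_equal(s$magnitude, 200)
  expect_equal(s$diversity, 0.3)
  expect_equal(s$score, 200.3)

  s0 <- elispot_score(rep(0, 10), rep(FALSE, 10))
  expect_equal(s0$score, 0)

  s1 <- elispot_score(rep(50, 10), rep(TRUE, 10))
  expect_equal(s1$magnitude, 50)
  expect_equal(s1$diversity, 1.0)
  expect_equal(s1$score, 51.0)
  expect_error(elispot_score(numeric(0), logical(0)), "no antigens")
})

test_that("heat-map bins follow the display scale with half-open closure", {
  expect_equal(heatmap_bin(100), 1L)
  expect_equal(heatmap_bin(400), 3L)
  expect_equal(heatmap_bin(650), 4L)
  expect_equal(heatmap_bin(c(175, 176, 350, 351, 525, 526, 800)),
               c(1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(heatmap_bin(0), 0L)
  expect_equal(heatmap_bin(500, positive = FALSE), 0L)
})

test_that("DTH grading follows the erythema scale and scores sum to 0..16", {
  expect_equal(as.integer(dth_grade("macular", 0.4)), 0L)
  expect_equal(as.integer(dth_grade("macular", 1.5)), 2L)
  expect_equal(as.integer(dth_grade("papular", 2.5)), 4L)
  expect_equal(as.integer(dth_grade("macular", c(0.5, 1.0, 1.1, 2.0, 2.1))),
               c(1L, 1L, 2L, 2L, 3L))
  # papular <= 2 cm: macular grade + 1, capped, flagged
  g <- dth_grade("papular", 1.5)
  expect_equal(as.integer(g), 3L)
  expect_true(attr(g, "flagged"))
  expect_equal(as.integer(dth_grade("papular", 2.0)), 3L)

  # grades (1,2,3,3) -> score 9
  expect_equal(dth_score(rep("macular", 4), c(0.8, 1.5, 2.5, 2.5)), 9L)
  expect_error(dth_score("macular", 1), "4 readings")
  expect_error(dth_grade("macular", -1), "negative")

  # monotone: enlarging any reading never decreases the score
  set.seed(41)
  for (i in 1:50) {
    d <- runif(4, 0, 3)
    ty <- sample(c("macular", "papular"), 4, TRUE)
    s1 <- dth_score(ty, d)
    j <- sample(4, 1)
    d2 <- d
    d2[j] <- d[j] + runif(1, 0, 2)
    expect_gte(dth_score(ty, d2), s1)
  }
})

test_that("correlation matches a from-scratch covariance computation", {
  mk <- function(x, col) data.frame(patient = "p", timepoint = seq_along(x),
                                    stats::setNames(list(x), col))
  r1 <- correlate_scores(mk(1:4, "dth_score"), mk(c(1, 2, 3, 4) * 2, "score"))
  expect_equal(r1$r, 1)
  r2 <- correlate_scores(mk(1:4, "dth_score"), mk(-(1:4), "score"))
  expect_equal(r2$r, -1)
  want <- pearson_oracle(c(1, 2, 3, 4), c(2, 4, 6, 9))
  r3 <- correlate_scores(mk(1:4, "dth_score"), mk(c(2, 4, 6, 9), "score"))
  expect_equal(r3$r, want$r, tolerance = 1e-12)
  expect_equal(r3$p_value, want$p, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- correlate_scores(mk(x, "dth_score"), mk(y, "score"))
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  expect_error(correlate_scores(mk(c(1, 1, 1), "dth_score"),
                                mk(1:3, "score")), "variance")
})

test_that("specific lysis applies the release formula and flags out-of-range", {
  expect_equal(as.numeric(specific_lysis(100, 100, 600)), 0)
  expect_equal(as.numeric(specific_lysis(600, 100, 600)), 100)
  expect_equal(as.numeric(specific_lysis(350, 100, 600)), 50)
  fl <- specific_lysis(c(50, 700), 100, 600)
  expect_equal(attr(fl, "flagged"), c(TRUE, TRUE))
  expect_error(specific_lysis(100, 200, 150), "exceed")
})

test_that("TMB divides mutation counts by exome size", {
  expect_equal(tmb(300, 0, 30), 10)
  expect_equal(tmb(0, 0, 30), 0)
  expect_equal(tmb(250, 50, 20), 15)
  expect_equal(tmb(400, 44, 30), 14.8)
  expect_error(tmb(1, 1, 0), "exome_mb")
})
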