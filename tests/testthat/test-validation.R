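# Accuracy assessment: buffered point sampling, confusion matrices,
# kappa, Z comparison, digitizer QA and sample-size design.

test_that("site buffers have the closed-form disc area", {
  site <- ground_truth_site(0, 0, "mangrove")
  expect_equal(site$buffer_area_ha, pi * 100^2 / 1e4)
  expect_equal(round(site$buffer_area_ha, 2), 3.14)
  expect_error(ground_truth_site(0, 0, "mangrove", buffer_radius = -5),
               "positive")
})

test_that("validation points are uniform in the disc and reproducible", {
  site <- ground_truth_site(1000, -500, "mangrove")
  a <- sample_validation_points(site, 500, seed = 7)
  b <- sample_validation_points(site, 500, seed = 7)
  expect_identical(a, b)
  big <- sample_validation_points(site, 1e5, seed = 1)
  r <- sqrt((big$x - 1000)^2 + (big$y + 500)^2)
  expect_true(all(r <= 100))
  # mean distance from centre of a uniform disc is 2R/3
  expect_equal(mean(r), 2 * 100 / 3, tolerance = 0.01)
})

test_that("confusion tallies map against truth with boundary points mangrove", {
  map <- square_layer(list(c(0, 0, 100)))
  pts <- data.frame(x = c(50, 150, 50, 150, 0),
                    y = c(50, 50, 60, 60, 50),
                    truth = c("mangrove", "non-mangrove", "non-mangrove",
                              "mangrove", "mangrove"))
  cm <- confusion(map, pts)
  expect_equal(sum(cm), 5)
  expect_equal(cm["mangrove", "mangrove"], 2)       # (50,50) + boundary (0,50)
  expect_equal(cm["mangrove", "non-mangrove"], 1)   # (50,60)
  expect_equal(cm["non-mangrove", "mangrove"], 1)   # (150,60)
  expect_error(confusion(map, pts[0, ]), "empty")
})

test_that("a planted disagreement rate is recovered exactly", {
  set.seed(31)
  map <- square_layer(list(c(0, 0, 1000)))
  n <- 400
  pts <- data.frame(x = runif(n, 10, 990), y = runif(n, 10, 990),
                    truth = "mangrove")
  flip <- sample(n, 20)  # plant 5% disagreement
  pts$truth[flip] <- "non-mangrove"
  cm <- confusion(map, pts)
  expect_equal(cm["mangrove", "non-mangrove"], 20)
  expect_equal(overall_accuracy(cm), 95)
})

test_that("overall accuracy and kappa match their formulas", {
  expect_equal(overall_accuracy(confusion_matrix(rbind(c(450, 0), c(0, 50)))), 100)
  cm <- confusion_matrix(rbind(c(45, 5), c(5, 45)))
  expect_equal(overall_accuracy(cm), 90)
  expect_equal(cohens_kappa(cm), 0.8)
  expect_equal(cohens_kappa(confusion_matrix(rbind(c(450, 0), c(0, 50)))), 1)
  expect_warning(k <- cohens_kappa(confusion_matrix(rbind(c(100, 0), c(0, 0)))),
                 "degenerate")
  expect_true(is.na(k))
  # independent random labels give kappa near zero
  set.seed(8)
  m <- sample(c(TRUE, FALSE), 1e4, replace = TRUE)
  t <- sample(c(TRUE, FALSE), 1e4, replace = TRUE)
  cmr <- confusion_matrix(table(factor(m, c(TRUE, FALSE)),
                                factor(t, c(TRUE, FALSE))))
  expect_lt(abs(cohens_kappa(cmr)), 0.05)
  expect_equal(overall_accuracy(cmr), 50, tolerance = 0.05)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(13)
  for (i in 1:10) {
    cm <- matrix(sample(5:200, 4), 2, 2)
    expect_equal(cohens_kappa(confusion_matrix(cm)),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
  }
})

test_that("Z comparison reproduces its formula and is antisymmetric", {
  z <- z_compare(450, 500, 450, 500)
  expect_equal(z$z, 0)
  expect_false(z$significant)
  a <- z_compare(480, 500, 440, 500)
  b <- z_compare(440, 500, 480, 500)
  expect_equal(a$z, -b$z)
  expect_equal(a$rho, 920 / 1000)
  expect_error(z_compare(0, 500, 0, 500), "degenerate")
  expect_error(z_compare(500, 500, 500, 500), "degenerate")
})

test_that("Z test holds its nominal type-I error rate", {
  set.seed(99)
  nsim <- 2000
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    x1 <- rbinom(1, 500, 0.9); x2 <- rbinom(1, 500, 0.9)
    rej[i] <- abs(z_compare(x1, 500, x2, 500)$z) >= 1.96
  }
  expect_equal(mean(rej) * 100, 5, tolerance = 1.5 / 5)  # 5% +/- 1.5 points
})

test_that("digitizer QA measures coinciding perimeter fractions", {
  sq <- unit_square(100)
  exact <- digitizer_qa(sq, sq, tol = 1)
  expect_equal(exact$fraction, 1)
  expect_true(exact$accurate)
  far <- digitizer_qa(translate_patch(sq, c(1000, 0)), sq, tol = 1)
  expect_equal(far$fraction, 0)
  expect_false(far$accurate)
  # one side displaced outward by 3x the tolerance: ~3/4 of the
  # (slightly stretched) boundary still coincides
  disp <- patch_polygon(cbind(c(0, 100, 100, 0), c(0, 0, 103, 103)))
  qa <- digitizer_qa(disp, sq, tol = 1)
  expect_equal(qa$fraction, 0.75, tolerance = 0.02)
  expect_true(qa$accurate)
})

test_that("per-stratum digitization error rates match hand division", {
  tab <- qa_error_rate(c(Isabela = 82, SanCristobal = 77, Baltra = 3),
                      c(37, 8, 0))
  expect_equal(round(tab$error_pct, 2), c(45.12, 10.39, 0))
  expect_error(qa_error_rate(c(10), c(11)))
})

test_that("survey sample sizes reproduce Cochran and fractional designs", {
  expect_equal(survey_sample_size(4099, 0.05, 2.58), 573L)
  expect_equal(fraction_sample_size(4099, 0.08), 328L)
  # margin -> 0 saturates at the population
  expect_equal(survey_sample_size(50, 0.001, 2.58), 50L)
  expect_equal(survey_sample_size(4099, 0.05, 1.96), 352L)
})

test_that("repeated validation reports mean accuracy across repeats", {
  map <- square_layer(list(c(-100, -100, 200)))
  sites <- list(ground_truth_site(0, 0, "mangrove", 50),
                ground_truth_site(500, 500, "non-mangrove", 50))
  v <- validate_map(map, sites, n_points = 200, repeats = 3, seed = 4)
  expect_equal(nrow(v$per_repeat), 3)
  expect_equal(v$mean_accuracy_pct, 100)
  expect_equal(v$mean_kappa, 1)
})
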