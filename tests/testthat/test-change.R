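# STAMP events, change summaries, K-S size comparison, epoch alignment.

test_that("identical epochs are entirely stable", {
  l <- square_layer(list(c(0, 0, 100), c(500, 0, 50)), epoch = 2004)
  l1 <- l; l1$epoch <- 2014
  ev <- stamp_events(l, l1)
  expect_true(all(ev$category[ev$area_m2 > 0] == "STB"))
  expect_equal(sum(ev$area_m2[ev$category == "STB"]), 100^2 + 50^2)
})

test_that("a concentric enlarged square splits into STB and EXP only", {
  l <- square_layer(list(c(0, 0, 100)), epoch = 2004)
  l1 <- square_layer(list(c(-2.5, -2.5, 105)), epoch = 2014)
  ev <- stamp_events(l, l1)
  tot <- tapply(ev$area_m2, ev$category, sum)
  expect_equal(unname(tot["STB"]), 10000)
  expect_equal(unname(tot["EXP"]), 11025 - 10000)
  expect_true(is.na(tot["CON"]) || tot["CON"] == 0)
})

test_that("patches beyond the threshold become DIS and GEN", {
  l <- square_layer(list(c(0, 0, 10)), epoch = 2004)
  l1 <- square_layer(list(c(30, 0, 10)), epoch = 2014)  # 20 m gap > 15 m
  ev <- stamp_events(l, l1, dist_threshold = 15)
  expect_setequal(ev$category, c("DIS", "GEN"))
  # and within the threshold they form one STB/CON/EXP group
  ev2 <- stamp_events(l, l1, dist_threshold = 25)
  expect_setequal(ev2$category, c("STB", "CON", "EXP"))
  expect_equal(ev2$area_m2[ev2$category == "STB"], 0)
})

test_that("CRS mismatch is refused", {
  a <- square_layer(list(c(0, 0, 10)))
  b <- square_layer(list(c(0, 0, 10)))
  b$crs <- "other"
  expect_error(stamp_events(a, b), "reference-system")
})

test_that("time reversal swaps EXP with CON and GEN with DIS", {
  set.seed(17)
  for (i in 1:20) {
    pair <- random_epoch_pair(n_groups = 4)
    fwd <- stamp_events(pair$t, pair$t1)
    rev <- stamp_events(pair$t1, pair$t)
    tot <- function(ev, k) sum(ev$area_m2[ev$category == k])
    expect_equal(tot(fwd, "STB"), tot(rev, "STB"), tolerance = 1e-9)
    expect_equal(tot(fwd, "EXP"), tot(rev, "CON"), tolerance = 1e-9)
    expect_equal(tot(fwd, "GEN"), tot(rev, "DIS"), tolerance = 1e-9)
  }
})

test_that("area conservation identities hold on random epoch pairs", {
  set.seed(23)
  for (i in 1:150) {
    pair <- random_epoch_pair(n_groups = sample(2:5, 1))
    ev <- stamp_events(pair$t, pair$t1)
    tot <- function(k) sum(ev$area_m2[ev$category == k])
    expect_equal(tot("STB") + tot("CON") + tot("DIS"), area(pair$t),
                 tolerance = 1e-6)
    expect_equal(tot("STB") + tot("EXP") + tot("GEN"), area(pair$t1),
                 tolerance = 1e-6)
  }
})

test_that("scripted generator events are recovered exactly", {
  ls <- generate_landscape(landscape_script(seed = 5, n_patches = 50),
                           scene = FALSE)
  ev <- stamp_events(ls$layer_t, ls$layer_t1, 15)
  tot <- function(k) sum(ev$area_m2[ev$category == k])
  led <- ls$ledger
  expect_equal(tot("STB"), sum(led$stb), tolerance = 1e-9)
  expect_equal(tot("EXP"), sum(led$expa), tolerance = 1e-9)
  expect_equal(tot("CON"), sum(led$con), tolerance = 1e-9)
  expect_equal(tot("GEN"), sum(led$gen), tolerance = 1e-9)
  expect_equal(tot("DIS"), sum(led$dis), tolerance = 1e-9)
})

test_that("change summaries normalise by coastline length and report the increase", {
  l <- square_layer(list(c(0, 0, 100)), epoch = 2004)
  l1 <- square_layer(list(c(-2.5, -2.5, 105)), epoch = 2014)
  coast <- coastline_layer(cbind(c(0, 2000), c(200, 200)))
  sm <- change_summary(stamp_events(l, l1), coast)
  expect_equal(sm$area_t_ha, 1)
  expect_equal(sm$area_t1_ha, 1.1025)
  expect_equal(sm$increase_pct, 10.25)
  expect_equal(sm$per_category$ha_per_km[sm$per_category$category == "STB"],
               1 / 2)
  # printed-cover arithmetic
  expect_equal(round(cover_increase_pct(203.7, 251.9), 1), 23.7)
  expect_equal(round(cover_increase_pct(118.8, 130.4), 1), 9.8)
})

test_that("no-change summaries have empty dynamic categories", {
  l <- square_layer(list(c(0, 0, 100)), epoch = 2004)
  l1 <- l; l1$epoch <- 2014
  sm <- change_summary(stamp_events(l, l1),
                       coastline_layer(cbind(c(0, 1000), c(50, 50))))
  dyn <- sm$per_category$area_ha[sm$per_category$category != "STB"]
  expect_true(all(dyn == 0))
})

test_that("K-S statistic spans its extremes and holds its size", {
  same <- ks_two_sample(1:50, 1:50)
  expect_equal(same$D, 0)
  disj <- ks_two_sample(1:50, 101:150)
  expect_equal(disj$D, 1)
  set.seed(41)
  rej <- replicate(2000, {
    ks_two_sample(runif(100), runif(100))$p_value < 0.05
  })
  expect_equal(mean(rej) * 100, 5, tolerance = 2 / 5)  # 5% +/- 2 points
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("epoch alignment is a rigid motion", {
  l <- square_layer(list(c(0, 0, 100), c(300, 10, 40)))
  expect_equal(align_epochs(l, c(0, 0)), l)
  back <- align_epochs(align_epochs(l, c(12.5, -7)), c(-12.5, 7))
  expect_equal(back, l)
  sh <- align_epochs(l, c(3, 4))
  d <- sqrt(rowSums((sh$patches[[1]]$exterior - l$patches[[1]]$exterior)^2))
  expect_true(all(abs(d - 5) < 1e-12))
  expect_equal(area(sh), area(l))
})
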