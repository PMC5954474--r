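test_that("pearson matches a direct product-moment evaluation", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("pearson handles perfect, hand-computed and degenerate cases", {
  x <- 1:5
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  # zero variance is flagged, not an error
  flat <- pearson(rep(2, 5), rnorm(5))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("depth zones partition 0-1000 m with half-open bounds", {
  expect_equal(classify_depth_zone(c(0, 5, 9.999)), c("A", "A", "A"))
  expect_equal(classify_depth_zone(c(10, 39.9)), c("B", "B"))
  expect_equal(classify_depth_zone(c(40, 100, 199.9)),
               rep("ignorance", 3))
  expect_equal(classify_depth_zone(c(200, 300, 499.9)), rep("C", 3))
  expect_equal(classify_depth_zone(c(500, 1000)), c("D", "D"))
  expect_equal(classify_depth_zone(1000.1), "out-of-range")
  # every depth maps to exactly one zone
  depths <- seq(0, 1000, by = 0.25)
  z <- classify_depth_zone(depths)
  expect_true(all(z %in% c("A", "B", "ignorance", "C", "D")))
  expect_equal(length(z), length(depths))
  # configurable bounds are honoured
  expect_equal(classify_depth_zone(45, bounds = c(a_b = 10, b_ign = 50,
                                                  ign_c = 200, c_d = 500,
                                                  max = 1000)), "B")
})

test_that("zone correlations recover the generator's sign structure", {
  zr <- zone_correlations(gen_benthic_samples(50, seed = 42))
  got <- setNames(zr$sign_class, zr$zone)
  expect_equal(got[["A"]], "positive")
  expect_equal(got[["B"]], "none")
  expect_equal(got[["ignorance"]], "insufficient")
  expect_equal(got[["C"]], "negative")
  expect_equal(got[["D"]], "none")
  expect_true(all(is.na(zr$r) | abs(zr$r) <= 1))
  expect_match(attr(zr, "metadata")$multiple_testing, "none")
})

test_that("degenerate zones are flagged insufficient", {
  # constant blue carbon within a zone: undefined correlation
  const <- data.frame(depth = runif(10, 0, 9), seaice_duration = runif(10, 50, 300),
                      blue_carbon = 5)
  zr <- zone_correlations(const)
  expect_equal(zr$sign_class[zr$zone == "A"], "insufficient")
  # fewer than min_n samples
  tiny <- data.frame(depth = c(2, 3), seaice_duration = c(100, 200),
                     blue_carbon = c(4, 5))
  expect_equal(zone_correlations(tiny)$sign_class[1], "insufficient")
  expect_error(zone_correlations(const[0, ]), "no samples")
})

test_that("a pattern concatenated with its mirror cancels to 'none'", {
  set.seed(7)
  ice <- runif(60, 50, 300)
  up <- data.frame(depth = runif(60, 0, 9), seaice_duration = ice,
                   blue_carbon = 10 + 0.05 * ice)
  down <- data.frame(depth = runif(60, 0, 9), seaice_duration = ice,
                     blue_carbon = 10 + 0.05 * (350 - ice))
  zr <- zone_correlations(rbind(up, down))
  expect_equal(zr$sign_class[zr$zone == "A"], "none")
})

test_that("fast-ice scour fit finds the negative relationship", {
  noiseless <- gen_monitoring_series(12, seed = 3, noise_sd = 0)
  fit <- fastice_scour_fit(noiseless)
  expect_equal(fit$r, -1)
  expect_equal(fit$slope, -(0.9 - 0.05) / 300, tolerance = 1e-10)

  noisy <- fastice_scour_fit(gen_monitoring_series(14, seed = 5))
  expect_lt(noisy$r, -0.7)
  expect_lt(noisy$p, 0.05)

  flat <- data.frame(fastice_duration = c(100, 200, 300),
                     scoured_proportion = c(0.2, 0.2, 0.2))
  expect_false(fastice_scour_fit(flat)$defined)
  expect_error(fastice_scour_fit(noiseless[1, , drop = FALSE]), "3 years")
})
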