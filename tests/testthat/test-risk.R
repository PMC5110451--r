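test_that("OEL derivation composes the documented factors", {
  expect_equal(derive_oel(dose_response_config(1000)), 10)          # NOAEL/100
  expect_equal(derive_oel(dose_response_config(500, uncertainty_factor = 1)), 500)
  expect_equal(derive_oel(dose_response_config(1000, pod_kind = "LOAEL")), 1)
  # linear (CMR) mode adds the extrapolation divisor
  expect_equal(derive_oel(dose_response_config(1000, cmr = TRUE)), 1)
  expect_error(dose_response_config(-5), "positive")
  expect_error(dose_response_config(10, uncertainty_factor = 0.5), ">= 1")
})

test_that("point-mass hazard quotients reduce to scalar ratios", {
  fc <- hazard_quotient(point_mass(5), point_mass(10))
  expect_equal(fc$mean_hq, 50)
  expect_equal(unname(fc$interval_90), c(50, 50))
  fc2 <- hazard_quotient(point_mass(10), point_mass(10))
  expect_equal(fc2$mean_hq, 100)
  expect_error(hazard_quotient(point_mass(5), point_mass(0)), "non-positive")
})

test_that("forecast matches a million-draw Monte-Carlo ratio oracle", {
  exposure <- bin_distribution(c(0.2, 0.5, 0.3), representative = c(2, 8, 30))
  oel <- bin_distribution(c(0.25, 0.45, 0.3), representative = c(1, 5, 20))
  fc <- hazard_quotient(exposure, oel)
  set.seed(1234)
  n <- 1e6
  draws <- 100 * sample(exposure$representative, n, TRUE, exposure$prob) /
    sample(oel$representative, n, TRUE, oel$prob)
  expect_equal(fc$mean_hq, mean(draws), tolerance = 0.005)
  q <- unname(stats::quantile(draws, c(0.05, 0.95), type = 1))
  expect_equal(unname(fc$interval_90), q, tolerance = 0.005)
  expect_equal(sum(fc$hq_distribution$prob), 1, tolerance = 1e-9)
  expect_equal(sum(fc$atoms$prob), 1, tolerance = 1e-9)
})

test_that("mean HQ scales with concentration and falls as the OEL rises", {
  exposure <- bin_distribution(c(0.2, 0.5, 0.3), representative = c(2, 8, 30))
  oel <- bin_distribution(c(0.5, 0.5), representative = c(4, 16))
  base <- hazard_quotient(exposure, oel)$mean_hq
  for (k in c(0.1, 2, 7)) {
    scaled <- bin_distribution(exposure$prob,
                               representative = exposure$representative * k)
    expect_equal(hazard_quotient(scaled, oel)$mean_hq, k * base,
                 tolerance = 1e-9)
  }
  hq_at <- vapply(c(1, 5, 25, 125), function(o)
    hazard_quotient(exposure, point_mass(o))$mean_hq, 0)
  expect_true(all(diff(hq_at) < 0))
})

test_that("control banding crosses acceptable -> potential risk exactly at 100%", {
  expect_identical(as.character(classify_risk(50)), "caution")
  expect_identical(as.character(classify_risk(100)), "caution")   # strict >
  expect_identical(as.character(classify_risk(100 + 1e-9)), "potential risk")
  expect_identical(as.character(classify_risk(250)), "potential risk")
  expect_identical(as.character(classify_risk(5)), "negligible")
  expect_identical(as.character(classify_risk(2000)), "high risk")
  fc <- hazard_quotient(point_mass(5), point_mass(10))
  expect_identical(as.character(classify_risk(fc)), "caution")
  expect_identical(fc$band, classify_risk(fc))
})

test_that("higher dispersibility does not lower the posterior mean concentration", {
  net <- default_network("CNT")
  mean_conc <- function(ev) {
    d <- exposure_posterior(net, ev)
    sum(d$representative * d$prob)
  }
  expect_gte(mean_conc(c(dispersibility = "high")),
             mean_conc(c(dispersibility = "low")))
})

test_that("evidence fixing the concentration bin gives a point-mass exposure", {
  net <- default_network("CNT")
  s <- net$variables$concentration$states[3]
  d <- exposure_posterior(net, stats::setNames(s, "concentration"))
  expect_equal(d$prob[3], 1)
  expect_equal(sum(d$prob), 1)
})

test_that("heat-map points carry means, intervals and consistent bands", {
  fcs <- lapply(c("TiO2", "Ag", "CNT"), function(m) {
    net <- truth_network(m)
    hazard_quotient(exposure_posterior(net), oel_posterior(net))
  })
  pts <- do.call(rbind, Map(heatmap_point, fcs, c("TiO2", "Ag", "CNT")))
  expect_identical(nrow(pts), 3L)
  expect_identical(anyDuplicated(pts[, c("oel", "concentration")]), 0L)
  # band ordering matches the ground-truth HQ ordering
  band_rank <- match(pts$band, c("negligible", "caution", "potential risk", "high risk"))
  expect_true(all(diff(order(pts$mean_hq)) > 0))
  expect_true(all(diff(band_rank[order(pts$mean_hq)]) >= 0))
})

test_that("on symmetric inputs the point lies inside its own 90% rectangle", {
  sym <- function(reps) bin_distribution(c(0.1, 0.2, 0.4, 0.2, 0.1),
                                         representative = reps)
  fc <- hazard_quotient(sym(c(2, 4, 6, 8, 10)), sym(c(5, 10, 15, 20, 25)))
  pt <- heatmap_point(fc)
  expect_true(pt$oel_lo <= pt$oel && pt$oel <= pt$oel_hi)
  expect_true(pt$conc_lo <= pt$concentration && pt$concentration <= pt$conc_hi)
  expect_true(fc$interval_90[["lo"]] <= fc$mean_hq &&
                fc$mean_hq <= fc$interval_90[["hi"]])
})

test_that("point-mass inputs give degenerate heat-map coordinates", {
  fc <- hazard_quotient(point_mass(5), point_mass(10))
  pt <- heatmap_point(fc, "pt")
  expect_equal(pt$oel, 10)
  expect_equal(pt$concentration, 5)
  expect_equal(pt$oel_lo, 10)
  expect_equal(pt$conc_hi, 5)
})

test_that("forecast accessors and plot builders work", {
  net <- truth_network("Ag")
  fc <- hazard_quotient(exposure_posterior(net), oel_posterior(net))
  gl <- glance(fc)
  expect_identical(names(gl)[1], "mean_hq")
  td <- tidy(fc)
  expect_equal(sum(td$prob), 1, tolerance = 1e-9)
  p <- autoplot(fc)
  expect_s3_class(p, "ggplot")
  p2 <- plot_control_banding(do.call(rbind, list(heatmap_point(fc, "Ag"))))
  expect_s3_class(p2, "ggplot")
})
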