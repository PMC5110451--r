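test_that("material truths share structure and pass validation", {
  nets <- lapply(c("CNT", "Ag", "TiO2"), truth_network)
  for (net in nets) expect_true(net$validated)
  for (i in 2:3) {
    expect_identical(nets[[1]]$edges, nets[[i]]$edges)
    expect_identical(lapply(nets[[1]]$variables, `[[`, "states"),
                     lapply(nets[[i]]$variables, `[[`, "states"))
  }
})

test_that("mean HQ of the three truths respects the configured ordering", {
  mean_hq <- function(material, order) {
    net <- truth_network(material, hq_order = order)
    hazard_quotient(exposure_posterior(net), oel_posterior(net))$mean_hq
  }
  default_order <- c("TiO2", "Ag", "CNT")
  hqs <- vapply(default_order, mean_hq, 0, order = default_order)
  expect_true(all(diff(hqs) > 0))
  # the ordering is configurable
  flipped <- rev(default_order)
  hqs2 <- vapply(flipped, mean_hq, 0, order = flipped)
  expect_true(all(diff(hqs2) > 0))
})

test_that("fixtures are deterministic and match the study row counts", {
  f1 <- generate_cases(fixture_spec("CNT", seed = 7))
  f2 <- generate_cases(fixture_spec("CNT", seed = 7))
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(46L, 14L))
  expect_identical(nrow(generate_cases(fixture_spec("Ag", seed = 1))), 39L)
  expect_identical(nrow(generate_cases(fixture_spec("TiO2", seed = 1))), 55L)
  # byte-identical on disk too
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cases(f1, p1); write_cases(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draw
  expect_false(identical(f1, generate_cases(fixture_spec("CNT", seed = 8))))
})

test_that("missing_rate 0 yields a complete table; 0.3 masks about 30%", {
  complete <- generate_cases(fixture_spec("CNT", missing_rate = 0, seed = 3))
  expect_false(anyNA(complete))
  masked <- generate_cases(fixture_spec("CNT", n_rows = 2000, seed = 3))
  expect_equal(mean(is.na(as.matrix(masked))), 0.3, tolerance = 0.02)
})

test_that("per-column missingness weights shift where cells go missing", {
  fix <- fixture_spec("CNT", n_rows = 3000, seed = 5,
                      missing_weights = c(coating = 2, oel = 0))
  tab <- generate_cases(fix)
  expect_false(anyNA(tab$oel))
  expect_gt(mean(is.na(tab$coating)), mean(is.na(tab$ph)))
})

test_that("sampled joint frequencies match the truth joint (chi-square)", {
  net <- four_node_net()
  tab <- generate_cases(fixture_spec("custom", n_rows = 50000, missing_rate = 0,
                                     seed = 17, truth = net))
  # exact joint over all 24 configurations, first variable fastest
  card <- vapply(net$variables, function(v) length(v$states), 0L)
  grid <- expand.grid(lapply(net$variables, `[[`, "states"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  probs <- apply(grid, 1L, function(row) {
    ev <- stats::setNames(as.character(row), names(card))
    exp(log_evidence(net, ev))
  })
  key <- do.call(paste, c(tab, sep = "|"))
  ref <- do.call(paste, c(grid, sep = "|"))
  counts <- as.numeric(table(factor(key, levels = ref)))
  expect_gt(stats::chisq.test(counts, p = probs / sum(probs))$p.value, 0.01)
})

test_that("a correctly specified model attains nominal predictive coverage", {
  truth <- truth_network("CNT")
  rep <- out_of_sample_check(truth, truth, n_test = 400, seed = 11)
  expect_gte(rep$coverage, 90)
  expect_gte(rep$mean_set_mass, 0.9)
})

test_that("a uniform-CPT model still covers but with near-vacuous sets", {
  truth <- truth_network("CNT")
  flat <- truth
  for (v in names(flat$cpts)) {
    pr <- flat$cpts[[v]]$prob
    flat$cpts[[v]]$prob <- matrix(1 / ncol(pr), nrow(pr), ncol(pr))
  }
  flat <- validate_network(flat)
  sharp <- out_of_sample_check(truth, truth, n_test = 150, seed = 2)
  vague <- out_of_sample_check(truth, flat, n_test = 150, seed = 2)
  expect_gte(vague$coverage, 90)
  expect_gt(vague$mean_set_size, sharp$mean_set_size)  # width flag
})

test_that("structure mismatches and empty test draws are rejected", {
  truth <- truth_network("CNT")
  expect_error(out_of_sample_check(truth, truth, n_test = 0), ">= 1")
  expect_error(out_of_sample_check(truth, six_node_net(), n_test = 10),
               "structure")
  expect_error(fixture_spec("CNT", missing_rate = 1), "missing_rate")
  expect_error(fixture_spec("CNT", n_rows = 0), "n_rows")
})

test_that("the pipeline closes end-to-end on a generated fixture", {
  fix <- fixture_spec("CNT", seed = 7)
  cases <- generate_cases(fix)
  fit <- em_fit(truth_network("CNT"), cases, max_iter = 40, seed = 7)
  fc <- hazard_quotient(exposure_posterior(fit$network),
                        oel_posterior(fit$network))
  expect_s3_class(fc, "hq_forecast")
  expect_true(is.finite(fc$mean_hq))
  expect_in(as.character(fc$band),
            c("negligible", "caution", "potential risk", "high risk"))
})
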