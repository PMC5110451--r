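test_that("complete data with zero prior reproduces relative frequencies exactly", {
  net <- six_node_net()
  cases <- generate_cases(fixture_spec("custom", n_rows = 400, missing_rate = 0,
                                       seed = 21, truth = net))
  fit <- em_fit(net, cases, prior_strength = 0, seed = 1)
  # count-and-divide oracle on the same table
  for (v in names(net$cpts)) {
    cp <- net$cpts[[v]]
    child_f <- factor(cases[[v]], levels = net$variables[[v]]$states)
    if (length(cp$parents) == 0L) {
      mle <- rbind(as.numeric(table(child_f)) / nrow(cases))
    } else {
      # CPT rows have the first parent varying fastest
      cfg <- do.call(interaction, c(
        lapply(cp$parents, function(p)
          factor(cases[[p]], levels = net$variables[[p]]$states)),
        list(lex.order = FALSE)))
      counts <- table(cfg, child_f)
      mle <- matrix(counts / pmax(rowSums(counts), 1), nrow = nrow(counts))
      mle[rowSums(counts) == 0, ] <- cp$prob[rowSums(counts) == 0, ]
    }
    expect_equal(fit$network$cpts[[v]]$prob, unname(mle), tolerance = 1e-12,
                 label = paste("MLE for", v))
  }
})

test_that("EM objective trace is non-decreasing on varied runs", {
  net <- six_node_net()
  for (s in 1:4) {
    cases <- generate_cases(fixture_spec(
      "custom", n_rows = 150, missing_rate = c(0, 0.2, 0.4, 0.6)[s],
      seed = 100 + s, truth = net))
    for (prior in c(0, 1)) {
      fit <- em_fit(net, cases, prior_strength = prior, seed = s, max_iter = 60)
      expect_true(all(diff(fit$loglik) >= -1e-8),
                  label = sprintf("monotone trace (seed %d, prior %g)", s, prior))
    }
  }
})

test_that("EM recovers a known 6-node network from 5,000 rows at 30% MCAR", {
  truth <- six_node_net()
  cases <- generate_cases(fixture_spec("custom", n_rows = 5000,
                                       missing_rate = 0.3, seed = 7,
                                       truth = truth))
  # start from an uninformed copy: uniform CPTs everywhere
  blank <- truth
  for (v in names(blank$cpts)) {
    pr <- blank$cpts[[v]]$prob
    blank$cpts[[v]]$prob <- matrix(1 / ncol(pr), nrow(pr), ncol(pr))
  }
  fit <- em_fit(blank, cases, prior_strength = 1, tol = 1e-5, max_iter = 100,
                seed = 3)
  for (v in names(truth$cpts)) {
    tv <- cpt_row_tv(fit$network, truth, v)
    expected_n <- 5000 * parent_config_probs(truth, v)
    well_supported <- expected_n >= 20
    expect_true(all(tv[well_supported] < 0.05),
                label = paste("TV recovery for", v))
  }
  # recovery improves with sample size (100 -> 5000 rows)
  small <- generate_cases(fixture_spec("custom", n_rows = 100,
                                       missing_rate = 0.3, seed = 7,
                                       truth = truth))
  fit_small <- em_fit(blank, small, prior_strength = 1, tol = 1e-5,
                      max_iter = 100, seed = 3)
  tv_large <- unlist(lapply(names(truth$cpts), function(v)
    cpt_row_tv(fit$network, truth, v)))
  tv_small <- unlist(lapply(names(truth$cpts), function(v)
    cpt_row_tv(fit_small$network, truth, v)))
  expect_lt(mean(tv_large), mean(tv_small))
})

test_that("empty or invalid case tables are rejected; all-missing columns warned", {
  net <- chain_net()
  expect_error(em_fit(net, data.frame(A = character())), "empty case table")
  expect_error(em_fit(net, data.frame(Q = "x")), "not a network variable")
  expect_error(em_fit(net, data.frame(A = "bogus")), "invalid state")
  tab <- data.frame(A = c("a0", "a1"), B = c(NA_character_, NA_character_))
  expect_warning(fit <- em_fit(net, tab, max_iter = 5), "all-missing")
  expect_s3_class(fit, "bn_fit")
})

test_that("tidy and glance expose the EM trace and summary", {
  net <- chain_net()
  cases <- generate_cases(fixture_spec("custom", n_rows = 60, missing_rate = 0.2,
                                       seed = 5, truth = net))
  fit <- em_fit(net, cases, seed = 2)
  td <- tidy(fit)
  expect_identical(names(td), c("iteration", "objective"))
  expect_identical(nrow(td), fit$iterations)
  gl <- glance(fit)
  expect_identical(gl$n_cases, 60L)
  expect_true(gl$converged)
})

test_that("updating with n complete cases adds exactly n experience per variable", {
  net <- chain_net()
  cases <- generate_cases(fixture_spec("custom", n_rows = 37, missing_rate = 0,
                                       seed = 9, truth = net))
  upd <- update_with_cases(net, cases)
  for (v in names(net$cpts))
    expect_equal(sum(upd$experience[[v]]), 37)
})

test_that("zero new cases leave network and experience unchanged", {
  net <- chain_net()
  upd <- update_with_cases(net, data.frame())
  expect_equal(upd$network$cpts, net$cpts)
  expect_equal(sum(unlist(upd$experience)), 0)
})

test_that("sequential complete-data batches equal one concatenated batch", {
  net <- six_node_net()
  cases <- generate_cases(fixture_spec("custom", n_rows = 240, missing_rate = 0,
                                       seed = 31, truth = net))
  u1 <- update_with_cases(net, cases[1:90, ])
  u2 <- update_with_cases(u1$network, cases[91:240, ], u1$experience)
  uc <- update_with_cases(net, cases)
  for (v in names(net$cpts)) {
    expect_lt(max(abs(u2$network$cpts[[v]]$prob - uc$network$cpts[[v]]$prob)), 1e-9)
    expect_lt(max(abs(u2$experience[[v]] - uc$experience[[v]])), 1e-9)
  }
})

test_that("new data moves a CPT row less the more experience backs it", {
  net <- chain_net()
  cases <- generate_cases(fixture_spec("custom", n_rows = 50, missing_rate = 0,
                                       seed = 13, truth = net))
  l1_change <- vapply(c(0, 1, 5, 20, 100, 1000), function(e) {
    exp_tab <- lapply(net$cpts, function(cp) rep(e, nrow(cp$prob)))
    upd <- update_with_cases(net, cases, exp_tab)
    sum(abs(upd$network$cpts$B$prob - net$cpts$B$prob))
  }, 0)
  expect_true(all(diff(l1_change) <= 1e-12))
})

test_that("negative experience is rejected", {
  net <- chain_net()
  exp_tab <- lapply(net$cpts, function(cp) rep(-1, nrow(cp$prob)))
  expect_error(update_with_cases(net, data.frame(A = "a0"), exp_tab),
               "negative experience")
})
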