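test_that("fitting inverts noiseless additive generation exactly", {
  truth <- toy_truth()
  ds <- generate_dataset(synthetic_config(truth = truth))
  fit <- fit_increments(ds)
  expect_tables_equal(fit, truth, tol = 1e-12)
  expect_identical(attr(fit, "source", exact = TRUE), NULL)
  expect_identical(fit$source, "fitted")

  # the equivalent least-squares formulation agrees on noiseless data
  fit_ls <- fit_increments(ds, method = "ls")
  expect_tables_equal(fit_ls, truth, tol = 1e-9)
})

test_that("fitting with supplied bases matches fitting with derived bases", {
  truth <- toy_truth()
  ds <- generate_dataset(synthetic_config(truth = truth))
  fit_a <- fit_increments(ds)
  fit_b <- fit_increments(ds, bases = default_bases())
  expect_tables_equal(fit_a, fit_b, tol = 1e-12)
})

test_that("degenerate datasets are handled without fabricating increments", {
  base_only <- generate_dataset(synthetic_config(proximal = "None,None",
                                                 distal = "None,None"))
  empty <- fit_increments(base_only)
  expect_length(empty$e_sub, 0)
  expect_length(empty$s_ster, 0)

  ds <- generate_dataset(synthetic_config(truth = toy_truth()))
  no3 <- ds[!(ds$proximal == "NO2,3" & ds$distal == "None,None"), ]
  no3 <- structure(no3, class = class(ds))
  expect_message(partial <- fit_increments(no3), "NO2")
  expect_identical(attr(partial, "unfit"), "NO2")
  expect_false(any(grepl("^NO2", names(partial$e_sub))))
  expect_true(all(c("Br:13", "NH2:24") %in% names(partial$e_sub)))
})

test_that("fitting on the ortho group is possible but warned about", {
  ds <- generate_dataset(synthetic_config(truth = toy_truth(),
                                          groups = c("ortho", "meta")))
  expect_warning(fit_increments(ds, groups = c("ortho", "meta")),
                 "ortho")
})

test_that("prediction applies the additive model term by term", {
  tab <- empirical_increments()
  base <- list(e_base = 10, s_base = 8)

  # unsubstituted view: the base compound itself
  p0 <- predict_bridge(tab, base, "None,None")
  expect_equal(p0$ea, 10)
  expect_equal(p0$sm, 8)

  # bridge-adjacent position: substituent + steric increments
  p1 <- predict_bridge(tab, base, "Br,1")
  expect_equal(p1$ea, 10 + (-0.670) + (-1.199), tolerance = 1e-12)
  expect_equal(p1$ea, 8.131, tolerance = 1e-9)

  # position 3 carries no steric term
  p3 <- predict_bridge(tab, base, "Br,3")
  expect_equal(p3$ea, 10 - 0.670, tolerance = 1e-12)
  expect_equal(p3$components$ea[p3$components$term == "ster"], 0)

  # the totals are exact sums of the itemised components
  expect_identical(p1$ea, sum(p1$components$ea))
  expect_identical(p1$sm, sum(p1$components$sm))
})

test_that("prediction errors name missing keys and falls back on missing distal", {
  empty <- increment_table()
  expect_error(predict_bridge(empty, list(e_base = 10, s_base = 8), "Br,1"),
               "Br:13")
  with_dist <- toy_truth(e_dist = c("Br,1" = 0.3), s_dist = c("Br,1" = 0.2))
  base <- list(e_base = 12, s_base = 10)
  p <- predict_bridge(with_dist, base, "NH2,3", "Br,1")
  expect_equal(p$components$ea[p$components$term == "dist"], 0.3)
  expect_warning(pf <- predict_bridge(with_dist, base, "NH2,3", "NO2,2"),
                 "NO2,2")
  expect_equal(pf$ea, predict_bridge(with_dist, base, "NH2,3")$ea)
})

test_that("prediction is linear in the increment table", {
  tab <- toy_truth()
  scale_by <- function(tab, c) {
    increment_table(e_sub = tab$e_sub * c, s_sub = tab$s_sub * c,
                    e_ster = tab$e_ster * c, s_ster = tab$s_ster * c)
  }
  base <- list(e_base = 12, s_base = 10)
  for (lab in c("Br,1", "NH2,2", "NO2,4", "Br,3")) {
    p1 <- predict_bridge(tab, base, lab)
    p2 <- predict_bridge(scale_by(tab, 2.5), base, lab)
    expect_equal(p2$ea - 12, 2.5 * (p1$ea - 12), tolerance = 1e-12)
    expect_equal(p2$sm - 10, 2.5 * (p1$sm - 10), tolerance = 1e-12)
  }
})

test_that("distal increments are recovered exactly from matched pairs", {
  e_dist <- c("NO2,1" = 0.3, "Br,3" = -0.2, "NH2,4" = 0.45)
  s_dist <- c("NO2,1" = 0.1, "Br,3" = -0.15, "NH2,4" = 0.05)
  truth <- toy_truth(e_dist = e_dist, s_dist = s_dist)
  ds <- generate_dataset(synthetic_config(
    truth = truth, distal = c("None,None", names(e_dist))))
  fit <- fit_increments(ds)
  fit <- estimate_distal_increments(ds, fit)
  expect_equal(fit$e_dist[names(e_dist)], e_dist, tolerance = 1e-12)
  expect_equal(fit$s_dist[names(s_dist)], s_dist, tolerance = 1e-12)

  # no distally substituted records: the maps stay empty
  mono <- generate_dataset(synthetic_config(truth = toy_truth(),
                                            distal = "None,None"))
  fit2 <- estimate_distal_increments(mono, fit_increments(mono))
  expect_length(fit2$e_dist, 0)
})

test_that("recovered distal increments inherit the generator's bound", {
  labs <- all_patterns(include_unsubstituted = FALSE)
  set.seed(11)
  e_dist <- setNames(runif(12, -0.5, 0.5), labs)
  s_dist <- setNames(runif(12, -0.5, 0.5), labs)
  truth <- toy_truth(e_dist = e_dist, s_dist = s_dist)
  ds <- generate_dataset(synthetic_config(truth = truth))
  fit <- estimate_distal_increments(ds, fit_increments(ds))
  expect_length(fit$e_dist, 12)
  expect_true(all(abs(fit$e_dist) <= 0.5 + 1e-12))
  expect_true(all(abs(fit$s_dist) <= 0.5 + 1e-12))
})

test_that("approximation error is relative percent, flagged at zero", {
  exact <- approximation_error(list(ea = 10, sm = 8), list(ea = 10, sm = 8))
  expect_equal(exact$ea_percent, 0)
  expect_equal(exact$sm_percent, 0)

  off <- approximation_error(list(ea = 10, sm = 8), list(ea = 9.8, sm = 8.4))
  expect_equal(off$ea_percent, 2, tolerance = 1e-12)
  expect_equal(off$sm_percent, 5, tolerance = 1e-12)
  expect_equal(off$ea_abs, 0.2, tolerance = 1e-12)

  expect_warning(z <- approximation_error(list(ea = 0, sm = 8),
                                          list(ea = 1, sm = 8)),
                 "zero actual")
  expect_true(is.na(z$ea_percent))
  expect_true("zero_actual_ea" %in% z$flags)
})

test_that("noisy fits are unbiased across replicates", {
  truth <- toy_truth()
  bases <- default_bases()
  n_rep <- 60
  keys <- names(truth$e_sub)
  acc <- matrix(0, n_rep, length(keys), dimnames = list(NULL, keys))
  for (r in seq_len(n_rep)) {
    ds <- generate_dataset(synthetic_config(truth = truth,
                                            distal = "None,None",
                                            noise_sd = 0.1,
                                            seed = 3000 + r))
    fit <- fit_increments(ds, bases = bases)
    acc[r, ] <- fit$e_sub[keys]
  }
  bias <- colMeans(acc) - truth$e_sub[keys]
  # mean of n_rep fits, each averaging 2 groups of sd-0.1 observations
  expect_true(all(abs(bias) < 3 * 0.1 / sqrt(2 * n_rep) + 0.01))
})
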