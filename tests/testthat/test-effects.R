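test_that("bridge matrices use the canonical grid with NA for missing cells", {
  ds <- generate_dataset(synthetic_config(truth = toy_truth()))
  m <- build_matrix(ds, "para", "ea")
  expect_identical(dim(m), c(13L, 13L))
  expect_identical(rownames(m), all_patterns())
  expect_identical(colnames(m), all_patterns())
  expect_false(anyNA(m))
  expect_equal(m["None,None", "None,None"], 12)

  small <- fake_dataset(data.frame(
    group = "meta",
    proximal = c("Br,1", "Br,1", "NO2,2", "NO2,2"),
    distal = c("None,None", "Br,3", "None,None", "Br,3"),
    ea = c(10, 10.2, 11, 11.3), sm = c(8, 8, 9, 9)))
  m2 <- build_matrix(small, "meta", "ea")
  expect_identical(dim(m2), c(2L, 2L))

  expect_error(build_matrix(ds, "para", "zeta"), "unknown parameter")

  # a record without a PT minimum yields a missing cell, not 0
  small$has_pt_minimum[2] <- FALSE
  m3 <- build_matrix(small, "meta", "ea")
  expect_true(is.na(m3["Br,1", "Br,3"]))
})

test_that("matrix cells can hold auxiliary scalars", {
  aux <- fake_dataset(data.frame(
    group = "para",
    proximal = c("Br,1", "NH2,2"), distal = c("None,None", "None,None"),
    ea = c(10, 11), sm = c(8, 9), oc4_distance = c(1.36, 1.38)))
  m <- build_matrix(aux, "para", "oc4_distance")
  expect_equal(m["NH2,2", "None,None"], 1.38)
})

test_that("effect spread summarises column-wise and row-wise sample SDs", {
  m <- matrix(c(0, 2, 1, 3), 2, 2)  # columns {0,2} and {1,3}; rows {0,1}, {2,3}
  sp <- effect_spread(m)
  expect_equal(sp$proximal_sd_mean, sqrt(2), tolerance = 1e-12)
  expect_equal(sp$distal_sd_mean, sqrt(0.5), tolerance = 1e-12)
  expect_equal(sp$proximal_sd_sd, 0)
  expect_true(all(c(sp$proximal_sd_mean, sp$distal_sd_mean) >= 0))

  # identical rows: no distal variation at all
  flat <- matrix(rep(c(1, 5, 2), each = 3), 3, 3, byrow = FALSE)
  expect_equal(effect_spread(t(flat))$distal_sd_mean, 0)

  # slices with fewer than two values are excluded with a warning
  holey <- matrix(c(1, NA, 2, 4, NA, 5), 2, 3, byrow = TRUE)
  expect_warning(sph <- effect_spread(holey), "excluded")
  expect_length(sph$proximal_sds, 2)

  expect_error(effect_spread(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("effect spread is transpose-dual", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(rnorm(35), 5, 7)
    a <- effect_spread(m)
    b <- effect_spread(t(m))
    expect_equal(a$proximal_sd_mean, b$distal_sd_mean, tolerance = 1e-12)
    expect_equal(a$proximal_sd_sd, b$distal_sd_sd, tolerance = 1e-12)
  }
})

test_that("additive grids give spreads equal to the increment-sum SDs", {
  labs <- all_patterns(include_unsubstituted = FALSE)
  set.seed(31)
  e_dist <- setNames(runif(12, -0.5, 0.5), labs)
  truth <- toy_truth(e_dist = e_dist,
                     s_dist = setNames(rep(0, 12), labs))
  ds <- generate_dataset(synthetic_config(truth = truth, groups = "para"))
  sp <- effect_spread(build_matrix(ds, "para", "ea"))

  prox_effect <- vapply(all_patterns(), function(lab) {
    p <- parse_pattern_label(lab)
    if (is.na(p$substituent)) return(0)
    v <- truth$e_sub[[paste0(p$substituent, ":",
                             if (p$position %in% c(1, 3)) "13" else "24")]]
    if (p$position %in% c(1, 4)) {
      v <- v + truth$e_ster[[paste0(p$substituent, ":", p$position)]]
    }
    v
  }, numeric(1))
  dist_effect <- c(0, unname(e_dist))
  expect_equal(sp$proximal_sd_mean, sd(prox_effect), tolerance = 1e-9)
  expect_equal(sp$distal_sd_mean, sd(dist_effect), tolerance = 1e-9)
  expect_equal(sp$proximal_sd_sd, 0, tolerance = 1e-9)
  expect_true(sp$proximal_sd_mean > sp$distal_sd_mean)
})

test_that("charge deltas difference against the unsubstituted reference", {
  base <- c(C1 = -0.020, C2 = 0.01, O = -1.2, N = -0.1, H = 0.6)
  subst <- c(C1 = -0.050, C2 = 0.02, O = -1.25, N = -0.12, H = 0.62,
             N_sub = -0.3)
  d <- charge_delta(subst, base)
  expect_equal(d$delta[["C1"]], -0.030, tolerance = 1e-12)
  expect_equal(d$substituent_only, c(N_sub = -0.3))

  # identity and antisymmetry
  expect_true(all(charge_delta(base, base)$delta == 0))
  both <- intersect(names(base), names(subst))
  expect_equal(charge_delta(subst, base)$delta[both],
               -charge_delta(base, subst)$delta[both], tolerance = 1e-12)

  expect_error(charge_delta(subst, base[names(base) != "N"]),
               "N")

  # data-frame input is accepted
  df <- data.frame(atom_label = names(base), charge = unname(base))
  expect_equal(charge_delta(df, df)$delta, setNames(rep(0, 5), names(base)))
})

test_that("distal charge sums correlate with EA as specified", {
  q <- c(0, 1, 2, 3)
  perfect <- fake_dataset(data.frame(
    group = "para", proximal = "None,None",
    distal = c("None,None", "Br,1", "Br,2", "Br,3"),
    ea = 2 * q + 5, sm = rep(1, 4), distal_charge_sum = q))
  r <- distal_charge_correlation(perfect, "para")
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 5, tolerance = 1e-12)

  # brute-force product-moment oracle on a non-degenerate 4-point set
  ea <- c(1, 2, 3, 5)
  ds <- fake_dataset(data.frame(
    group = "meta", proximal = "None,None",
    distal = c("None,None", "Br,1", "Br,2", "Br,3"),
    ea = ea, sm = rep(0.5, 4), distal_charge_sum = q))
  out <- distal_charge_correlation(ds, "meta")
  r_oracle <- sum((q - mean(q)) * (ea - mean(ea))) /
    sqrt(sum((q - mean(q))^2) * sum((ea - mean(ea))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  expect_identical(out$n, 4L)

  const <- fake_dataset(data.frame(
    group = "meta", proximal = "None,None",
    distal = c("None,None", "Br,1", "Br,2"),
    ea = c(1, 2, 3), sm = 0.5, distal_charge_sum = rep(0.3, 3)))
  expect_error(distal_charge_correlation(const, "meta"), "zero variance")
  expect_error(distal_charge_correlation(perfect[1:2, ] |> fake_dataset(),
                                         "para"),
               "at least 3")
})

test_that("bridge-matrix heatmaps render without error", {
  ds <- generate_dataset(synthetic_config(truth = toy_truth(), groups = "meta"))
  g <- plot_bridge_matrix(build_matrix(ds, "meta", "ea"))
  expect_s3_class(g, "ggplot")
  built <- ggplot2::ggplot_build(g)
  expect_identical(nrow(built$data[[1]]), 169L)
})
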