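geom <- survey_geometry(22, 350)

# Inclusion set with known probabilities, for arithmetic contracts.
manual_inclusion <- function(pi, sizes = rep(1L, length(pi))) {
  frac_low <- mean(pi > 0.1 & pi <= 0.2)
  structure(list(pi = pi, p_z = pi, p_apex = 1, mode = "perfect",
                 screening = list(min = min(pi), frac_low = frac_low,
                                  pass = all(pi > 0.1) && frac_low < 0.05),
                 data = data.frame(size = sizes)),
            class = "inclusion_set")
}

test_that("the Horvitz-Thompson estimator is exactly sum(s_i / pi_i)", {
  # covered area equals study area: no expansion
  tr <- data.frame(transect = 1, area = 12)
  est <- ht_abundance(manual_inclusion(rep(1, 5)), tr, geom, study_area = 12)
  expect_equal(est$N_c, 5)
  expect_equal(est$N, 5)

  est2 <- ht_abundance(manual_inclusion(c(0.5, 0.5), sizes = c(2L, 3L)),
                       tr, geom)
  expect_equal(est2$N_c, 2 / 0.5 + 3 / 0.5)
  expect_equal(est2$N_c, 10)

  # expansion scales by the area ratio and density is per 1000 km^2
  est3 <- ht_abundance(manual_inclusion(rep(0.25, 4)), tr, geom,
                       study_area = 36)
  expect_equal(est3$N, est3$N_c * 3)
  expect_equal(est3$density, 1000 * est3$N / 36)
})

test_that("covered area comes from per-transect areas or lengths times the
          strip width", {
  tr_len <- data.frame(transect = 1:2, length = c(30, 30))
  expect_equal(unimodalMRDS:::covered_area(tr_len, geom), 2 * 30 * 0.328)
  tr_area <- data.frame(transect = 1:2, area = c(5, 7))
  expect_equal(unimodalMRDS:::covered_area(tr_area, geom), 12)
  expect_error(unimodalMRDS:::covered_area(data.frame(transect = 1), geom),
               "area")
})

test_that("screening verdict implements the small-probability rule", {
  ok <- manual_inclusion(seq(0.25, 0.9, length.out = 50))
  expect_true(ok$screening$pass)
  low_min <- manual_inclusion(c(0.05, seq(0.3, 0.9, length.out = 49)))
  expect_false(low_min$screening$pass)
  # > 5% of probabilities in (0.1, 0.2] also fails
  many_low <- manual_inclusion(c(rep(0.15, 4), seq(0.3, 0.9,
                                                   length.out = 46)))
  expect_gt(many_low$screening$frac_low, 0.05)
  expect_false(many_low$screening$pass)
  expect_warning(ht_abundance(low_min, data.frame(transect = 1, area = 1),
                              geom), "screening FAILED")
})

test_that("pipeline inclusion probabilities are valid and consistent across
          modes", {
  fx <- fixture_fits()
  inc_pi <- inclusion_probabilities(fx$mcds, fx$mr, mode = "PI")
  inc_avg <- inclusion_probabilities(fx$mcds, fx$mr, mode = "PI_averaged")
  inc_fi <- inclusion_probabilities(fx$mcds, fx$mr, mode = "FI")
  inc_pf <- inclusion_probabilities(fx$mcds, fx$mr, mode = "perfect")
  for (inc in list(inc_pi, inc_avg, inc_fi, inc_pf)) {
    expect_true(all(inc$pi > 0 & inc$pi <= 1))
    expect_equal(inc$screening$pass,
                 all(inc$pi > 0.1) &&
                   mean(inc$pi > 0.1 & inc$pi <= 0.2) < 0.05)
  }
  # the default conditional model carries no covariates beyond distance and
  # observer, so per-record and averaged apex detection coincide
  expect_equal(inc_pi$pi, inc_avg$pi, tolerance = 1e-12)
  # apex detection <= 1 means PI estimates at least the perfect-detection N
  tr <- fx$sim$transects
  n_pi <- ht_abundance(inc_avg, tr, geom)$N
  n_pf <- ht_abundance(inc_pf, tr, geom)$N
  expect_gte(n_pi, n_pf)
})

test_that("the averaged apex detection is the inverse-inclusion weighted
          mean of per-record apex detections", {
  fx <- fixture_fits()
  p_i <- p_dot_at_apex(fx$mr, fx$mcds$mu, fx$mcds$data)
  w <- 1 / fx$mcds$p_z
  expect_equal(average_apex_detection(fx$mr, fx$mcds),
               sum(p_i * w) / sum(w))
  # a constant is its own weighted average
  expect_equal(average_apex_detection(fx$mr, fx$mcds), p_i[1],
               tolerance = 1e-12)
})

test_that("full-independence inclusion probabilities match a trapezoid
          oracle of the combined conditional curve", {
  fx <- fixture_fits()
  inc_fi <- inclusion_probabilities(fx$mcds, fx$mr, mode = "FI")
  idx <- c(1, 5, 9)
  yy <- seq(22, 350, length.out = 2001)
  for (i in idx) {
    z <- fx$mcds$data[i, ]
    p1 <- suppressWarnings(conditional_prob(fx$mr, 1L, yy, z))
    p2 <- suppressWarnings(conditional_prob(fx$mr, 2L, yy, z))
    pc <- p1 + p2 - p1 * p2
    trap <- sum((pc[-1] + pc[-length(pc)]) / 2 * diff(yy)) / 328
    expect_equal(inc_fi$pi[i], trap, tolerance = 1e-4)
  }
})

test_that("abundance is invariant to record order and transect labels", {
  fx <- fixture_fits()
  inc <- inclusion_probabilities(fx$mcds, fx$mr)
  tr <- fx$sim$transects
  base <- ht_abundance(inc, tr, geom)$N_c
  tr2 <- tr[sample(nrow(tr)), ]
  tr2$transect <- rev(tr2$transect)
  expect_equal(ht_abundance(inc, tr2, geom)$N_c, base)
  set.seed(3)
  perm <- sample(fx$mcds$n)
  mcds2 <- fit_mcds(fx$mcds$data[perm, ], geom, shared = ~ flat + cover20,
                    restarts = 0L, start = coef(fx$mcds))
  mr2 <- fit_mrcond(mcds2$data)
  inc2 <- inclusion_probabilities(mcds2, mr2)
  expect_equal(ht_abundance(inc2, tr, geom)$N_c, base, tolerance = 1e-4)
})

test_that("comparator table reports all four independence modes from
          identical inputs", {
  fx <- fixture_fits()
  tab <- comparator_estimates(fx$mcds, fx$mr, fx$sim$transects, geom)
  expect_setequal(tab$mode, c("PI_averaged", "PI", "FI", "perfect"))
  expect_true(all(tab$N_c > 0))
  ests <- attr(tab, "estimates")
  expect_s3_class(ests$PI_averaged, "abundance_estimate")
  expect_equal(tab$N[tab$mode == "perfect"], ests$perfect$N)
})

test_that("with zero parameter uncertainty the delta-method variance
          reduces to the Horvitz-Thompson component", {
  fx <- fixture_fits()
  est <- mrds_estimate(fx$sim$observations, fx$sim$transects, geom,
                       shared = ~ flat + cover20, restarts = 0L)
  est0 <- est
  est0$mcds$vcov[] <- 0
  est0$mr$vcov[] <- 0
  v0 <- analytic_variance(est0)
  expect_equal(unname(v0$estimate$var_components["parameter"]), 0,
               tolerance = 1e-6)
  s <- est$inclusion$data$size
  ht <- sum(s^2 * (1 - est$inclusion$pi) / est$inclusion$pi^2) *
    est$estimate$expansion^2
  expect_equal(v0$estimate$se, sqrt(ht), tolerance = 1e-6)

  v <- analytic_variance(est)
  expect_gt(v$estimate$se, v0$estimate$se)
  expect_true(v$estimate$ci[1] < v$estimate$N &&
                v$estimate$N < v$estimate$ci[2])
  # t-multiplier widens the log-normal interval
  vt <- analytic_variance(est, ci_method = "lognormal_t")
  expect_gt(vt$estimate$ci[2], v$estimate$ci[2])
})

test_that("the transect bootstrap is deterministic given a seed and refuses
          degenerate designs", {
  fx <- fixture_fits()
  b1 <- bootstrap_variance(fx$sim$observations, fx$sim$transects, geom,
                           shared = ~ flat + cover20, B = 3L, seed = 77)
  b2 <- bootstrap_variance(fx$sim$observations, fx$sim$transects, geom,
                           shared = ~ flat + cover20, B = 3L, seed = 77)
  expect_identical(b1$estimates, b2$estimates)
  one <- fx$sim$transects[1, , drop = FALSE]
  obs1 <- fx$sim$observations[fx$sim$observations$transect ==
                                one$transect, ]
  expect_error(bootstrap_variance(obs1, one, geom, B = 2L, seed = 1),
               "at least 2 transects")
})

test_that("bootstrap and delta-method standard errors agree on a simulated
          survey", {
  sim <- suppressWarnings(simulate_survey(sim_config(seed = 505)))
  est <- mrds_estimate(sim$observations, sim$transects, geom,
                       shared = ~ flat + cover20, restarts = 0L)
  va <- analytic_variance(est)
  vb <- bootstrap_variance(sim$observations, sim$transects, geom,
                           shared = ~ flat + cover20, B = 100L, seed = 11)
  expect_lt(abs(va$estimate$se - vb$se) / vb$se, 0.25)
})
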