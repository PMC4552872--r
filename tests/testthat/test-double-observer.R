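test_that("stacked conditional rows follow the capture-history accounting", {
  both <- data.frame(distance = runif(10, 50, 300),
                     seen_by_1 = 1L, seen_by_2 = 1L)
  r <- build_conditional_rows(both)
  expect_equal(nrow(r), 20L)            # (1,1) contributes two rows
  expect_true(all(r$response == 1L))

  only1 <- data.frame(distance = runif(5, 50, 300),
                      seen_by_1 = 1L, seen_by_2 = 0L)
  r1 <- build_conditional_rows(only1)
  expect_equal(nrow(r1), 5L)
  expect_true(all(r1$observer == "backseat"))  # observer 2 is the response
  expect_true(all(r1$response == 0L))

  set.seed(8)
  h <- data.frame(distance = runif(200, 30, 340),
                  seen_by_1 = rbinom(200, 1, 0.7),
                  seen_by_2 = rbinom(200, 1, 0.7))
  h <- h[h$seen_by_1 + h$seen_by_2 > 0, ]
  n11 <- sum(h$seen_by_1 == 1 & h$seen_by_2 == 1)
  n10 <- sum(h$seen_by_1 == 1 & h$seen_by_2 == 0)
  n01 <- sum(h$seen_by_1 == 0 & h$seen_by_2 == 1)
  expect_equal(nrow(build_conditional_rows(h)), 2L * n11 + n10 + n01)

  bad <- data.frame(distance = 100, seen_by_1 = 0L, seen_by_2 = 0L)
  expect_error(build_conditional_rows(bad), "\\(0,0\\)")
})

test_that("a null conditional model recovers a constant detection
          probability", {
  set.seed(12)
  n <- 4000
  d <- data.frame(distance = runif(n, 30, 340),
                  seen_by_1 = rbinom(n, 1, 0.8),
                  seen_by_2 = rbinom(n, 1, 0.8))
  d <- d[d$seen_by_1 + d$seen_by_2 > 0, ]
  m <- fit_mrcond(d, formula = ~ 1)
  expect_equal(unname(coef(m)), qlogis(0.8), tolerance = 0.08)
  expect_equal(m$aic, -2 * m$loglik + 2 * length(coef(m)))
})

test_that("conditional probabilities equal a hand-assembled linear predictor
          pushed through the inverse logit", {
  fx <- fixture_fits()
  m <- fx$mr
  z <- fx$mcds$data[7, ]
  y <- 140
  nd <- unimodalMRDS:::mr_newdata(m, 2L, y, z)
  X <- model.matrix(delete.response(terms(m$glm)), nd)
  manual <- plogis(drop(X %*% coef(m)))
  expect_equal(conditional_prob(m, 2L, y, z), unname(manual),
               tolerance = 1e-12)

  # all-zero coefficients give probability exactly 1/2
  m0 <- m
  m0$glm$coefficients[] <- 0
  expect_equal(conditional_prob(m0, 1L, 140, z), 0.5)

  # a negative backseat effect means the pilot detects better everywhere
  bk <- coef(m)[["observerbackseat"]]
  p_pilot <- conditional_prob(m, 1L, 140, z)
  p_back <- conditional_prob(m, 2L, 140, z)
  expect_equal(bk < 0, p_pilot > p_back)
})

test_that("out-of-range prediction distances are clamped with a warning", {
  fx <- fixture_fits()
  z <- fx$mcds$data[1, ]
  expect_warning(p <- conditional_prob(fx$mr, 1L, 1000, z), "clamped")
  expect_equal(p,
               suppressWarnings(conditional_prob(fx$mr, 1L,
                                                 fx$mr$boundary[2], z)))
})

test_that("combined apex detection obeys the at-least-one-observer
          algebra", {
  fx <- fixture_fits()
  z <- fx$mcds$data[1:20, ]
  mu <- fx$mcds$mu
  p1 <- conditional_prob(fx$mr, 1L, mu, z)
  p2 <- conditional_prob(fx$mr, 2L, mu, z)
  pd <- p_dot_at_apex(fx$mr, mu, z)
  expect_equal(pd, p1 + p2 - p1 * p2)
  expect_equal(pd, 1 - (1 - p1) * (1 - p2))
  expect_true(all(pd >= pmax(p1, p2) - 1e-12))
  expect_true(all(pd > 0 & pd < 1))
})

test_that("refitting after permuting row order reproduces the model", {
  fx <- fixture_fits()
  set.seed(2)
  perm <- sample(nrow(fx$mcds$data))
  m2 <- fit_mrcond(fx$mcds$data[perm, ])
  expect_equal(coef(m2), coef(fx$mr), tolerance = 1e-10)
  expect_equal(m2$aic, fx$mr$aic, tolerance = 1e-10)
})

test_that("the mark-recapture apex matches a brute-force grid maximum and
          flat curves are flagged", {
  fx <- fixture_fits()
  ap <- mr_apex(fx$mr)
  z <- average_covariates(fx$mcds$data[setdiff(colnames(fx$mcds$data),
                                               c("seen_by_1", "seen_by_2",
                                                 "distance"))])
  yy <- seq(fx$mr$boundary[1], fx$mr$boundary[2], length.out = 3000)
  brute <- yy[which.max(p_dot_at_apex(fx$mr, yy, z))]
  expect_false(ap$flat)
  expect_lt(abs(ap$apex - brute), 1.0)
  expect_equal(ap$value,
               p_dot_at_apex(fx$mr, ap$apex, z), tolerance = 1e-8)

  m_flat <- fit_mrcond(fx$mcds$data, formula = ~ observer)
  expect_true(mr_apex(m_flat)$flat)
})

test_that("AIC model selection returns the lowest-AIC candidate with a
          comparison table", {
  fx <- fixture_fits()
  best <- suppressWarnings(select_mrcond(fx$mcds$data,
                                         mr_candidate_formulas()))
  tab <- attr(best, "aic_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(best$aic, min(tab$aic))
})

test_that("the calibration-style goodness of fit runs and degenerate
          binning is refused", {
  fx <- fixture_fits()
  g <- mr_gof(fx$mr, n_bins = 10)
  expect_equal(g$df, nrow(g$bins) - 2L)
  expect_equal(sum(g$bins$n), nrow(fx$mr$rows))
  expect_gt(g$p_value, 0)

  m0 <- fit_mrcond(fx$mcds$data, formula = ~ 1)
  expect_error(mr_gof(m0), "constant")
})
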