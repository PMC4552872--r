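geom <- survey_geometry(22, 350)

test_that("scale values reduce to exp(beta0) with no covariate effects and
          evaluate the partitioned linear predictors", {
  sp0 <- covariate_spec()
  pa0 <- detection_params(mu = 100, beta0 = 1.7)
  s <- scale_values(pa0, data.frame(x = 0), sp0)
  expect_equal(s$sigma1, exp(1.7))
  expect_equal(s$sigma2, exp(1.7))

  # partitioned groups: shared terms enter both sides, side-only terms one
  sp <- covariate_spec(shared = c("flat", "cover20"), right = "bin_lnsd")
  pa <- detection_params(mu = 102.6, beta0 = 3.5549,
                         beta_shared = c(flat = 0.5199, cover20 = -0.0944),
                         beta_right = c(bin_lnsd = 0.4526))
  z <- data.frame(flat = 0, cover20 = 0, bin_lnsd = 0)
  s <- scale_values(pa, z, sp)
  expect_equal(s$sigma1, exp(3.5549))
  v <- 4.2
  z2 <- data.frame(flat = 1, cover20 = 2.5, bin_lnsd = v)
  s2 <- scale_values(pa, z2, sp)
  lp_shared <- 3.5549 + 0.5199 * 1 - 0.0944 * 2.5
  expect_equal(s2$sigma1, exp(lp_shared))
  expect_equal(s2$sigma2, exp(lp_shared + 0.4526 * v))
})

test_that("scale_values errors name missing covariates and reject non-finite
          predictors", {
  sp <- covariate_spec(shared = c("flat", "cover20"))
  pa <- detection_params(100, 3, beta_shared = c(flat = 1, cover20 = 1))
  expect_error(scale_values(pa, data.frame(flat = 1), sp), "cover20")
  expect_error(scale_values(pa, data.frame(flat = Inf, cover20 = 0), sp),
               "non-finite")
})

test_that("detection probability has apex 1 at mu, is symmetric when scales
          match, and matches a direct piecewise evaluation", {
  sp <- covariate_spec(left = "a", right = "b")
  pa <- detection_params(mu = 120, beta0 = log(40),
                         beta_left = c(a = 0.2), beta_right = c(b = -0.3))
  z <- data.frame(a = 1, b = 1)
  expect_equal(detection_prob(120, pa, z, sp, geom), 1.0)

  # sigma1 == sigma2 => symmetric about mu
  pa_sym <- detection_params(mu = 150, beta0 = log(50))
  sp0 <- covariate_spec()
  z0 <- data.frame(x = 0)
  d <- c(10, 40, 90)
  expect_equal(detection_prob(150 - d, pa_sym, z0, sp0, geom),
               detection_prob(150 + d, pa_sym, z0, sp0, geom))

  # grid vs an independent evaluation of the piecewise formula
  s1 <- exp(log(40) + 0.2); s2 <- exp(log(40) - 0.3)
  yy <- seq(22, 350, length.out = 97)
  oracle <- ifelse(yy < 120, exp(-((yy - 120) / (2 * s1))^2),
                   exp(-((yy - 120) / (2 * s2))^2))
  expect_equal(detection_prob(yy, pa, z, sp, geom), oracle,
               tolerance = 1e-12)
})

test_that("detection probability rejects distances outside the strip", {
  pa <- detection_params(100, log(40))
  sp <- covariate_spec()
  z <- data.frame(x = 0)
  expect_error(detection_prob(10, pa, z, sp, geom), "strip")
  expect_error(detection_prob(351, pa, z, sp, geom), "strip")
})

test_that("the key function is unimodal with a single apex for randomized
          parameters", {
  set.seed(71)
  for (i in 1:25) {
    mu <- runif(1, 30, 340)
    s1 <- exp(runif(1, 2.5, 5)); s2 <- exp(runif(1, 2.5, 5))
    pa <- detection_params(mu, log(s1), beta_right = c(r = log(s2 / s1)))
    sp <- covariate_spec(right = "r")
    z <- data.frame(r = 1)
    yy <- seq(22, 350, length.out = 400)
    g <- detection_prob(yy, pa, z, sp, geom)
    left <- yy <= mu; right <- yy >= mu
    expect_true(all(diff(g[left]) >= -1e-12))   # non-decreasing to the apex
    expect_true(all(diff(g[right]) <= 1e-12))   # non-increasing after it
    expect_true(all(g <= 1))
    expect_lt(max(g[abs(yy - mu) > 1]), 1)      # 1 attained only at the apex
    expect_equal(detection_prob(mu, pa, z, sp, geom), 1)
  }
})

test_that("closed-form strip average matches adaptive quadrature to 1e-8 on
          random parameter draws", {
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    mu <- runif(1, 30, 340)
    s1 <- exp(runif(1, 2, 5.5)); s2 <- exp(runif(1, 2, 5.5))
    pa <- detection_params(mu, log(s1), beta_right = c(r = log(s2 / s1)))
    sp <- covariate_spec(right = "r")
    cf <- strip_average_detection(pa, data.frame(r = 1), sp, geom)
    qd <- unimodalMRDS:::strip_average_quadrature(mu, s1, s2, geom)
    worst <- max(worst, abs(cf - qd))
  }
  expect_lt(worst, 1e-8)
})

test_that("symmetric-midpoint strip average collapses to the single-erf
          closed form", {
  w_b <- 22; w <- 350
  mu <- (w_b + w) / 2
  sigma <- 60
  pa <- detection_params(mu, log(sigma))
  got <- strip_average_detection(pa, data.frame(x = 0), covariate_spec(),
                                 geom)
  erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1
  expect_equal(got, 2 * sigma * sqrt(pi) * erf((w - w_b) / (4 * sigma)) /
                 (w - w_b))
})

test_that("strip average is monotone in each scale and approaches its
          limits", {
  sp <- covariate_spec()
  z <- data.frame(x = 0)
  pav <- function(s1, s2) {
    pa <- detection_params(100, log(s1),
                           beta_right = c(r = log(s2 / s1)))
    strip_average_detection(pa, data.frame(r = 1),
                            covariate_spec(right = "r"), geom)
  }
  s1s <- c(10, 30, 90, 270)
  expect_true(all(diff(vapply(s1s, pav, numeric(1), s2 = 50)) > 0))
  expect_true(all(diff(vapply(s1s, function(s) pav(50, s), numeric(1))) > 0))
  expect_gt(pav(1e7, 1e7), 1 - 1e-6)   # sigma -> Inf: detection -> 1
  expect_lt(pav(1e-3, 1e-3), 1e-4)     # sigma -> 0: detection -> 0
})

test_that("random two-piece draws follow the key density (quantile check)", {
  set.seed(9)
  mu <- 110; s1 <- 40; s2 <- 70
  y <- unimodalMRDS:::rtpn(20000, mu, s1, s2, 22, 350)
  expect_true(all(y >= 22 & y <= 350))
  # empirical CDF at probe points vs normalized closed-form integral
  tot <- unimodalMRDS:::tpn_integral(22, 350, mu, s1, s2)
  for (q in c(60, 110, 200, 300)) {
    expect_equal(mean(y <= q),
                 unimodalMRDS:::tpn_integral(22, q, mu, s1, s2) / tot,
                 tolerance = 0.015)
  }
})
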