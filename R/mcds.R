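# Multiple-covariate distance sampling (MCDS) fit with the two-piece normal
# key. The conditional distance log-likelihood for observation i is
#   ln g(y_i, z_i) + ln pi(y) - ln p(z_i),
# and since p(z_i) = (1/width) * int g(y, z_i) dy the width terms cancel:
#   l = sum_i ln g(y_i, z_i) - sum_i ln int_{w_b}^{w} g(y, z_i) dy.
# mu is optimized on the ln scale so the apex stays positive and its printed
# coefficient is ln(mu).

# Resolve a one-sided formula / character vector / NULL into a design matrix
# (no intercept column; the log-scale intercept beta0 is a separate term).
mcds_design <- function(spec, data, what) {
  if (is.null(spec)) return(matrix(0, nrow(data), 0L))
  if (is.character(spec)) {
    if (length(spec) == 0L) return(matrix(0, nrow(data), 0L))
    spec <- stats::reformulate(spec)
  }
  if (!inherits(spec, "formula"))
    stop("'", what, "' must be NULL, a one-sided formula or character vector",
         call. = FALSE)
  mf <- stats::model.frame(spec, data, na.action = stats::na.fail)
  X <- stats::model.matrix(spec, mf)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

# Pack/unpack: theta = c(ln(mu), beta0, beta_shared, beta_left, beta_right)
mcds_nll_factory <- function(y, Xs, Xl, Xr, geom) {
  k1 <- ncol(Xs); k2 <- ncol(Xl); k3 <- ncol(Xr)
  w_b <- geom$w_b; w <- geom$w
  is_left <- NULL  # depends on mu, computed per evaluation
  function(theta) {
    mu <- exp(theta[1L])
    if (!is.finite(mu) || mu <= w_b || mu >= w) return(1e10)
    b0 <- theta[2L]
    lp_shared <- b0 + if (k1) drop(Xs %*% theta[3:(2 + k1)]) else 0
    lp1 <- lp_shared + if (k2) drop(Xl %*% theta[(3 + k1):(2 + k1 + k2)]) else 0
    lp2 <- lp_shared + if (k3) drop(Xr %*% theta[(3 + k1 + k2):(2 + k1 + k2 + k3)]) else 0
    s1 <- exp(lp1); s2 <- exp(lp2)
    if (any(!is.finite(s1)) || any(!is.finite(s2))) return(1e10)
    s <- ifelse(y < mu, s1, s2)
    log_g <- -((y - mu) / (2 * s))^2
    tot <- tpn_integral(w_b, w, mu, s1, s2)
    if (any(tot <= 0) || any(!is.finite(tot))) return(1e10)
    nll <- -(sum(log_g) - sum(log(tot)))
    if (!is.finite(nll)) return(1e10)
    nll
  }
}

#' Starting values for a two-piece normal MCDS fit
#'
#' The apex start is the mode of a Gaussian kernel density estimate of the
#' observed distances; the log-scale intercept starts at the log of the
#' sample standard deviation of the distances; covariate coefficients start
#' from a log-linear regression of the per-observation scale proxy
#' `ln(|y - mu0| + 1)` on the design columns (zeros if that regression is
#' degenerate).
#'
#' @param y Numeric vector of observed distances within the strip.
#' @param Xs,Xl,Xr Design matrices for the shared, left-only and right-only
#'   covariate groups (may have zero columns).
#' @param geom A [survey_geometry()].
#' @return Numeric starting vector `c(ln(mu), beta0, beta_shared, beta_left,
#'   beta_right)`.
#' @keywords internal
mcds_start <- function(y, Xs, Xl, Xr, geom) {
  d <- stats::density(y, bw = "nrd0", from = geom$w_b, to = geom$w)
  mu0 <- d$x[which.max(d$y)]
  mu0 <- min(max(mu0, geom$w_b + 0.05 * geom$width),
             geom$w - 0.05 * geom$width)
  b0 <- log(stats::sd(y))
  k1 <- ncol(Xs); k2 <- ncol(Xl); k3 <- ncol(Xr)
  beta <- numeric(k1 + k2 + k3)
  if (k1 + k2 + k3 > 0) {
    X <- cbind(Xs, Xl * (y < mu0), Xr * (y >= mu0))
    proxy <- log(abs(y - mu0) + 1)
    fit <- tryCatch(stats::lm.fit(cbind(1, X), proxy), error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- fit$coefficients[-1L]
      cf[!is.finite(cf)] <- 0
      beta <- cf
    }
  }
  c(log(mu0), b0, beta)
}

#' Fit a two-piece normal multiple-covariate distance sampling model
#'
#' Maximizes the conditional distance likelihood of perpendicular detection
#' distances under the unimodal two-piece normal key function, with
#' covariates acting log-linearly on the two scale parameters. Distances
#' outside `[w_b, w]` are truncated before fitting.
#'
#' @param data A data frame of detections, one row per detected group,
#'   containing the distance column and all covariates named in the scale
#'   model formulas.
#' @param geom A [survey_geometry()] giving the blind-strip and right
#'   truncation distances.
#' @param shared,left,right Scale-model terms: one-sided formulas (or
#'   character vectors of column names; `NULL` for none). `shared` terms act
#'   on both scales, `left` only on the inner (`y < mu`) scale, `right` only
#'   on the outer (`y >= mu`) scale.
#' @param distance Name of the distance column (metres). Default
#'   `"distance"`.
#' @param start Optional starting vector `c(ln(mu), beta0, ...)`; computed
#'   from the data when `NULL`.
#' @param restarts Number of additional optimizations from apex-jittered
#'   starts (`mu` multiplied by up to +/-20%); the best optimum is kept.
#' @param min_n_per_param Fit is refused when there are fewer than
#'   `min_n_per_param` observations per free parameter.
#' @return An object of class `"mcds"` with components `coefficients`, `mu`,
#'   `loglik`, `aic`, `vcov`, `converged`, `n`, `n_params`, per-observation
#'   fitted scales `sigma1`, `sigma2` and strip-averaged detection `p_z`.
#' @seealso [mcds_gof_chisq()], [mcds_ks()], [mcds_qq()], [fit_mrcond()]
#' @examples
#' geom <- survey_geometry(22, 350)
#' sim <- simulate_survey(sim_config(seed = 1))
#' fit <- fit_mcds(truncate_strip(sim$observations, geom), geom,
#'                 shared = ~ flat + cover20)
#' summary(fit)
#' @export
fit_mcds <- function(data, geom, shared = NULL, left = NULL, right = NULL,
                     distance = "distance", start = NULL, restarts = 2L,
                     min_n_per_param = 10) {
  stopifnot(inherits(geom, "survey_geometry"), is.data.frame(data))
  if (!distance %in% colnames(data))
    stop("distance column '", distance, "' not found", call. = FALSE)
  keep <- data[[distance]] >= geom$w_b & data[[distance]] <= geom$w
  n_total <- nrow(data)
  data <- data[keep, , drop = FALSE]
  y <- data[[distance]]
  n <- length(y)
  if (n == 0L) stop("no observations inside the strip", call. = FALSE)

  Xs <- mcds_design(shared, data, "shared")
  Xl <- mcds_design(left, data, "left")
  Xr <- mcds_design(right, data, "right")
  n_params <- 2L + ncol(Xs) + ncol(Xl) + ncol(Xr)
  if (n < min_n_per_param * n_params)
    stop("only ", n, " observations for ", n_params,
         " parameters; need at least ", min_n_per_param, " per parameter",
         call. = FALSE)

  nll <- mcds_nll_factory(y, Xs, Xl, Xr, geom)
  if (is.null(start)) start <- mcds_start(y, Xs, Xl, Xr, geom)
  if (length(start) != n_params)
    stop("'start' must have length ", n_params, call. = FALSE)

  run_one <- function(st) {
    o <- tryCatch(stats::optim(st, nll, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e9)
      o <- tryCatch(stats::optim(st, nll, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    o
  }
  best <- run_one(start)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      st <- start
      st[1L] <- st[1L] + log(1 + stats::runif(1, -0.2, 0.2))
      o <- run_one(st)
      if (!is.null(o) && (is.null(best) || o$value < best$value - 1e-8)) best <- o
    }
  }
  if (is.null(best)) stop("MCDS optimization failed from all starts", call. = FALSE)
  theta <- best$par
  converged <- best$convergence == 0 && best$value < 1e9

  H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc) || any(!is.finite(vc))) {
    vc <- matrix(NA_real_, n_params, n_params)
  }

  nm <- c("ln(mu)", "(Intercept)",
          colnames(Xs),
          if (ncol(Xl)) paste0("I(y<mu):", colnames(Xl)),
          if (ncol(Xr)) paste0("I(y>mu):", colnames(Xr)))
  names(theta) <- nm
  dimnames(vc) <- list(nm, nm)

  mu <- exp(theta[[1L]])
  k1 <- ncol(Xs); k2 <- ncol(Xl); k3 <- ncol(Xr)
  b_s <- theta[seq_len(k1) + 2L]
  b_l <- if (k2) theta[2L + k1 + seq_len(k2)] else numeric()
  b_r <- if (k3) theta[2L + k1 + k2 + seq_len(k3)] else numeric()
  lp_shared <- theta[[2L]] + if (k1) drop(Xs %*% b_s) else 0
  s1 <- exp(lp_shared + if (k2) drop(Xl %*% b_l) else 0)
  s2 <- exp(lp_shared + if (k3) drop(Xr %*% b_r) else 0)
  p_z <- tpn_integral(geom$w_b, geom$w, mu, s1, s2) / geom$width

  loglik <- -best$value
  structure(list(
    coefficients = theta, mu = mu, loglik = loglik,
    aic = -2 * loglik + 2 * n_params,
    vcov = vc, converged = converged, n = n, n_total = n_total,
    n_params = n_params,
    sigma1 = s1, sigma2 = s2, p_z = p_z,
    data = data, distance = distance, geom = geom,
    formulas = list(shared = shared, left = left, right = right),
    design_names = list(shared = colnames(Xs), left = colnames(Xl),
                        right = colnames(Xr)),
    call = match.call()
  ), class = "mcds")
}

#' Truncate observations to the observed strip
#'
#' Drops rows whose distance falls outside `[w_b, w]`. [fit_mcds()] truncates
#' internally; this helper makes the analysis set explicit (e.g. to count
#' trimmed detections).
#'
#' @param data Data frame with a distance column.
#' @param geom A [survey_geometry()].
#' @param distance Name of the distance column.
#' @return The truncated data frame.
#' @export
truncate_strip <- function(data, geom, distance = "distance") {
  stopifnot(inherits(geom, "survey_geometry"))
  data[data[[distance]] >= geom$w_b & data[[distance]] <= geom$w, ,
       drop = FALSE]
}

#' Negative conditional distance log-likelihood
#'
#' Direct evaluation of the negative MCDS log-likelihood for a given
#' parameter set, covariate specification and dataset; exposed so the
#' likelihood can be checked term by term against independent evaluation.
#'
#' @param params A [detection_params()] object.
#' @param data Data frame of truncated observations.
#' @param spec A [covariate_spec()].
#' @param geom A [survey_geometry()].
#' @param distance Name of the distance column.
#' @return A single number, `-sum_i [ln g(y_i,z_i) + ln pi(y) - ln p(z_i)]`.
#'   Underflow of any `p(z_i)` yields `+Inf` rather than an error.
#' @export
mcds_negloglik <- function(params, data, spec, geom, distance = "distance") {
  y <- data[[distance]]
  if (any(y < geom$w_b | y > geom$w))
    stop("data must be truncated to the strip before evaluation", call. = FALSE)
  s <- scale_values(params, data, spec)
  g <- tpn_key(y, params$mu, s$sigma1, s$sigma2)
  p_z <- tpn_integral(geom$w_b, geom$w, params$mu, s$sigma1, s$sigma2) /
    geom$width
  if (any(p_z <= 0)) return(Inf)
  ll <- sum(log(g)) + length(y) * log(pi_y(geom)) - sum(log(p_z))
  if (!is.finite(ll)) return(Inf)
  -ll
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.mcds <- function(x, digits = 4, ...) {
  cat("Two-piece normal MCDS fit\n")
  cat(sprintf("  n = %d detections in [%g, %g] m (%d truncated)\n",
              x$n, x$geom$w_b, x$geom$w, x$n_total - x$n))
  cat(sprintf("  apex mu = %.*f m, logLik = %.*f, AIC = %.*f%s\n",
              digits, x$mu, digits, x$loglik, digits, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.mcds <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se)
  mu_se <- se[1L] * object$mu  # delta method from ln(mu)
  out <- list(coefficients = tab, mu = object$mu, mu_se = mu_se,
              loglik = object$loglik, aic = object$aic, n = object$n,
              converged = object$converged)
  class(out) <- "summary.mcds"
  out
}

#' @export
print.summary.mcds <- function(x, digits = 4, ...) {
  cat("Two-piece normal MCDS fit\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\napex mu = %.2f m (se %.3f); logLik %.2f; AIC %.2f; n = %d%s\n",
              x$mu, x$mu_se, x$loglik, x$aic, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.mcds <- function(object, ...) object$coefficients

#' @export
vcov.mcds <- function(object, ...) object$vcov

#' @export
logLik.mcds <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

# Per-observation fitted scales for arbitrary data, using stored formulas.
mcds_scales <- function(object, newdata) {
  Xs <- mcds_design(object$formulas$shared, newdata, "shared")
  Xl <- mcds_design(object$formulas$left, newdata, "left")
  Xr <- mcds_design(object$formulas$right, newdata, "right")
  th <- object$coefficients
  k1 <- ncol(Xs); k2 <- ncol(Xl); k3 <- ncol(Xr)
  lp <- th[[2L]] + if (k1) drop(Xs %*% th[seq_len(k1) + 2L]) else 0
  list(sigma1 = exp(lp + if (k2) drop(Xl %*% th[2L + k1 + seq_len(k2)]) else 0),
       sigma2 = exp(lp + if (k3) drop(Xr %*% th[2L + k1 + k2 + seq_len(k3)]) else 0))
}

#' Predict from a two-piece normal MCDS fit
#'
#' @param object An `"mcds"` fit.
#' @param newdata Data frame of covariates (defaults to the fitting data).
#' @param y Distances at which to evaluate the detection function (for
#'   `type = "detection"`); defaults to the observed distances.
#' @param type `"detection"` for the key function value `g(y, z)`,
#'   `"strip_average"` for `p(z) = int g(y, z) pi(y) dy`.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.mcds <- function(object, newdata = NULL,
                         y = NULL, type = c("detection", "strip_average"),
                         ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  s <- mcds_scales(object, newdata)
  geom <- object$geom
  if (type == "strip_average")
    return(tpn_integral(geom$w_b, geom$w, object$mu, s$sigma1, s$sigma2) /
             geom$width)
  if (is.null(y)) y <- newdata[[object$distance]]
  tpn_key(y, object$mu, s$sigma1, s$sigma2)
}

#' Simulate detection distances from a fitted MCDS model
#'
#' Draws new distances for the fitting data's covariate rows from the fitted
#' two-piece normal truncated to the strip (parametric-bootstrap style).
#'
#' @param object An `"mcds"` fit.
#' @param nsim Number of replicate distance vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames: the fitting data with the distance
#'   column replaced by simulated distances.
#' @export
simulate.mcds <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  geom <- object$geom
  lapply(seq_len(nsim), function(i) {
    d <- object$data
    d[[object$distance]] <- rtpn(object$n, object$mu, object$sigma1,
                                 object$sigma2, geom$w_b, geom$w)
    d
  })
}

#' Plot a two-piece normal MCDS fit
#'
#' Histogram of observed distances (density scale) overlaid with the fitted
#' average detection curve scaled to the strip density.
#'
#' @param x An `"mcds"` fit.
#' @param n_bins Number of histogram bins.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the data frame of curve coordinates.
#' @export
plot.mcds <- function(x, n_bins = 15, ...) {
  geom <- x$geom
  y <- x$data[[x$distance]]
  br <- seq(geom$w_b, geom$w, length.out = n_bins + 1)
  h <- graphics::hist(y, breaks = br, freq = FALSE,
                      xlab = "Perpendicular distance (m)",
                      main = "Two-piece normal MCDS fit", ...)
  yy <- seq(geom$w_b, geom$w, length.out = 301)
  gbar <- vapply(yy, function(yi) mean(tpn_key(yi, x$mu, x$sigma1, x$sigma2)),
                 numeric(1))
  # scale so that the curve integrates like the fitted pdf of observed y
  pdf_y <- gbar / (mean(x$p_z) * geom$width)
  graphics::lines(yy, pdf_y, lwd = 2)
  graphics::abline(v = x$mu, lty = 2)
  invisible(data.frame(y = yy, density = pdf_y))
}
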