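# Goodness-of-fit diagnostics for the MCDS fit: binned chi-square, a
# Kolmogorov-Smirnov test on the fitted-CDF transform, and q-q plot data.

# Per-observation fitted conditional CDF at distances y (vectorized):
# u_i = int_{w_b}^{y_i} g(y, z_i) pi(y) dy / p(z_i). `data` defaults to the
# fitting data; supplying fresh data evaluates the fitted model there.
mcds_cdf <- function(object, y = NULL, data = NULL) {
  geom <- object$geom
  if (is.null(data)) {
    s1 <- object$sigma1; s2 <- object$sigma2
    if (is.null(y)) y <- object$data[[object$distance]]
  } else {
    sc <- mcds_scales(object, data)
    s1 <- sc$sigma1; s2 <- sc$sigma2
    if (is.null(y)) y <- data[[object$distance]]
  }
  num <- tpn_integral(geom$w_b, y, object$mu, s1, s2)
  tot <- tpn_integral(geom$w_b, geom$w, object$mu, s1, s2)
  num / tot
}

#' Binned chi-square goodness of fit for an MCDS fit
#'
#' Distances are binned into `n_bins` equal-width intervals on the strip;
#' the expected count in each bin sums each observation's fitted conditional
#' probability of falling there. Tail bins are pooled (and noted) until all
#' expected counts are at least `min_expected`. Degrees of freedom are
#' `bins - 1 - n_params`.
#'
#' @param object An `"mcds"` fit.
#' @param n_bins Number of equal-width bins before any pooling.
#' @param min_expected Minimum expected count per bin; tail bins are pooled
#'   to reach it.
#' @param data Optional data frame to evaluate the fitted model on
#'   (default: the fitting data).
#' @param n_params Parameter count subtracted from the degrees of freedom;
#'   defaults to the fit's. Set to 0 when the model was specified
#'   independently of `data` (e.g. calibration against a known generating
#'   model), where the classical `bins - 1` df applies.
#' @return An object of class `"gof_result"`: list with `statistic`, `df`,
#'   `p_value`, a `bins` data frame (`lower`, `upper`, `observed`,
#'   `expected`) and `pooled` (number of pooling merges applied).
#' @export
mcds_gof_chisq <- function(object, n_bins = 15, min_expected = 1,
                           data = NULL, n_params = object$n_params) {
  stopifnot(inherits(object, "mcds"))
  geom <- object$geom
  if (is.null(data)) {
    y <- object$data[[object$distance]]
    s1 <- object$sigma1; s2 <- object$sigma2
  } else {
    y <- data[[object$distance]]
    sc <- mcds_scales(object, data)
    s1 <- sc$sigma1; s2 <- sc$sigma2
  }
  br <- seq(geom$w_b, geom$w, length.out = n_bins + 1)
  obs <- as.vector(table(cut(y, br, include.lowest = TRUE)))
  tot <- tpn_integral(geom$w_b, geom$w, object$mu, s1, s2)
  expd <- vapply(seq_len(n_bins), function(j) {
    sum(tpn_integral(br[j], br[j + 1], object$mu, s1, s2) / tot)
  }, numeric(1))
  lower <- br[-length(br)]; upper <- br[-1L]

  pooled <- 0L
  pool_once <- function(i, j) {
    # merge bin i into bin j (adjacent)
    obs[j] <<- obs[j] + obs[i]; expd[j] <<- expd[j] + expd[i]
    lower[j] <<- min(lower[i], lower[j]); upper[j] <<- max(upper[i], upper[j])
    obs <<- obs[-i]; expd <<- expd[-i]
    lower <<- lower[-i]; upper <<- upper[-i]
    pooled <<- pooled + 1L
  }
  repeat {
    k <- length(expd)
    if (k <= 2L || all(expd >= min_expected)) break
    if (expd[1L] < min_expected) { pool_once(1L, 2L); next }
    if (expd[k] < min_expected) { pool_once(k, k - 1L); next }
    i <- which.min(expd)   # interior shortfall: merge into smaller neighbour
    j <- if (i == 1L) 2L else if (i == k) k - 1L else
      if (expd[i - 1L] <= expd[i + 1L]) i - 1L else i + 1L
    pool_once(i, j)
  }

  df <- length(expd) - 1L - n_params
  if (df < 1L)
    stop("chi-square df = ", df,
         " < 1; use more bins or a model with fewer parameters",
         call. = FALSE)
  statistic <- sum((obs - expd)^2 / expd)
  structure(list(
    statistic = statistic, df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    bins = data.frame(lower = lower, upper = upper, observed = obs,
                      expected = expd),
    pooled = pooled
  ), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: statistic = %.3f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p_value))
  if (x$pooled > 0)
    cat(sprintf("  (%d bin-pooling merge%s applied)\n", x$pooled,
                if (x$pooled > 1) "s" else ""))
  invisible(x)
}

#' Kolmogorov-Smirnov test of an MCDS fit
#'
#' Each observation is transformed to its fitted conditional CDF value
#' `u_i in (0, 1)`; under a correct model the `u_i` are uniform, and a
#' one-sample KS test against Uniform(0,1) is applied.
#'
#' @param object An `"mcds"` fit.
#' @param data Optional data frame to evaluate the fitted model on
#'   (default: the fitting data).
#' @return List with `D` (the KS statistic), `p_value`, and the vector `u`
#'   of CDF transforms.
#' @export
mcds_ks <- function(object, data = NULL) {
  stopifnot(inherits(object, "mcds"))
  u <- mcds_cdf(object, data = data)
  kt <- suppressWarnings(stats::ks.test(u, "punif"))
  list(D = unname(kt$statistic), p_value = kt$p.value, u = u)
}

#' Q-q plot data for an MCDS fit
#'
#' @param object An `"mcds"` fit.
#' @param data Optional data frame to evaluate the fitted model on
#'   (default: the fitting data).
#' @return Data frame with `empirical` quantiles `(i - 0.5)/n` and sorted
#'   `fitted` conditional-CDF transforms; points near the identity line
#'   indicate good fit.
#' @export
mcds_qq <- function(object, data = NULL) {
  stopifnot(inherits(object, "mcds"))
  u <- sort(mcds_cdf(object, data = data))
  n <- length(u)
  data.frame(empirical = (seq_len(n) - 0.5) / n, fitted = u)
}
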