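# Variance for the MRDS abundance estimate: delta-method propagation of the
# two fitted parameter vectors plus the Horvitz-Thompson conditional
# component, and a transect-based nonparametric bootstrap of the whole
# pipeline.

# Recompute the study-area abundance for perturbed parameter vectors.
# theta stacks (MCDS coefficients, MR coefficients).
nhat_at_theta <- function(theta, mcds, mr, transects, geom, study_area,
                          size_col, mode) {
  k <- length(mcds$coefficients)
  m2 <- mcds
  m2$coefficients[] <- theta[seq_len(k)]
  m2$mu <- exp(theta[1L])
  sc <- mcds_scales(m2, m2$data)
  m2$sigma1 <- sc$sigma1; m2$sigma2 <- sc$sigma2
  m2$p_z <- tpn_integral(geom$w_b, geom$w, m2$mu, sc$sigma1, sc$sigma2) /
    geom$width
  mr2 <- mr
  mr2$coefficients[] <- theta[-seq_len(k)]
  mr2$glm$coefficients[] <- theta[-seq_len(k)]
  inc <- inclusion_probabilities(m2, mr2, mode = mode)
  est <- suppressWarnings(ht_abundance(inc, transects, geom,
                                       study_area = study_area,
                                       size_col = size_col))
  est$N
}

#' Delta-method variance for the MRDS abundance estimate
#'
#' Propagates the estimated parameter covariance of the MCDS and
#' mark-recapture fits through the abundance functional by numerical
#' differencing (block-diagonal parameter covariance; the two likelihoods
#' are maximized separately), and adds the Horvitz-Thompson conditional
#' component `sum s_i^2 (1 - pi_i)/pi_i^2` (scaled by the area expansion).
#' The confidence interval is multiplicative log-normal, with a z or t
#' multiplier.
#'
#' @param est An `"mrds_est"` pipeline fit.
#' @param level Confidence level.
#' @param ci_method `"lognormal_z"` (normal multiplier) or `"lognormal_t"`
#'   (t multiplier on `n_transects - 1` degrees of freedom).
#' @param size_col Group-size column name.
#' @return The `"mrds_est"` with `estimate$se`, `estimate$cv` and
#'   `estimate$ci` filled in; component breakdown in
#'   `estimate$var_components`.
#' @export
analytic_variance <- function(est, level = 0.95,
                              ci_method = c("lognormal_z", "lognormal_t"),
                              size_col = "size") {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(est, "mrds_est"))
  mcds <- est$mcds; mr <- est$mr
  if (any(!is.finite(mcds$vcov)))
    stop("MCDS parameter covariance is unavailable; use the bootstrap",
         call. = FALSE)
  theta <- c(mcds$coefficients, mr$coefficients)
  k <- length(theta)
  f <- function(th) nhat_at_theta(th, mcds, mr, est$transects, est$geom,
                                  est$estimate$study_area, size_col,
                                  est$inclusion$mode)
  grad <- numeric(k)
  for (j in seq_len(k)) {
    h <- max(1e-5, 1e-4 * abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    grad[j] <- (f(up) - f(dn)) / (2 * h)
  }
  V <- matrix(0, k, k)
  k1 <- length(mcds$coefficients)
  V[seq_len(k1), seq_len(k1)] <- mcds$vcov
  V[(k1 + 1):k, (k1 + 1):k] <- mr$vcov
  var_param <- drop(t(grad) %*% V %*% grad)
  if (var_param < 0) var_param <- 0  # numerical round-off guard

  s <- if (size_col %in% colnames(est$inclusion$data))
    est$inclusion$data[[size_col]] else rep(1, length(est$inclusion$pi))
  pi_i <- est$inclusion$pi
  var_ht <- sum(s^2 * (1 - pi_i) / pi_i^2) * est$estimate$expansion^2

  se <- sqrt(var_param + var_ht)
  N <- est$estimate$N
  cv <- se / N
  mult <- if (ci_method == "lognormal_z")
    stats::qnorm(1 - (1 - level) / 2)
  else
    stats::qt(1 - (1 - level) / 2, df = max(1L, nrow(est$transects) - 1L))
  C <- exp(mult * sqrt(log(1 + cv^2)))
  est$estimate$se <- se
  est$estimate$cv <- cv
  est$estimate$ci <- c(N / C, N * C)
  est$estimate$var_components <- c(parameter = var_param,
                                   horvitz_thompson = var_ht)
  est
}

#' Transect bootstrap for the MRDS abundance estimate
#'
#' Resamples transects with replacement, carries each sampled transect's
#' observations along, refits the full pipeline (MCDS + mark-recapture +
#' Horvitz-Thompson) per replicate, and summarizes the replicate abundance
#' estimates. Replicates whose fits fail are dropped (with a count reported);
#' more than 10% failures is an error.
#'
#' @param obs,transects,geom,shared,left,right,mr_formula,mode,study_area,size_col
#'   As in [mrds_estimate()]. Observations are matched to transects by the
#'   `transect` column.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed (required: replicates are deterministic given
#'   the seed).
#' @param level Confidence level for the percentile interval.
#' @return List with `se`, `ci` (percentile), `estimates` (replicate values,
#'   `NA` for failures removed), `B`, `n_fail`.
#' @export
bootstrap_variance <- function(obs, transects, geom, shared = NULL,
                               left = NULL, right = NULL,
                               mr_formula = ~ observer + bs(distance, degree = 4),
                               mode = "PI_averaged", study_area = NULL,
                               size_col = "size", B = 200L, seed,
                               level = 0.95) {
  stopifnot(is.data.frame(obs), is.data.frame(transects))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!"transect" %in% colnames(obs) || !"transect" %in% colnames(transects))
    stop("both tables need a 'transect' column for the bootstrap",
         call. = FALSE)
  ids <- transects$transect
  with_obs <- unique(obs$transect)
  if (length(ids) < 2L || sum(ids %in% with_obs) < 2L)
    stop("need at least 2 transects (with observations) to bootstrap",
         call. = FALSE)
  set.seed(seed)
  obs_by_tr <- split(obs, factor(obs$transect, levels = ids))
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample(length(ids), replace = TRUE)
    tr_b <- transects[pick, , drop = FALSE]
    tr_b$transect <- seq_along(pick)
    ob_list <- obs_by_tr[pick]
    keep <- vapply(ob_list, nrow, integer(1)) > 0
    ob_b <- do.call(rbind, ob_list[keep])
    if (is.null(ob_b) || nrow(ob_b) == 0L) next
    ob_b$transect <- rep(seq_along(pick)[keep],
                         vapply(ob_list[keep], nrow, integer(1)))
    vals[b] <- tryCatch({
      e <- mrds_estimate(ob_b, tr_b, geom, shared = shared, left = left,
                         right = right, mr_formula = mr_formula,
                         mode = mode, study_area = study_area,
                         size_col = size_col, restarts = 0L)
      if (!e$mcds$converged) NA_real_ else e$estimate$N
    }, error = function(e) NA_real_, warning = function(w) {
      # screening warnings are fine in replicates; recompute quietly
      tryCatch({
        e <- suppressWarnings(
          mrds_estimate(ob_b, tr_b, geom, shared = shared, left = left,
                        right = right, mr_formula = mr_formula, mode = mode,
                        study_area = study_area, size_col = size_col,
                        restarts = 0L))
        if (!e$mcds$converged) NA_real_ else e$estimate$N
      }, error = function(e) NA_real_)
    })
  }
  n_fail <- sum(is.na(vals))
  if (n_fail > 0.1 * B)
    stop(n_fail, " of ", B, " bootstrap replicates failed (> 10%)",
         call. = FALSE)
  ok <- vals[!is.na(vals)]
  alpha <- (1 - level) / 2
  list(se = stats::sd(ok),
       ci = unname(stats::quantile(ok, c(alpha, 1 - alpha))),
       estimates = vals, B = B, n_fail = n_fail)
}
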