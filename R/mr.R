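# Conditional (Huggins-type) double-observer detection model. Each detected
# group carries a capture history over the two observers; conditioning on one
# observer's detection gives a binary outcome for the other, and a logistic
# model of those outcomes estimates p_{1|2}(y, z) and p_{2|1}(y, z). Under
# point independence these conditionals equal the unconditional detection
# probabilities at the apex only, which is all the abundance estimator uses.

#' Stack capture histories into conditional binary-response rows
#'
#' Every detection by observer j contributes one row whose response is
#' whether the *other* observer also detected the group; `(1,1)` histories
#' contribute two rows, `(1,0)` and `(0,1)` one each. The `observer` column
#' of a row names the observer whose (potential) detection is the response.
#'
#' @param data Data frame with logical/0-1 columns `seen_by_1` (pilot) and
#'   `seen_by_2` (backseat) plus distance and covariates.
#' @return Data frame of stacked rows: `response` (0/1), `observer` (factor
#'   `"pilot"`/`"backseat"`), `.record` (originating row index) and all other
#'   columns of `data`.
#' @export
build_conditional_rows <- function(data) {
  stopifnot(is.data.frame(data))
  for (cl in c("seen_by_1", "seen_by_2"))
    if (!cl %in% colnames(data))
      stop("column '", cl, "' required for capture histories", call. = FALSE)
  s1 <- as.integer(data$seen_by_1); s2 <- as.integer(data$seen_by_2)
  if (any(is.na(s1) | is.na(s2) | !(s1 %in% 0:1) | !(s2 %in% 0:1)))
    stop("'seen_by_1'/'seen_by_2' must be 0/1 with no missing values",
         call. = FALSE)
  bad <- which(s1 == 0 & s2 == 0)
  if (length(bad))
    stop("capture history (0,0) is unobservable; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  # rows where observer 1's detection is the response: condition on observer 2
  idx1 <- which(s2 == 1)
  # rows where observer 2's detection is the response: condition on observer 1
  idx2 <- which(s1 == 1)
  rows <- rbind(data[idx1, , drop = FALSE], data[idx2, , drop = FALSE])
  rows$.record <- c(idx1, idx2)
  rows$observer <- factor(rep(c("pilot", "backseat"),
                              c(length(idx1), length(idx2))),
                          levels = c("pilot", "backseat"))
  rows$response <- c(s1[idx1], s2[idx2])
  rownames(rows) <- NULL
  rows
}

#' Fit the conditional double-observer logistic model
#'
#' Binomial-logit maximum likelihood on the stacked conditional rows of
#' [build_conditional_rows()]. Distance is typically entered as a polynomial
#' B-spline, `bs(distance, degree = 4)` (degree-4 basis, boundary knots at
#' the observed distance range, no interior knots), so the fitted conditional
#' detection curve can be unimodal without constraining its apex.
#'
#' @param data Data frame of detected groups with capture-history columns
#'   (see [build_conditional_rows()]); stacked internally.
#' @param formula One-sided formula of predictors for the conditional
#'   detection probability. `observer` (the response observer's identity) and
#'   `bs(distance, ...)` may be used directly. Default
#'   `~ observer + bs(distance, degree = 4)`.
#' @return An object of class `"mrcond"`: the stacked `rows`, fitted `glm`,
#'   `coefficients`, `loglik`, `aic`, `vcov`, the distance `boundary` used
#'   for prediction clamping, and the original `data`.
#' @seealso [conditional_prob()], [p_dot_at_apex()], [mr_apex()], [mr_gof()]
#' @export
fit_mrcond <- function(data, formula = ~ observer + bs(distance, degree = 4)) {
  rows <- build_conditional_rows(data)
  if (!inherits(formula, "formula") || length(formula) != 2L)
    stop("'formula' must be one-sided (~ terms)", call. = FALSE)
  f <- stats::as.formula(call("~", quote(response), formula[[2L]]))
  environment(f) <- environment()  # so bs() resolves to splines::bs
  g <- stats::glm(f, family = stats::binomial(), data = rows)
  if (any(is.na(stats::coef(g))))
    stop("rank-deficient conditional model; aliased term(s): ",
         paste(names(stats::coef(g))[is.na(stats::coef(g))], collapse = ", "),
         call. = FALSE)
  structure(list(
    glm = g, rows = rows, data = data,
    coefficients = stats::coef(g),
    loglik = as.numeric(stats::logLik(g)),
    aic = stats::AIC(g),
    vcov = stats::vcov(g),
    boundary = range(rows$distance),
    formula = formula, converged = g$converged,
    call = match.call()
  ), class = "mrcond")
}

#' @export
print.mrcond <- function(x, digits = 4, ...) {
  cat("Conditional double-observer logistic model\n")
  cat(sprintf("  %d stacked rows from %d detections; logLik = %.*f, AIC = %.*f\n",
              nrow(x$rows), nrow(x$data), digits, x$loglik, digits, x$aic))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.mrcond <- function(object, ...) summary(object$glm, ...)

#' @export
coef.mrcond <- function(object, ...) object$coefficients

#' @export
vcov.mrcond <- function(object, ...) object$vcov

#' @export
logLik.mrcond <- function(object, ...) stats::logLik(object$glm)

# Build prediction data: recycle z rows against y, set observer, clamp y.
mr_newdata <- function(object, observer, y, z) {
  if (!is.data.frame(z)) z <- as.data.frame(as.list(z))
  n <- max(length(y), nrow(z))
  if (nrow(z) == 1L && n > 1L) z <- z[rep(1L, n), , drop = FALSE]
  y <- rep_len(y, n)
  lo <- object$boundary[1L]; hi <- object$boundary[2L]
  if (any(y < lo | y > hi)) {
    warning("distance(s) outside the fitted spline range [",
            signif(lo, 4), ", ", signif(hi, 4), "] clamped to the boundary",
            call. = FALSE)
    y <- pmin(pmax(y, lo), hi)
  }
  z$distance <- y
  z$observer <- factor(if (identical(observer, 1) || identical(observer, 1L) ||
                             identical(observer, "pilot")) "pilot"
                       else "backseat",
                       levels = c("pilot", "backseat"))
  z
}

#' Conditional detection probability for one observer
#'
#' Probability that the given observer detects a group at distance `y` with
#' covariates `z`, conditional on the other observer having detected it:
#' the inverse logit of the fitted linear predictor with the observer
#' indicator set accordingly. Distances outside the fitted spline range are
#' clamped to the boundary with a warning.
#'
#' @param object An `"mrcond"` fit.
#' @param observer `1`/`"pilot"` or `2`/`"backseat"`: the observer whose
#'   detection probability is requested.
#' @param y Distance(s) in metres.
#' @param z Data frame (or named list) of covariate values.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
conditional_prob <- function(object, observer, y, z) {
  stopifnot(inherits(object, "mrcond"))
  nd <- mr_newdata(object, observer, y, z)
  as.vector(stats::predict(object$glm, newdata = nd, type = "response"))
}

#' Combined at-apex detection probability
#'
#' Under point independence the observers are independent at the detection
#' apex, so the probability that at least one detects a group there is
#' `p1 + p2 - p1*p2` with `p1 = p_{1|2}(mu, z)` and `p2 = p_{2|1}(mu, z)`.
#'
#' @param object An `"mrcond"` fit.
#' @param mu Apex distance (from the MCDS fit).
#' @param z Data frame of covariate values (one result per row).
#' @return Numeric vector of probabilities; always at least
#'   `max(p1, p2)`.
#' @export
p_dot_at_apex <- function(object, mu, z) {
  p1 <- conditional_prob(object, 1L, mu, z)
  p2 <- conditional_prob(object, 2L, mu, z)
  p1 + p2 - p1 * p2
}

#' Select a conditional double-observer model by AIC
#'
#' Fits each candidate formula with [fit_mrcond()] and returns the fit with
#' the lowest AIC (ties within 2 AIC units are reported via the
#' `"aic_table"` attribute; the lowest-AIC model is returned).
#'
#' @param data Data frame of detected groups (see
#'   [build_conditional_rows()]).
#' @param candidates List of one-sided predictor formulas.
#' @return The best `"mrcond"` fit, with an `"aic_table"` attribute
#'   (data frame of formula strings and AICs, ordered) recording the
#'   comparison.
#' @export
select_mrcond <- function(data, candidates) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  fits <- lapply(candidates, function(f)
    tryCatch(fit_mrcond(data, formula = f), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate conditional models failed", call. = FALSE)
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  tab <- data.frame(
    formula = vapply(candidates[ok], function(f) deparse1(f), character(1)),
    aic = aics)
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  best <- fits[ok][[which.min(aics)]]
  attr(best, "aic_table") <- tab
  best
}

#' Default candidate formulas for the conditional model
#'
#' A small ladder of polynomial-spline distance terms (the degree-4 basis
#' with 0, 1 and 2 interior knots) with an observer effect; extra terms can
#' be appended to every candidate.
#'
#' @param extra Optional character vector of additional covariate terms.
#' @return List of one-sided formulas for [select_mrcond()].
#' @export
mr_candidate_formulas <- function(extra = NULL) {
  rhs <- c("observer + bs(distance, degree = 4)",
           "observer + bs(distance, degree = 4, df = 5)",
           "observer + bs(distance, degree = 4, df = 6)")
  if (!is.null(extra))
    rhs <- vapply(rhs, function(r) paste(c(r, extra), collapse = " + "),
                  character(1))
  lapply(rhs, function(r) stats::as.formula(paste("~", r)))
}

#' Average covariate values of the detected groups
#'
#' Means for numeric columns, most frequent level for factors/characters;
#' used for average-covariate detection curves and the mark-recapture apex.
#'
#' @param data Data frame (one row per detected group).
#' @return One-row data frame.
#' @export
average_covariates <- function(data) {
  out <- lapply(data, function(col) {
    if (is.numeric(col)) mean(col)
    else if (is.logical(col)) mean(col) >= 0.5
    else {
      tb <- table(col)
      f <- names(tb)[which.max(tb)]
      if (is.factor(col)) factor(f, levels = levels(col)) else f
    }
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Apex of the fitted mark-recapture detection curve
#'
#' Distance maximizing the combined conditional detection probability
#' `p1|2 + p2|1 - p1|2 p2|1` at averaged covariates, found by a grid search
#' with local refinement over the fitted distance range. The spline fit's
#' apex is unrestricted, so it need not coincide with the MCDS apex.
#'
#' @param object An `"mrcond"` fit.
#' @param z Covariate row at which to evaluate (default: averages of the
#'   detected groups via [average_covariates()]).
#' @param grid_n Grid resolution.
#' @return List with `apex` (m), `value` (combined detection there), `flat`
#'   (TRUE when the curve varies by < 1e-6 across the range) and `boundary`
#'   (TRUE when the maximum sits on the range boundary).
#' @export
mr_apex <- function(object, z = NULL, grid_n = 400L) {
  stopifnot(inherits(object, "mrcond"))
  if (is.null(z)) {
    drop_cols <- c("seen_by_1", "seen_by_2", "distance")
    z <- average_covariates(object$data[setdiff(colnames(object$data),
                                                drop_cols)])
  }
  lo <- object$boundary[1L]; hi <- object$boundary[2L]
  yy <- seq(lo, hi, length.out = grid_n)
  pp <- p_dot_at_apex(object, yy, z)
  flat <- diff(range(pp)) < 1e-6
  i <- which.max(pp)
  if (flat || i == 1L || i == grid_n) {
    return(list(apex = yy[i], value = pp[i], flat = flat,
                boundary = !flat && (i == 1L || i == grid_n)))
  }
  opt <- stats::optimize(function(y) p_dot_at_apex(object, y, z),
                         c(yy[i - 1L], yy[i + 1L]), maximum = TRUE,
                         tol = 1e-6)
  list(apex = opt$maximum, value = opt$objective, flat = FALSE,
       boundary = FALSE)
}

#' Hosmer-Lemeshow-style goodness of fit for the conditional model
#'
#' Stacked rows are grouped into bins of similar fitted probability;
#' observed and expected successes are compared with a chi-square statistic.
#' Degrees of freedom are `bins - 1 - df_correction` (the conventional
#' Hosmer-Lemeshow rule is `df_correction = 1`, i.e. `bins - 2`).
#'
#' @param object An `"mrcond"` fit.
#' @param n_bins Number of probability bins (quantile-based); empty bins are
#'   pooled.
#' @param df_correction Subtracted (beyond the usual 1) from the bin count to
#'   give the degrees of freedom.
#' @return A `"gof_result"` (see [mcds_gof_chisq()]); `bins` holds per-group
#'   row counts, observed and expected successes.
#' @export
mr_gof <- function(object, n_bins = 10, df_correction = 1) {
  stopifnot(inherits(object, "mrcond"))
  p <- stats::fitted(object$glm)
  yobs <- object$rows$response
  qs <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 3L)
    stop("fitted probabilities are (nearly) constant; cannot bin for the ",
         "goodness-of-fit test (df would be < 1)", call. = FALSE)
  grp <- cut(p, qs, include.lowest = TRUE)
  ng <- tapply(yobs, grp, length)
  keep <- !is.na(ng) & ng > 0
  O <- tapply(yobs, grp, sum)[keep]
  E <- tapply(p, grp, sum)[keep]
  n_g <- ng[keep]
  pooled <- n_bins - length(n_g)
  denom <- E * (1 - E / n_g)
  denom[denom < 1e-12] <- 1e-12
  statistic <- sum((O - E)^2 / denom)
  df <- length(n_g) - 1L - df_correction
  if (df < 1L)
    stop("goodness-of-fit df = ", df, " < 1; increase 'n_bins'",
         call. = FALSE)
  structure(list(
    statistic = statistic, df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    bins = data.frame(n = as.vector(n_g), observed = as.vector(O),
                      expected = as.vector(E)),
    pooled = pooled
  ), class = "gof_result")
}
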