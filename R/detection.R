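# Two-piece (split) normal detection key function and its strip integrals.
#
# The key function is
#   g(y) = exp{-[(y - mu) / (2 sigma1)]^2}   for w_b <= y < mu
#        = exp{-[(y - mu) / (2 sigma2)]^2}   for y >= mu
# i.e. two half-normal curves sharing the mode mu but with different scales,
# so the curve is unimodal with a single apex at mu regardless of covariates.
# Note the 2*sigma (not sqrt(2)*sigma) in the denominator: this is the adopted
# parameterization; it differs from the textbook half-normal only by a
# rescaling of sigma (sigma -> sigma * sqrt(2)), so fitted curves are
# identical and only printed coefficient values depend on the choice.

erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1
erfinv <- function(x) stats::qnorm((x + 1) / 2) / sqrt(2)

#' Covariate specification for a two-piece normal detection model
#'
#' Names the covariates entering the two scale parameters. Shared covariates
#' act on both scales; left-only covariates act on `sigma1` (the inner,
#' `y < mu` side); right-only covariates act on `sigma2` (the outer,
#' `y >= mu` side). The three groups must be disjoint.
#'
#' @param shared,left,right Character vectors of covariate names (possibly
#'   empty). Covariates are used as supplied, i.e. any preprocessing
#'   (e.g. percent cover divided by 20) must already be applied; see
#'   [read_observations()] for the standard transforms.
#' @return An object of class `"covariate_spec"`.
#' @examples
#' covariate_spec(shared = c("flat", "cover20"), right = "bin_lnsd")
#' @export
covariate_spec <- function(shared = character(), left = character(),
                           right = character()) {
  shared <- as.character(shared); left <- as.character(left)
  right <- as.character(right)
  all_terms <- c(shared, left, right)
  if (anyDuplicated(all_terms))
    stop("covariate groups must be disjoint; duplicated: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
         call. = FALSE)
  structure(list(shared = shared, left = left, right = right,
                 k = length(all_terms)),
            class = "covariate_spec")
}

#' Two-piece normal detection parameters
#'
#' @param mu Detection apex (mode) in metres; must lie strictly inside the
#'   observed strip when used with a [survey_geometry()].
#' @param beta0 Log-scale intercept: with all covariates zero both scales
#'   equal `exp(beta0)`.
#' @param beta_shared,beta_left,beta_right Named coefficient vectors matching
#'   the `shared`, `left` and `right` groups of a [covariate_spec()].
#' @return An object of class `"detection_params"`.
#' @export
detection_params <- function(mu, beta0, beta_shared = numeric(),
                             beta_left = numeric(), beta_right = numeric()) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0,
            is.numeric(beta0), length(beta0) == 1L, is.finite(beta0))
  structure(list(mu = mu, beta0 = beta0,
                 beta_shared = beta_shared, beta_left = beta_left,
                 beta_right = beta_right),
            class = "detection_params")
}

# Extract the covariate columns named in `names` from z (data.frame, list or
# named vector), as an n x k numeric matrix. Errors name any missing covariate.
covariate_matrix <- function(z, names) {
  if (length(names) == 0L) {
    n <- if (is.data.frame(z)) nrow(z) else 1L
    return(matrix(0, n, 0L))
  }
  if (!is.data.frame(z)) z <- as.data.frame(as.list(z))
  missing <- setdiff(names, colnames(z))
  if (length(missing))
    stop("covariate(s) not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(z[names])
  storage.mode(m) <- "double"
  m
}

#' Scale parameters of the two-piece normal under covariates
#'
#' Computes the left and right scales
#' `sigma1 = exp(beta0 + shared terms + left terms)` and
#' `sigma2 = exp(beta0 + shared terms + right terms)` for each covariate
#' row in `z`.
#'
#' @param params A [detection_params()] object.
#' @param z A data frame (one row per observation), list or named vector of
#'   covariate values, already transformed.
#' @param spec A [covariate_spec()].
#' @return A list with numeric vectors `sigma1` and `sigma2` (strictly
#'   positive, one element per row of `z`).
#' @examples
#' sp <- covariate_spec(shared = "flat")
#' pa <- detection_params(mu = 100, beta0 = 3.5, beta_shared = c(flat = 0.5))
#' scale_values(pa, data.frame(flat = c(0, 1)), sp)
#' @export
scale_values <- function(params, z, spec) {
  stopifnot(inherits(params, "detection_params"), inherits(spec, "covariate_spec"))
  Xs <- covariate_matrix(z, spec$shared)
  Xl <- covariate_matrix(z, spec$left)
  Xr <- covariate_matrix(z, spec$right)
  lp_shared <- params$beta0 + drop(Xs %*% params$beta_shared)
  lp1 <- lp_shared + drop(Xl %*% params$beta_left)
  lp2 <- lp_shared + drop(Xr %*% params$beta_right)
  if (any(!is.finite(lp1)) || any(!is.finite(lp2)))
    stop("non-finite linear predictor for detection scale", call. = FALSE)
  list(sigma1 = exp(lp1), sigma2 = exp(lp2))
}

# Vectorized key function given precomputed scales; y, sigma1, sigma2 recycled.
tpn_key <- function(y, mu, sigma1, sigma2) {
  s <- ifelse(y < mu, sigma1, sigma2)
  exp(-((y - mu) / (2 * s))^2)
}

# Closed-form integral of the key function over [a, b] within one covariate
# row: int exp{-[(y-mu)/(2s)]^2} dy = s*sqrt(pi)*[erf((b-mu)/(2s)) -
# erf((a-mu)/(2s))] on a side with constant s; split at mu when straddled.
# All arguments may be vectors (recycled to common length).
tpn_integral <- function(a, b, mu, sigma1, sigma2) {
  n <- max(length(a), length(b), length(mu), length(sigma1), length(sigma2))
  a <- rep_len(a, n); b <- rep_len(b, n); mu <- rep_len(mu, n)
  sigma1 <- rep_len(sigma1, n); sigma2 <- rep_len(sigma2, n)
  one_side <- function(lo, hi, m, s) {
    # lo, hi already on a single side of m
    s * sqrt(pi) * (erf((hi - m) / (2 * s)) - erf((lo - m) / (2 * s)))
  }
  lo1 <- pmin(a, mu); hi1 <- pmin(b, mu)   # left-of-mu portion
  lo2 <- pmax(a, mu); hi2 <- pmax(b, mu)   # right-of-mu portion
  out <- numeric(n)
  left <- hi1 > lo1
  right <- hi2 > lo2
  if (any(left))
    out[left] <- one_side(lo1[left], hi1[left], mu[left], sigma1[left])
  if (any(right))
    out[right] <- out[right] +
      one_side(lo2[right], hi2[right], mu[right], sigma2[right])
  out
}

#' Two-piece normal detection probability
#'
#' Evaluates the unimodal detection key function at distance `y` for the
#' covariate values `z`. The curve rises from the blind-strip edge to an apex
#' of exactly 1 at `y = mu` and falls beyond it; the inner and outer slopes
#' are governed by `sigma1` and `sigma2` respectively.
#'
#' @inheritParams scale_values
#' @param y Numeric vector of distances (metres), all within `[w_b, w]`.
#' @param geom A [survey_geometry()].
#' @return Numeric vector of detection probabilities in `(0, 1]`. If `z` has
#'   multiple rows its length must match `y` (or `y` have length 1).
#' @export
detection_prob <- function(y, params, z, spec, geom) {
  stopifnot(inherits(geom, "survey_geometry"))
  if (any(y < geom$w_b - 1e-9 | y > geom$w + 1e-9))
    stop("distance outside the observed strip [",
         geom$w_b, ", ", geom$w, "]", call. = FALSE)
  if (params$mu <= geom$w_b || params$mu >= geom$w)
    stop("detection apex 'mu' must lie strictly inside the strip", call. = FALSE)
  s <- scale_values(params, z, spec)
  tpn_key(y, params$mu, s$sigma1, s$sigma2)
}

#' Strip-averaged detection probability
#'
#' The average of the detection key function over the strip under the uniform
#' distance density: `p(z) = int_{w_b}^{w} g(y, z) pi(y) dy`, evaluated in
#' closed form via the error function.
#'
#' @inheritParams detection_prob
#' @return Numeric vector (one value per covariate row) in `(0, 1]`.
#' @examples
#' geom <- survey_geometry(22, 350)
#' sp <- covariate_spec()
#' pa <- detection_params(mu = 102.6, beta0 = log(50))
#' strip_average_detection(pa, data.frame(row = 1), sp, geom)
#' @export
strip_average_detection <- function(params, z, spec, geom) {
  stopifnot(inherits(geom, "survey_geometry"))
  if (params$mu <= geom$w_b || params$mu >= geom$w)
    stop("detection apex 'mu' must lie strictly inside the strip", call. = FALSE)
  s <- scale_values(params, z, spec)
  tpn_integral(geom$w_b, geom$w, params$mu, s$sigma1, s$sigma2) / geom$width
}

# Quadrature cross-check of the closed form (used by tests and on demand).
strip_average_quadrature <- function(mu, sigma1, sigma2, geom,
                                     rel.tol = 1e-10) {
  f <- function(y) tpn_key(y, mu, sigma1, sigma2)
  v1 <- stats::integrate(f, geom$w_b, mu, rel.tol = rel.tol)$value
  v2 <- stats::integrate(f, mu, geom$w, rel.tol = rel.tol)$value
  (v1 + v2) / geom$width
}

# Random distances from the two-piece normal key truncated to [w_b, w]:
# side chosen with probability proportional to the side areas, then the
# truncated half-normal inverted via erfinv. Vectorized over n.
rtpn <- function(n, mu, sigma1, sigma2, w_b, w) {
  sigma1 <- rep_len(sigma1, n); sigma2 <- rep_len(sigma2, n)
  a1 <- sigma1 * sqrt(pi) * erf((mu - w_b) / (2 * sigma1))
  a2 <- sigma2 * sqrt(pi) * erf((w - mu) / (2 * sigma2))
  left <- stats::runif(n) < a1 / (a1 + a2)
  u <- stats::runif(n)
  y <- numeric(n)
  e1 <- erf((mu - w_b) / (2 * sigma1))
  e2 <- erf((w - mu) / (2 * sigma2))
  y[left] <- mu - 2 * sigma1[left] * erfinv(u[left] * e1[left])
  y[!left] <- mu + 2 * sigma2[!left] * erfinv(u[!left] * e2[!left])
  pmin(pmax(y, w_b), w)
}
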