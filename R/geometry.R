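#' Survey strip geometry
#'
#' Describes the one-sided observation strip of a line-transect survey:
#' distances are perpendicular (closest) distances to the transect, observed
#' between a left (blind-strip) truncation distance `w_b` and a right
#' truncation distance `w`. Under random transect placement the implied
#' distance density is uniform, `pi(y) = 1 / (w - w_b)` on `[w_b, w]`.
#'
#' Aerial surveys typically have a blind strip directly under the aircraft
#' that neither observer can see; `w_b` is its outer edge (0 for ground
#' surveys with full visibility at the line).
#'
#' @param w_b Left (blind-strip) truncation distance in metres, `>= 0`.
#' @param w Right truncation distance in metres, `> w_b`.
#' @return An object of class `"survey_geometry"`: a list with elements
#'   `w_b`, `w` and `width = w - w_b`.
#' @examples
#' geom <- survey_geometry(w_b = 22, w = 350)
#' pi_y(geom)  # 1/328
#' @export
survey_geometry <- function(w_b = 0, w) {
  if (!is.numeric(w_b) || length(w_b) != 1L || !is.finite(w_b) || w_b < 0)
    stop("'w_b' must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= w_b)
    stop("'w' must be a single finite number greater than 'w_b'", call. = FALSE)
  structure(list(w_b = w_b, w = w, width = w - w_b),
            class = "survey_geometry")
}

#' @rdname survey_geometry
#' @param geom A `"survey_geometry"` object.
#' @export
pi_y <- function(geom) {
  stopifnot(inherits(geom, "survey_geometry"))
  1 / geom$width
}

#' @export
print.survey_geometry <- function(x, ...) {
  cat(sprintf("One-sided survey strip: [%g, %g] m (width %g m), pi(y) = 1/%g\n",
              x$w_b, x$w, x$width, x$width))
  invisible(x)
}
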