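#' Ellipticity of an eye opening
#'
#' Treats the palpebral fissure as an ellipse with semi-major axis `a` and
#' semi-minor axis `b` and returns its eccentricity
#' \eqn{e = \sqrt{1 - b^2/a^2}}: 0 for a perfectly round opening,
#' approaching 1 for a slit.
#'
#' @param a Semi-major axis (any length unit).
#' @param b Semi-minor axis (same unit); must satisfy `0 < b <= a`.
#' @return Ellipticity in `[0, 1)`. Vectorized over `a` and `b`.
#' @examples
#' ellipticity(1, 0.38) # ~0.92, the Soat1-null slit-eye phenotype
#' ellipticity(1, 1)    # 0, a round eye
#' @export
ellipticity <- function(a, b) {
  check_axes(a, b)
  sqrt(1 - (b / a)^2)
}

#' Short-to-long axis ratio of an eye opening
#'
#' @inheritParams ellipticity
#' @return `b / a` in `(0, 1]`. Vectorized.
#' @export
axis_ratio <- function(a, b) {
  check_axes(a, b)
  b / a
}

check_axes <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(b <= 0)) {
    stop("axes must be finite and positive", call. = FALSE)
  }
  if (any(b > a)) {
    stop("semi-minor axis exceeds semi-major axis; check axis order",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Append eye-shape metrics to a measurement table
#'
#' @param data Data frame with semi-major and semi-minor axis columns
#'   (default names `a` and `b`), e.g. read from a morphometry CSV with
#'   columns `animal_id`, `genotype`, `a`, `b`.
#' @param a,b Column names (strings) of the axes.
#' @return The input as a tibble with `ellipticity` and `axis_ratio`
#'   columns appended.
#' @export
add_eye_metrics <- function(data, a = "a", b = "b") {
  out <- tibble::as_tibble(data)
  out$ellipticity <- ellipticity(out[[a]], out[[b]])
  out$axis_ratio <- axis_ratio(out[[a]], out[[b]])
  out
}
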