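#' Noise envelope for gating and synaptic variables
#'
#' Builds the envelope function chi that multiplies the square-root Langevin
#' diffusion of every gating (`n`, `m`, `h`) and synaptic (`y`) variable.
#' The structural hypothesis on the channel-noise model requires chi to be
#' bounded, Lipschitz, and compactly supported inside (0, 1); together with
#' inward-pointing drifts at the boundary this confines the proportion
#' variables to \[0, 1\] (see [check_boundary_conditions()]).
#'
#' Two compliant shapes are provided, plus a deliberately non-compliant one:
#' \describe{
#'   \item{`trapezoid`}{0 outside `[lo, hi]`, `peak` on `[lo + ramp, hi - ramp]`,
#'     linear in between. Lipschitz constant `peak / ramp`. The default
#'     (`lo = 0.05`, `hi = 0.95`, `ramp = 0.05`) is ~1 in the bulk so the
#'     Langevin noise is unattenuated away from the boundaries.}
#'   \item{`cosine_bump`}{`peak * sin(pi * (x - lo)/(hi - lo))^2` on `(lo, hi)`,
#'     0 outside; smooth, Lipschitz constant `peak * pi / (hi - lo)`.}
#'   \item{`constant`}{chi identically `peak`. This violates the compact-support
#'     hypothesis and exists only as a negative control for
#'     [validate_hypotheses()] and the excursion experiments.}
#' }
#'
#' @param shape one of `"trapezoid"`, `"cosine_bump"`, `"constant"`.
#' @param lo,hi support endpoints, `0 < lo < hi < 1` (ignored for `"constant"`).
#' @param peak maximum value (default 1).
#' @param ramp trapezoid ramp width on each side (default 0.05).
#' @return an object of class `nm_chi`: a list with the shape parameters and
#'   the reportable Lipschitz constant.
#' @examples
#' ch <- chi_fun()
#' chi_eval(ch, c(0, 0.5, 1))
#' @export
chi_fun <- function(shape = c("trapezoid", "cosine_bump", "constant"),
                    lo = 0.05, hi = 0.95, peak = 1, ramp = 0.05) {
  shape <- match.arg(shape)
  stopifnot(peak >= 0)  # peak 0 = noiseless Langevin limit (degenerate envelope)
  if (shape != "constant") {
    if (!(lo > 0 && hi < 1 && lo < hi)) {
      abort("chi support must satisfy 0 < lo < hi < 1")
    }
    if (shape == "trapezoid" && 2 * ramp > (hi - lo)) {
      abort("trapezoid ramps overlap: need 2 * ramp <= hi - lo")
    }
  }
  lip <- switch(shape,
    trapezoid   = peak / ramp,
    cosine_bump = peak * pi / (hi - lo),
    constant    = 0
  )
  structure(
    list(shape = shape, lo = lo, hi = hi, peak = peak, ramp = ramp,
         lipschitz = lip),
    class = "nm_chi"
  )
}

#' Evaluate the noise envelope
#'
#' @param chi an [chi_fun()] object.
#' @param x numeric vector of proportions (any real values are accepted; the
#'   envelope vanishes outside its support).
#' @return numeric vector of envelope values in `[0, peak]`.
#' @export
chi_eval <- function(chi, x) {
  stopifnot(inherits(chi, "nm_chi"))
  switch(chi$shape,
    constant = rep_len(chi$peak, length(x)),
    trapezoid = {
      # ramp fraction, snapped to the plateau within 1e-12 so that the
      # envelope is exactly `peak` on [lo + ramp, hi - ramp] despite the
      # breakpoints not being representable in binary
      u <- pmin((x - chi$lo) / chi$ramp, (chi$hi - x) / chi$ramp)
      u <- pmax(0, pmin(1, u))
      u[u > 1 - 1e-12] <- 1
      chi$peak * u
    },
    cosine_bump = {
      inside <- x > chi$lo & x < chi$hi
      out <- numeric(length(x))
      z <- (x[inside] - chi$lo) / (chi$hi - chi$lo)
      out[inside] <- chi$peak * sin(pi * z)^2
      out
    }
  )
}

#' @export
print.nm_chi <- function(x, ...) {
  if (x$shape == "constant") {
    cat(sprintf("<nm_chi> constant envelope, value %g (non-compliant: no compact support)\n",
                x$peak))
  } else {
    cat(sprintf("<nm_chi> %s on (%g, %g), peak %g, Lipschitz constant %g\n",
                x$shape, x$lo, x$hi, x$peak, x$lipschitz))
  }
  invisible(x)
}
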