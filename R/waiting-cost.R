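#' Waiting-cost curve for victims' bearing capacity
#'
#' The per-kilogram monetary loss of victims who have waited `t` seconds for a
#' PPE item grows quadratically with the waiting time and saturates at a
#' maximum bearable loss: `lambda(t) = a * t^2` for `t <= T` and
#' `lambda(t) = lambda_max` for `t > T`.  The quadratic branch captures the
#' accelerating physiological and psychological toll of waiting; the plateau
#' is the loss of a victim who effectively never receives the item.
#'
#' The three parameters must describe a continuous curve: `a * T^2` has to
#' equal `lambda_max` up to a relative tolerance of `1e-4`.
#'
#' @param quad_coeff growth coefficient `a` of the quadratic branch
#'   (yuan s^-2 per kg); must be positive.
#' @param breakpoint saturation time `T` in seconds; must be positive.
#' @param plateau maximum per-kg loss `lambda_max` in yuan; must be positive.
#' @return An object of class `waiting_cost_curve`.
#' @examples
#' crv <- waiting_cost_curve(1 / 7315661, 604800, 50000)
#' waiting_cost(crv, c(0, 302400, 7e5))
#' @seealso [waiting_cost()], [wenzhou_curve()]
#' @export
waiting_cost_curve <- function(quad_coeff, breakpoint, plateau) {
  stopifnot(is.numeric(quad_coeff), length(quad_coeff) == 1L,
            is.numeric(breakpoint), length(breakpoint) == 1L,
            is.numeric(plateau), length(plateau) == 1L)
  if (!is.finite(quad_coeff) || quad_coeff <= 0)
    stop("'quad_coeff' must be a positive finite number")
  if (!is.finite(breakpoint) || breakpoint <= 0)
    stop("'breakpoint' must be a positive finite number")
  if (!is.finite(plateau) || plateau <= 0)
    stop("'plateau' must be a positive finite number")
  gap <- abs(quad_coeff * breakpoint^2 - plateau) / plateau
  if (gap > 1e-4)
    stop(sprintf(paste0("curve is discontinuous at the breakpoint: ",
                        "|a*T^2 - plateau|/plateau = %.3g > 1e-4"), gap))
  structure(list(quad_coeff = quad_coeff, breakpoint = breakpoint,
                 plateau = plateau),
            class = "waiting_cost_curve")
}

#' The case-study waiting-cost curve
#'
#' Quadratic coefficient `1/7315661` yuan s^-2 per kg, breakpoint one week
#' (604800 s), plateau 50000 yuan per kg.
#'
#' @return A [waiting_cost_curve()].
#' @export
wenzhou_curve <- function() {
  waiting_cost_curve(quad_coeff = 1 / 7315661, breakpoint = 604800,
                     plateau = 50000)
}

#' Evaluate a waiting-cost curve
#'
#' @param curve a [waiting_cost_curve()].
#' @param t waiting time(s) in seconds; vectorized, all values must be `>= 0`.
#' @return Per-kg loss in yuan, same length as `t`; always in
#'   `[0, curve$plateau]` and non-decreasing in `t`.
#' @export
waiting_cost <- function(curve, t) {
  stopifnot(inherits(curve, "waiting_cost_curve"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("waiting time 't' must be finite and non-negative")
  ifelse(t <= curve$breakpoint,
         pmin(curve$quad_coeff * t^2, curve$plateau),
         curve$plateau)
}

#' @export
print.waiting_cost_curve <- function(x, ...) {
  cat(sprintf(
    "Waiting-cost curve: lambda(t) = %.6g * t^2 (t <= %g s), plateau %g yuan/kg\n",
    x$quad_coeff, x$breakpoint, x$plateau))
  invisible(x)
}
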