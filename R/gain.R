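#' Transfer-function (gain) parameters
#'
#' The stochastic neuron's instantaneous firing rate is a parametric function
#' of its membrane potential, \eqn{g(u) = r_0 \log(1 + e^{(u - u_0)/u_\alpha})}
#' (a softplus). The three parameters are the handles of intrinsic plasticity:
#' `r0` sets the slope (asymptotic slope is `r0 / u_alpha`), `u0` shifts the
#' curve along the membrane-potential axis, and `u_alpha` rescales that axis.
#'
#' @param r0 Rate scale in Hz; must be positive.
#' @param u0 Threshold shift in mV.
#' @param u_alpha Membrane-axis scale in mV; must be positive.
#'
#' @return An object of class `gain_params` (a named list).
#' @examples
#' p <- gain_params()
#' gain(-55, p)  # = 10 * log(2)
#' @export
gain_params <- function(r0 = 10, u0 = -55, u_alpha = 2) {
  stopifnot(is.numeric(r0), is.numeric(u0), is.numeric(u_alpha),
            length(r0) == 1L, length(u0) == 1L, length(u_alpha) == 1L)
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be finite and > 0")
  if (!is.finite(u_alpha) || u_alpha <= 0) stop("u_alpha must be finite and > 0")
  if (!is.finite(u0)) stop("u0 must be finite")
  structure(list(r0 = r0, u0 = u0, u_alpha = u_alpha), class = "gain_params")
}

#' @export
print.gain_params <- function(x, ...) {
  cat(sprintf("gain_params: r0 = %.4g Hz, u0 = %.4g mV, u_alpha = %.4g mV\n",
              x$r0, x$u0, x$u_alpha))
  invisible(x)
}

# numerically stable softplus and logistic
softplus <- function(x) ifelse(x > 35, x, ifelse(x < -35, exp(x), log1p(exp(x))))
logistic <- function(x) 1 / (1 + exp(-x))

#' Instantaneous firing rate as a function of membrane potential
#'
#' Softplus gain \eqn{g(u) = r_0 \log(1 + e^{(u-u_0)/u_\alpha})}: nonnegative,
#' strictly increasing and continuous in `u`, vanishing as \eqn{u \to -\infty}
#' and asymptotically linear with slope `r0 / u_alpha` for \eqn{u \gg u_0}.
#'
#' @param u Membrane potential in mV (vectorized).
#' @param p A [gain_params()] object.
#' @return Instantaneous rate(s) in Hz.
#' @export
gain <- function(u, p) {
  if (!inherits(p, "gain_params")) p <- do.call(gain_params, as.list(p)[c("r0", "u0", "u_alpha")])
  if (any(!is.finite(u))) stop("membrane potential must be finite")
  p$r0 * softplus((u - p$u0) / p$u_alpha)
}

#' Analytic partial derivatives of the gain function
#'
#' Returns the partials needed by the intrinsic-plasticity updates: the
#' derivative with respect to each gain parameter, the slope in `u`, and the
#' mixed second derivatives of the slope with respect to each parameter.
#'
#' @inheritParams gain
#' @return A list with elements `g`, `d_r0`, `d_u0`, `d_ualpha`, `d_u`,
#'   `d2_u_r0`, `d2_u_u0`, `d2_u_ualpha` (all vectorized over `u`).
#' @export
gain_gradients <- function(u, p) {
  if (any(!is.finite(u))) stop("membrane potential must be finite")
  ua <- p$u_alpha
  x <- (u - p$u0) / ua
  s <- softplus(x)
  sg <- logistic(x)
  g <- p$r0 * s
  list(
    g = g,
    d_r0 = s,
    d_u0 = -p$r0 * sg / ua,
    d_ualpha = -p$r0 * sg * x / ua,
    d_u = p$r0 * sg / ua,
    d2_u_r0 = sg / ua,
    d2_u_u0 = -p$r0 * sg * (1 - sg) / ua^2,
    d2_u_ualpha = -p$r0 * (sg + x * sg * (1 - sg)) / ua^2
  )
}
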