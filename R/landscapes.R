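#' Sex-specific fecundity landscapes
#'
#' Construct a pair of male and female fecundity landscapes over the trait
#' interval \eqn{[-\theta, \theta]}, with the male optimum at \eqn{-\theta}
#' and the female optimum at \eqn{+\theta}. Two families are supported:
#'
#' * `"power"`:
#'   \deqn{w_m(z) = K_m\,(1 - c_m\,[1 - ((\theta - z)/(2\theta))^{b_m}])}
#'   \deqn{w_f(z) = K_f\,(1 - c_f\,[1 - ((\theta + z)/(2\theta))^{b_f}])}
#'   so male fecundity declines from \eqn{K_m} at \eqn{z=-\theta} to
#'   \eqn{K_m(1-c_m)} at \eqn{z=\theta}, and symmetrically for females. The
#'   costs \eqn{c_u \in [0,1]} tune the strength of the fecundity trade-off
#'   and the exponents \eqn{b_u > 0} its shape: landscapes are accelerating
#'   (convex) when \eqn{b_u > 1} and diminishing (concave) when
#'   \eqn{b_u < 1}.
#' * `"gaussian"`:
#'   \eqn{w_u(z) = K_u \exp(-(z - o_u)^2 / (2\sigma_u^2))} with optima
#'   \eqn{o_m = -\theta}, \eqn{o_f = +\theta}.
#'
#' All parameters are validated here, at construction; evaluation functions
#' assume a valid object.
#'
#' @param family `"power"` or `"gaussian"`.
#' @param theta Half-width of the trait interval (trait units, > 0). The two
#'   sex optima sit at `-theta` and `+theta`.
#' @param K_m,K_f Maximum gamete numbers (scale of each landscape, > 0).
#' @param c_m,c_f Fecundity cost coefficients in `[0, 1]` (power family).
#' @param b_m,b_f Landscape shape exponents, > 0 (power family).
#' @param sigma_m,sigma_f Gaussian widths in trait units, > 0 (gaussian
#'   family).
#'
#' @return An object of class `landscape_pair`.
#' @examples
#' lp <- landscape_pair("power", theta = 2, c_m = 0.9, c_f = 0.9,
#'                      b_m = 1.5, b_f = 1.5)
#' fecundity(0, "male", lp)
#' @seealso [fecundity()], [log_slope()], [log_curvature()]
#' @export
landscape_pair <- function(family = c("power", "gaussian"), theta,
                           K_m = 1, K_f = 1,
                           c_m = NULL, c_f = NULL, b_m = NULL, b_f = NULL,
                           sigma_m = NULL, sigma_f = NULL) {
  family <- match.arg(family)
  check_scalar(theta, "theta", lower = 0, strict = TRUE)
  check_scalar(K_m, "K_m", lower = 0, strict = TRUE)
  check_scalar(K_f, "K_f", lower = 0, strict = TRUE)
  lp <- list(family = family, theta = theta, K_m = K_m, K_f = K_f)
  if (family == "power") {
    if (is.null(c_m) || is.null(c_f) || is.null(b_m) || is.null(b_f))
      stop("power family requires c_m, c_f, b_m, b_f", call. = FALSE)
    check_scalar(c_m, "c_m", lower = 0, upper = 1)
    check_scalar(c_f, "c_f", lower = 0, upper = 1)
    check_scalar(b_m, "b_m", lower = 0, strict = TRUE)
    check_scalar(b_f, "b_f", lower = 0, strict = TRUE)
    lp <- c(lp, list(c_m = c_m, c_f = c_f, b_m = b_m, b_f = b_f))
  } else {
    if (is.null(sigma_m) || is.null(sigma_f))
      stop("gaussian family requires sigma_m and sigma_f", call. = FALSE)
    check_scalar(sigma_m, "sigma_m", lower = 0, strict = TRUE)
    check_scalar(sigma_f, "sigma_f", lower = 0, strict = TRUE)
    lp <- c(lp, list(sigma_m = sigma_m, sigma_f = sigma_f))
  }
  structure(lp, class = "landscape_pair")
}

#' Symmetric power landscape shorthand
#'
#' Convenience constructor for the common symmetric case `c_m = c_f = c`,
#' `b_m = b_f = b`, `K_m = K_f = K`.
#'
#' @param c Shared fecundity cost in `[0, 1]`.
#' @param b Shared shape exponent, > 0.
#' @param theta Trait-space half-width (default 2).
#' @param K Shared maximum fecundity (default 1).
#' @return A `landscape_pair`.
#' @export
symmetric_power <- function(c, b, theta = 2, K = 1) {
  landscape_pair("power", theta = theta, K_m = K, K_f = K,
                 c_m = c, c_f = c, b_m = b, b_f = b)
}

#' @export
print.landscape_pair <- function(x, ...) {
  cat("<landscape_pair> family:", x$family, " theta:", x$theta, "\n")
  if (x$family == "power") {
    cat(sprintf("  male:   K=%g c=%g b=%g (optimum -theta)\n",
                x$K_m, x$c_m, x$b_m))
    cat(sprintf("  female: K=%g c=%g b=%g (optimum +theta)\n",
                x$K_f, x$c_f, x$b_f))
  } else {
    cat(sprintf("  male:   K=%g sigma=%g (optimum -theta)\n", x$K_m, x$sigma_m))
    cat(sprintf("  female: K=%g sigma=%g (optimum +theta)\n", x$K_f, x$sigma_f))
  }
  invisible(x)
}

# shared domain guard: the model is defined on [-theta, theta] only
check_z <- function(z, lp, tol = 1e-8) {
  bound <- lp$theta * (1 + tol) + tol
  if (any(abs(z) > bound))
    stop(sprintf("trait value out of bounds: |z| must be <= theta = %g",
                 lp$theta), call. = FALSE)
  invisible(z)
}

#' Fecundity at a trait value
#'
#' Evaluate the male or female fecundity landscape at trait value(s) `z`.
#'
#' @param z Trait value(s) in `[-theta, theta]`; values outside the bound
#'   (beyond a small tolerance) are an error, since the model is only defined
#'   between the two sex optima.
#' @param sex `"male"` or `"female"`.
#' @param lp A [landscape_pair()].
#' @return Non-negative fecundity, vectorized over `z`.
#' @export
fecundity <- function(z, sex = c("male", "female"), lp) {
  sex <- match.arg(sex)
  stopifnot(inherits(lp, "landscape_pair"))
  check_z(z, lp)
  th <- lp$theta
  if (lp$family == "power") {
    if (sex == "male") {
      u <- pmax((th - z) / (2 * th), 0)
      lp$K_m * (1 - lp$c_m * (1 - u^lp$b_m))
    } else {
      v <- pmax((th + z) / (2 * th), 0)
      lp$K_f * (1 - lp$c_f * (1 - v^lp$b_f))
    }
  } else {
    if (sex == "male") {
      lp$K_m * exp(-(z + th)^2 / (2 * lp$sigma_m^2))
    } else {
      lp$K_f * exp(-(z - th)^2 / (2 * lp$sigma_f^2))
    }
  }
}

#' Logarithmic slope of a fecundity landscape
#'
#' Computes \eqn{w_u'(z) / w_u(z)}, the slope of the log fitness landscape in
#' sex `u`, per trait unit. Closed forms are used for both families; these
#' agree with central finite differences of `log(fecundity())`.
#'
#' @inheritParams fecundity
#' @return \eqn{w'(z)/w(z)}, vectorized over `z`.
#' @export
log_slope <- function(z, sex = c("male", "female"), lp) {
  sex <- match.arg(sex)
  stopifnot(inherits(lp, "landscape_pair"))
  check_z(z, lp)
  th <- lp$theta
  if (lp$family == "gaussian") {
    opt <- if (sex == "male") -th else th
    return(-(z - opt) / (if (sex == "male") lp$sigma_m else lp$sigma_f)^2)
  }
  w <- fecundity(z, sex, lp)
  if (any(w <= 0))
    stop("degenerate landscape point: fecundity is zero, log slope undefined",
         call. = FALSE)
  if (sex == "male") {
    u <- pmax((th - z) / (2 * th), 0)
    dw <- -lp$K_m * lp$c_m * lp$b_m * u^(lp$b_m - 1) / (2 * th)
  } else {
    v <- pmax((th + z) / (2 * th), 0)
    dw <- lp$K_f * lp$c_f * lp$b_f * v^(lp$b_f - 1) / (2 * th)
  }
  dw / w
}

#' Logarithmic curvature of a fecundity landscape
#'
#' Computes \eqn{w_u''(z) / w_u(z)}, the curvature of fitness in sex `u`, per
#' trait unit squared. Positive values mean the sex-specific landscape is
#' accelerating (convex) at `z`; negative values, diminishing (concave).
#'
#' @inheritParams fecundity
#' @return \eqn{w''(z)/w(z)}, vectorized over `z`.
#' @export
log_curvature <- function(z, sex = c("male", "female"), lp) {
  sex <- match.arg(sex)
  stopifnot(inherits(lp, "landscape_pair"))
  check_z(z, lp)
  th <- lp$theta
  if (lp$family == "gaussian") {
    opt <- if (sex == "male") -th else th
    s2 <- (if (sex == "male") lp$sigma_m else lp$sigma_f)^2
    return(((z - opt)^2 - s2) / s2^2)
  }
  b <- if (sex == "male") lp$b_m else lp$b_f
  if (b == 1) return(rep(0, length(z))) # linear landscape
  w <- fecundity(z, sex, lp)
  if (any(w <= 0))
    stop("degenerate landscape point: fecundity is zero, curvature undefined",
         call. = FALSE)
  if (sex == "male") {
    u <- pmax((th - z) / (2 * th), 0)
    d2w <- lp$K_m * lp$c_m * b * (b - 1) * u^(b - 2) / (4 * th^2)
  } else {
    v <- pmax((th + z) / (2 * th), 0)
    d2w <- lp$K_f * lp$c_f * b * (b - 1) * v^(b - 2) / (4 * th^2)
  }
  d2w / w
}

# internal: scalar validation with a named error
check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("%s must be a finite numeric scalar", name), call. = FALSE)
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    stop(sprintf("%s = %g out of range %s%g, %g%s", name, x,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  invisible(x)
}
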