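#' Invasion fitness of a rare mutant allele
#'
#' Geometric growth rate of a rare mutant allele with phenotypic effect
#' `x_mut` arising in a population monomorphic for allelic effect `x_res`, at
#' a single additive autosomal locus with fully sex-concordant effects.
#' Residents express `z = 2 x_res` and mutant heterozygotes
#' `z = x_mut + x_res`, so
#' \deqn{W(x_\bullet, x) = \tfrac{1}{2}\frac{w_m(x_\bullet + x)}{w_m(2x)} +
#'   \tfrac{1}{2}\frac{w_f(x_\bullet + x)}{w_f(2x)}.}
#'
#' @param x_mut Mutant allelic value (trait units).
#' @param x_res Resident allelic value; requires `|x_mut + x_res| <= theta`
#'   and `|2 x_res| <= theta`.
#' @param lp A [landscape_pair()].
#' @return Dimensionless growth rate; equals 1 when `x_mut == x_res`.
#' @export
invasion_fitness <- function(x_mut, x_res, lp) {
  stopifnot(inherits(lp, "landscape_pair"))
  check_z(x_mut + x_res, lp)
  check_z(2 * x_res, lp)
  wm_res <- fecundity(2 * x_res, "male", lp)
  wf_res <- fecundity(2 * x_res, "female", lp)
  if (any(wm_res <= 0) || any(wf_res <= 0))
    stop("degenerate resident: fecundity is zero in one sex", call. = FALSE)
  0.5 * fecundity(x_mut + x_res, "male", lp) / wm_res +
    0.5 * fecundity(x_mut + x_res, "female", lp) / wf_res
}

#' Selection gradient on allelic value
#'
#' The derivative of invasion fitness with respect to the mutant effect,
#' evaluated at the resident:
#' \eqn{s(x) = \frac{1}{2}[w_m'(2x)/w_m(2x) + w_f'(2x)/w_f(2x)]}. Positive
#' values favor larger allelic values (evolution toward the female optimum).
#'
#' @param x Resident allelic value(s), `|2x| <= theta`.
#' @param lp A [landscape_pair()].
#' @return `s(x)`, vectorized over `x`.
#' @export
selection_gradient <- function(x, lp) {
  0.5 * (log_slope(2 * x, "male", lp) + log_slope(2 * x, "female", lp))
}

#' Disruptiveness coefficient at a resident value
#'
#' Second derivative of invasion fitness in the mutant direction,
#' \eqn{h(x) = \frac{1}{2}[w_m''(2x)/w_m(2x) + w_f''(2x)/w_f(2x)]}. At a
#' convergence-stable singular value, `h > 0` means selection is disruptive
#' and the population undergoes evolutionary branching.
#'
#' @inheritParams selection_gradient
#' @return `h(x)`, vectorized over `x`.
#' @export
disruptiveness <- function(x, lp) {
  0.5 * (log_curvature(2 * x, "male", lp) + log_curvature(2 * x, "female", lp))
}

# d s(x) / dx; convergence stability requires this < 0 at the root
gradient_slope <- function(x, lp) {
  z <- 2 * x
  gm <- log_slope(z, "male", lp); gf <- log_slope(z, "female", lp)
  hm <- log_curvature(z, "male", lp); hf <- log_curvature(z, "female", lp)
  (hm - gm^2) + (hf - gf^2)
}

#' Locate and classify singular trait values
#'
#' Finds all interior roots of the selection gradient on
#' `(-theta/2, theta/2)` by sign-bracketed root finding on a regular grid,
#' and annotates each root `x*` (singular trait value `z* = 2 x*`) with the
#' convergence criterion `s'(x*)` and the disruptiveness `h(x*)`. Each root
#' is classified as:
#'
#' * `"diversifying"`: `s'(x*) < 0` and `h(x*) > 0` (convergence-stable and
#'   disruptive: evolutionary branching);
#' * `"stabilizing"`: `s'(x*) < 0` and `h(x*) <= 0`;
#' * `"directional"`: `s'(x*) > 0` (`z*` is a repellor);
#' * `"boundary"`: a diagnostic falls within `tol` of zero, so the sign call
#'   is not made.
#'
#' When the gradient has no interior root, the result records directional
#' selection toward the favored optimum; when selection is absent
#' (`s` identically 0, e.g. `c_m = c_f = 0`), the result is flagged neutral.
#'
#' @param lp A [landscape_pair()].
#' @param n_grid Number of bracketing points (default 512).
#' @param tol Sign tolerance for regime calls, on the scale of
#'   `theta`-normalized diagnostics (default 1e-10).
#' @return An object of class `singular_analysis`: a list with `roots` (data
#'   frame of `x_star`, `z_star`, `s_prime`, `h`, `regime`), `regime` (label
#'   for the attracting dynamics), `neutral`, `favored_sign` (for rootless
#'   directional selection), and `tolerance`.
#' @export
find_singular <- function(lp, n_grid = 512, tol = 1e-10) {
  stopifnot(inherits(lp, "landscape_pair"))
  th <- lp$theta
  eps <- 1e-9 * th
  xs <- seq(-th / 2 + eps, th / 2 - eps, length.out = n_grid)
  s <- vapply(xs, selection_gradient, numeric(1), lp = lp)

  # neutral: gradient vanishes everywhere (scale-normalized)
  if (all(abs(s) * th < tol)) {
    out <- list(roots = empty_roots(), regime = "neutral", neutral = TRUE,
                favored_sign = 0, tolerance = tol)
    return(structure(out, class = "singular_analysis"))
  }

  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (is.na(s[i]) || is.na(s[i + 1])) next
    if (s[i] == 0) roots <- c(roots, xs[i])
    else if (s[i] * s[i + 1] < 0) {
      r <- stats::uniroot(function(x) selection_gradient(x, lp),
                          c(xs[i], xs[i + 1]), tol = 1e-12 * th)
      roots <- c(roots, r$root)
    }
  }
  if (s[n_grid] == 0) roots <- c(roots, xs[n_grid])
  roots <- sort(unique(roots))

  if (length(roots) == 0) {
    out <- list(roots = empty_roots(), regime = "directional", neutral = FALSE,
                favored_sign = sign(mean(s)), tolerance = tol)
    return(structure(out, class = "singular_analysis"))
  }

  sp <- vapply(roots, gradient_slope, numeric(1), lp = lp)
  h <- vapply(roots, disruptiveness, numeric(1), lp = lp)
  regime <- mapply(function(spi, hi) {
    if (abs(spi) * th^2 < tol || abs(hi) * th^2 < tol) return("boundary")
    if (spi > 0) return("directional")
    if (hi > 0) "diversifying" else "stabilizing"
  }, sp, h)
  out <- list(
    roots = data.frame(x_star = roots, z_star = 2 * roots, s_prime = sp,
                       h = h, regime = regime, stringsAsFactors = FALSE),
    regime = overall_regime(regime), neutral = FALSE,
    favored_sign = NA_real_, tolerance = tol)
  structure(out, class = "singular_analysis")
}

empty_roots <- function() {
  data.frame(x_star = numeric(0), z_star = numeric(0), s_prime = numeric(0),
             h = numeric(0), regime = character(0), stringsAsFactors = FALSE)
}

# label for the attracting dynamics given per-root labels
overall_regime <- function(per_root) {
  attracting <- per_root[per_root %in% c("diversifying", "stabilizing")]
  if (any(attracting == "diversifying")) return("diversifying")
  if (any(attracting == "stabilizing")) return("stabilizing")
  if (any(per_root == "boundary")) return("boundary")
  "directional"
}

#' @export
print.singular_analysis <- function(x, ...) {
  cat("<singular_analysis> regime:", x$regime, "\n")
  if (x$neutral) {
    cat("  selection gradient vanishes everywhere (neutral landscapes)\n")
  } else if (nrow(x$roots) == 0) {
    cat("  no interior singular value; selection favors the",
        if (x$favored_sign > 0) "female (+theta)" else "male (-theta)",
        "optimum\n")
  } else {
    print(x$roots, row.names = FALSE)
  }
  invisible(x)
}

#' Classify the selection regime of a landscape pair
#'
#' Runs [find_singular()] and reports the regime of the attracting dynamics:
#' `"diversifying"` when an attracting singular value is disruptive (both
#' that the sex-averaged fitness curvature at `z*` is positive and that it is
#' smaller than the squared strength of directional selection),
#' `"stabilizing"` when an attracting singular value is not disruptive,
#' `"directional"` when every singular value is a repellor or none exists,
#' and `"neutral"` or `"boundary"` in the corresponding degenerate cases.
#'
#' @inheritParams find_singular
#' @return A single regime string.
#' @export
classify_regime <- function(lp, n_grid = 512, tol = 1e-10) {
  find_singular(lp, n_grid = n_grid, tol = tol)$regime
}

#' Small-cost closed form for the singular trait value
#'
#' For power landscapes with shared shape `b != 1`, the singular trait value
#' admits the expansion
#' \deqn{z^* = \theta\,\frac{1 - \rho}{1 + \rho} + O(\epsilon^2), \quad
#'   \rho = (c_m/c_f)^{1/(1-b)},}
#' accurate to second order in the (small) costs. Useful as an analytic check
#' on the numeric root of the selection-gradient condition.
#'
#' @param lp A power-family [landscape_pair()] with `b_m == b_f != 1`.
#' @return Approximate `z*` in trait units.
#' @export
z_star_small_cost <- function(lp) {
  stopifnot(inherits(lp, "landscape_pair"), lp$family == "power")
  if (lp$b_m != lp$b_f)
    stop("closed form assumes a shared shape exponent b", call. = FALSE)
  b <- lp$b_m
  if (b == 1) stop("closed form undefined at b = 1", call. = FALSE)
  if (lp$c_f <= 0) stop("closed form requires c_f > 0", call. = FALSE)
  rho <- (lp$c_m / lp$c_f)^(1 / (1 - b))
  lp$theta * (1 - rho) / (1 + rho)
}

#' Critical symmetric cost for diversifying selection
#'
#' For symmetric power landscapes (`c_m = c_f = c`, `b_m = b_f = b`,
#' `K_m = K_f`) with accelerating shape `b > 1`, the singular value sits at
#' `z* = 0` and the regime flips from directional to diversifying as the
#' shared cost `c` crosses
#' \deqn{c^* = \frac{b - 1}{b\,2^{-b} + (b - 1)(1 - 2^{-b})}.}
#' For `b <= 1` no such boundary exists (selection is never diversifying on a
#' diminishing or linear symmetric landscape) and an error is raised.
#'
#' @param b Shape exponent, must be > 1.
#' @return The critical cost `c*` in (0, 1).
#' @export
critical_cost <- function(b) {
  check_scalar(b, "b", lower = 0, strict = TRUE)
  if (b <= 1)
    stop("no directional/diversifying boundary exists for b <= 1", call. = FALSE)
  (b - 1) / (b * 2^(-b) + (b - 1) * (1 - 2^(-b)))
}

#' Regime map over a grid of symmetric landscapes
#'
#' Classifies the selection regime over a `(c, b)` grid of symmetric power
#' landscapes. `method = "search"` calls [classify_regime()] (generic
#' root-finding) for every cell; `method = "symmetric"` uses the fact that
#' the singular value of a symmetric pair is `z* = 0` and evaluates the two
#' classification inequalities there directly (much faster on large grids).
#'
#' @param c_values,b_values Grid coordinates: costs in (0, 1], shapes > 0.
#' @param theta,K Passed to [symmetric_power()].
#' @param method `"symmetric"` (default) or `"search"`.
#' @return A data frame with columns `c`, `b`, `regime`.
#' @export
regime_map <- function(c_values, b_values, theta = 2, K = 1,
                       method = c("symmetric", "search")) {
  method <- match.arg(method)
  grid <- expand.grid(c = c_values, b = b_values, KEEP.OUT.ATTRS = FALSE)
  regime <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lp <- symmetric_power(grid$c[i], grid$b[i], theta = theta, K = K)
    regime[i] <- if (method == "search") classify_regime(lp)
                 else classify_symmetric(lp)
  }
  grid$regime <- regime
  grid
}

# fast path: symmetric pair, singular value known to be z* = 0
classify_symmetric <- function(lp, tol = 1e-10) {
  if (lp$c_m == 0 && lp$c_f == 0) return("neutral")
  th <- lp$theta
  sp <- gradient_slope(0, lp)
  h <- disruptiveness(0, lp)
  if (abs(sp) * th^2 < tol || abs(h) * th^2 < tol) return("boundary")
  if (sp > 0) return("directional")
  if (h > 0) "diversifying" else "stabilizing"
}
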