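# Independent oracles used by the test suite. These re-derive quantities
# through a different route than the package implementation (direct formula
# evaluation, finite differences, enumeration, or a separate simulator) so
# that agreement is informative.

# direct evaluation of the sex-specific power fecundity functions, written
# out without reusing package code
oracle_power_w <- function(z, sex, theta, K, cc, b) {
  if (sex == "male") K * (1 - cc * (1 - ((theta - z) / (2 * theta))^b))
  else K * (1 - cc * (1 - ((theta + z) / (2 * theta))^b))
}

# central finite differences of log fecundity
fd_log_slope <- function(z, sex, lp, h = 1e-6 * lp$theta) {
  (log(fecundity(z + h, sex, lp)) - log(fecundity(z - h, sex, lp))) / (2 * h)
}
fd_log_curvature <- function(z, sex, lp, h = 1e-4 * lp$theta) {
  w <- function(zz) fecundity(zz, sex, lp)
  (w(z + h) - 2 * w(z) + w(z - h)) / (h^2 * w(z))
}
fd_selection_gradient <- function(x, lp, h = 1e-6 * lp$theta) {
  (invasion_fitness(x + h, x, lp) - invasion_fitness(x - h, x, lp)) / (2 * h)
}

# brute-force sign scan: smallest symmetric cost at which the classifier
# reports diversifying selection, located by bisection on classify_regime
scan_critical_cost <- function(b, theta = 2, tol = 1e-6) {
  is_div <- function(cc)
    classify_regime(symmetric_power(cc, b, theta = theta)) == "diversifying"
  lo <- 1e-6; hi <- 1 - 1e-9
  if (!is_div(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_div(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# independent evaluation of the two diversifying-selection inequalities for a
# symmetric power pair at its singular value z* = 0: the sex-averaged log
# fitness curvature must be positive yet smaller than the summed squared log
# slopes. Derivatives are written out directly from the power form.
oracle_symmetric_regime <- function(cc, b, theta = 2) {
  if (cc == 0) return("neutral")
  w0 <- 1 - cc * (1 - 0.5^b)
  d1 <- cc * b * 0.5^(b - 1) / (2 * theta)         # |w'| at z = 0, each sex
  d2 <- cc * b * (b - 1) * 0.5^(b - 2) / (4 * theta^2) # w'' at z = 0
  curv_sum <- 2 * d2 / w0
  slope_sq <- 2 * (d1 / w0)^2
  if (curv_sum > 0 && curv_sum < slope_sq) return("diversifying")
  if (curv_sum >= slope_sq) return("directional") # z* is a repellor
  "stabilizing"
}

# deterministic two-sex single-locus recursion (L = 1, alleles +/- delta):
# genotype frequencies among juveniles after one round of fecundity-weighted
# reproduction with symmetric mutation
oracle_l1_recursion <- function(geno_freq, lp, delta, mu) {
  z <- c(-2 * delta, 0, 2 * delta) # aa, Aa, AA
  wm <- vapply(z, fecundity, numeric(1), sex = "male", lp = lp)
  wf <- vapply(z, fecundity, numeric(1), sex = "female", lp = lp)
  fm <- geno_freq * wm / sum(geno_freq * wm)
  ff <- geno_freq * wf / sum(geno_freq * wf)
  pm <- fm[3] + fm[2] / 2
  pf <- ff[3] + ff[2] / 2
  pm <- pm * (1 - mu) + (1 - pm) * mu
  pf <- pf * (1 - mu) + (1 - pf) * mu
  c(aa = (1 - pm) * (1 - pf), Aa = pm * (1 - pf) + (1 - pm) * pf,
    AA = pm * pf)
}

# pure-R mirror of one continuum-of-alleles generation, consuming RNG draws
# in the engine's documented order
mirror_coa_generation <- function(x1, x2, n_male, lp, mu, kernel_sd) {
  N <- length(x1)
  half <- lp$theta / 2
  wm <- pmax(fecundity((x1 + x2)[seq_len(n_male)], "male", lp), 0)
  wf <- pmax(fecundity((x1 + x2)[(n_male + 1):N], "female", lp), 0)
  cumm <- cumsum(wm); cumf <- cumsum(wf)
  tm <- cumm[n_male]; tf <- cumf[N - n_male]
  pick <- function(cum, total) min(which(cum >= runif(1) * total))
  draw <- function(i1, i2, idx) {
    al <- if (runif(1) < 0.5) i1[idx] else i2[idx]
    if (runif(1) < mu) al <- al + rnorm(1) * kernel_sd
    min(max(al, -half), half)
  }
  y1 <- y2 <- numeric(N)
  for (i in seq_len(N)) {
    dad <- pick(cumm, tm)
    y1[i] <- draw(x1, x2, dad)
    mom <- n_male + pick(cumf, tf)
    y2[i] <- draw(x1, x2, mom)
  }
  list(x1 = y1, x2 = y2)
}

# independent scalar-trait drift simulator (neutral continuum-of-alleles):
# uniform parent choice within each sex, same mutation kernel and clamping
drift_sim_variance <- function(n_per_sex, mu, kernel_sd, half, generations,
                               burn_in) {
  N <- 2 * n_per_sex
  x <- matrix(0, N, 2)
  vs <- numeric(generations - burn_in)
  for (g in seq_len(generations)) {
    dads <- sample.int(n_per_sex, N, replace = TRUE)
    moms <- n_per_sex + sample.int(n_per_sex, N, replace = TRUE)
    from_dad <- x[cbind(dads, sample(1:2, N, replace = TRUE))]
    from_mom <- x[cbind(moms, sample(1:2, N, replace = TRUE))]
    y <- cbind(from_dad, from_mom)
    mut <- matrix(runif(2 * N) < mu, N, 2)
    y[mut] <- y[mut] + rnorm(sum(mut)) * kernel_sd
    y[y > half] <- half; y[y < -half] <- -half
    x <- y
    if (g > burn_in) vs[g - burn_in] <- var(c(x))
  }
  mean(vs)
}

# toy parentage table builder
toy_parentage <- function(sex, offspring, dose, fecundity = NULL) {
  dose <- as.matrix(dose)
  colnames(dose) <- paste0("dose_", seq_len(ncol(dose)))
  df <- data.frame(sex = sex, offspring = offspring,
                   fecundity = fecundity %||% rep(1, length(sex)))
  cbind(df, as.data.frame(dose))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
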