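#' Configuration for a continuum-of-alleles run
#'
#' The continuum-of-alleles model follows a single additive autosomal locus
#' whose allelic values mutate by small random steps, in a population of
#' `n_per_sex` adult males and `n_per_sex` adult females. Each generation,
#' every offspring draws a father with probability proportional to
#' `w_m(z)` and a mother proportional to `w_f(z)`; each transmitted allele
#' mutates with probability `mu` by a zero-mean normal step of standard
#' deviation `kernel_sd`, and allelic values are clamped to
#' `[-theta/2, theta/2]` so phenotypes stay on the interval the landscapes
#' are defined on.
#'
#' @param lp A [landscape_pair()].
#' @param n_per_sex Adults per sex (>= 2); default 500.
#' @param mu Per-allele-copy per-generation mutation probability; default
#'   1e-3.
#' @param kernel_sd Mutation step standard deviation in trait units; default
#'   `0.02 * theta` (small-effect mutations, as assumed by the invasion
#'   analysis).
#' @param generations Number of generations to run.
#' @param init_x Initial allelic value, `|init_x| <= theta/2`; the population
#'   starts monomorphic and homozygous for it.
#' @param sample_every Sampling cadence in generations.
#' @param sample_size Alleles (and phenotypes) sampled per record; default
#'   10.
#' @return An object of class `coa_config`.
#' @export
coa_config <- function(lp, n_per_sex = 500, mu = 1e-3, kernel_sd = NULL,
                       generations = 10000, init_x = 0,
                       sample_every = 100, sample_size = 10) {
  stopifnot(inherits(lp, "landscape_pair"))
  if (is.null(kernel_sd)) kernel_sd <- 0.02 * lp$theta
  check_scalar(n_per_sex, "n_per_sex", lower = 2)
  check_scalar(mu, "mu", lower = 0, upper = 1)
  check_scalar(kernel_sd, "kernel_sd", lower = 0, strict = TRUE)
  check_scalar(generations, "generations", lower = 1)
  check_scalar(init_x, "init_x", lower = -lp$theta / 2, upper = lp$theta / 2)
  check_scalar(sample_every, "sample_every", lower = 1)
  check_scalar(sample_size, "sample_size", lower = 1)
  structure(list(lp = lp, n_per_sex = as.integer(n_per_sex), mu = mu,
                 kernel_sd = kernel_sd, generations = as.integer(generations),
                 init_x = init_x, sample_every = as.integer(sample_every),
                 sample_size = as.integer(sample_size)),
            class = "coa_config")
}

#' Continuum-of-alleles population state
#'
#' A population of diploid individuals at a single additive locus. Males
#' occupy the first `n_per_sex` rows by convention.
#'
#' @param x1,x2 Numeric vectors of allelic values (first and second copy),
#'   each within `[-theta/2, theta/2]`.
#' @param n_per_sex Number of males (= number of females); `length(x1)` must
#'   equal `2 * n_per_sex`.
#' @param lp The [landscape_pair()] the values must respect.
#' @param generation Generation counter (default 0).
#' @return An object of class `coa_state`.
#' @export
coa_state <- function(x1, x2, n_per_sex, lp, generation = 0) {
  stopifnot(length(x1) == length(x2), length(x1) == 2 * n_per_sex)
  half <- lp$theta / 2
  if (any(abs(c(x1, x2)) > half + 1e-12))
    stop("allelic values must lie in [-theta/2, theta/2]", call. = FALSE)
  structure(list(x1 = as.numeric(x1), x2 = as.numeric(x2),
                 n_per_sex = as.integer(n_per_sex),
                 sex = rep(c("M", "F"), each = n_per_sex),
                 generation = as.integer(generation)),
            class = "coa_state")
}

#' Advance a continuum-of-alleles population by one or more generations
#'
#' @param state A [coa_state()].
#' @param cfg A [coa_config()].
#' @param n_gens Number of generations to advance (default 1).
#' @return The new `coa_state`, with attributes `mean_wm` and `mean_wf`
#'   giving the per-generation mean fecundities over the advanced span.
#' @export
step_coa <- function(state, cfg, n_gens = 1) {
  stopifnot(inherits(state, "coa_state"), inherits(cfg, "coa_config"))
  res <- .coa_chunk(state$x1, state$x2, state$n_per_sex, as.integer(n_gens),
                    cfg$mu, cfg$kernel_sd, unclass(cfg$lp))
  out <- coa_state(res$x1, res$x2, state$n_per_sex, cfg$lp,
                   generation = state$generation + n_gens)
  attr(out, "mean_wm") <- res$mean_wm
  attr(out, "mean_wf") <- res$mean_wf
  out
}

#' Run a continuum-of-alleles simulation
#'
#' Runs `cfg$generations` generations from a monomorphic start at
#' `cfg$init_x`, recording on the cadence `cfg$sample_every`: a random sample
#' of allelic values, a random sample of phenotypes with sexes, and the
#' population-level fecundity variance
#' \eqn{\mathrm{Var}[w_m(z)]/2 + \mathrm{Var}[w_f(z)]/2}. The run is
#' deterministic given the RNG state (use `set.seed()` before calling, or
#' pass `seed`).
#'
#' @param cfg A [coa_config()].
#' @param seed Optional integer seed applied with `set.seed()`.
#' @return An object of class `coa_result`: list with `allele_samples` (data
#'   frame `generation`, `value`), `pheno_samples` (data frame `generation`,
#'   `sex`, `z`), `series` (data frame at the sampling cadence: `generation`,
#'   `mean_wm`, `mean_wf`, `fec_var`, `pheno_var`), `mean_fecundity` (full
#'   per-generation mean fecundities by sex), `final` (`coa_state`), and
#'   `config`.
#' @export
run_coa <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "coa_config"))
  if (!is.null(seed)) set.seed(seed)
  lp <- cfg$lp
  n <- cfg$n_per_sex
  state <- coa_state(rep(cfg$init_x, 2 * n), rep(cfg$init_x, 2 * n), n, lp)

  breaks <- chunk_sizes(cfg$generations, cfg$sample_every)
  gens_at <- cumsum(breaks)
  n_rec <- length(breaks)
  allele_samples <- vector("list", n_rec)
  pheno_samples <- vector("list", n_rec)
  mean_wm_all <- numeric(cfg$generations)
  mean_wf_all <- numeric(cfg$generations)
  series <- data.frame(generation = gens_at, mean_wm = NA_real_,
                       mean_wf = NA_real_, fec_var = NA_real_,
                       pheno_var = NA_real_)
  for (i in seq_len(n_rec)) {
    state <- step_coa(state, cfg, breaks[i])
    mwm <- attr(state, "mean_wm"); mwf <- attr(state, "mean_wf")
    span <- (gens_at[i] - breaks[i] + 1):gens_at[i]
    mean_wm_all[span] <- mwm
    mean_wf_all[span] <- mwf
    series$mean_wm[i] <- mwm[length(mwm)]
    series$mean_wf[i] <- mwf[length(mwf)]
    z <- state$x1 + state$x2
    zm <- z[seq_len(n)]; zf <- z[n + seq_len(n)]
    series$fec_var[i] <- stats::var(fecundity(zm, "male", lp)) / 2 +
      stats::var(fecundity(zf, "female", lp)) / 2
    series$pheno_var[i] <- stats::var(z)
    pool <- c(state$x1, state$x2)
    allele_samples[[i]] <- data.frame(
      generation = gens_at[i],
      value = pool[sample.int(length(pool), min(cfg$sample_size, length(pool)))])
    idx <- sample.int(2 * n, min(cfg$sample_size, 2 * n))
    pheno_samples[[i]] <- data.frame(generation = gens_at[i],
                                     sex = state$sex[idx], z = z[idx])
  }
  structure(list(allele_samples = do.call(rbind, allele_samples),
                 pheno_samples = do.call(rbind, pheno_samples),
                 series = series,
                 mean_fecundity = data.frame(generation = seq_len(cfg$generations),
                                             mean_wm = mean_wm_all,
                                             mean_wf = mean_wf_all),
                 final = state, config = cfg),
            class = "coa_result")
}

chunk_sizes <- function(total, every) {
  n_full <- total %/% every
  sizes <- rep(every, n_full)
  if (total %% every > 0) sizes <- c(sizes, total %% every)
  sizes
}

#' Gap-based one-dimensional clustering
#'
#' Sorts the values and splits them wherever the gap between consecutive
#' values exceeds `gap`. Operationalizes counting of phenotypic "types" in a
#' branched population (e.g. male-adapted, female-adapted, and intermediate
#' heterozygote clusters).
#'
#' @param values Non-empty numeric vector (phenotypes or allelic values).
#' @param gap Minimum between-cluster gap, trait units (> 0).
#' @return A list with `n` (cluster count), `means`, and `sizes`.
#' @export
detect_clusters <- function(values, gap) {
  stopifnot(length(values) > 0, is.numeric(values), gap > 0)
  v <- sort(values)
  id <- cumsum(c(1, diff(v) > gap))
  list(n = max(id),
       means = as.numeric(tapply(v, id, mean)),
       sizes = as.integer(table(id)))
}

#' @export
print.coa_result <- function(x, ...) {
  st <- x$final
  cat("<coa_result>", st$generation, "generations, n_per_sex =",
      st$n_per_sex, "\n")
  cl <- detect_clusters(st$x1 + st$x2, gap = x$config$lp$theta / 4)
  cat("  final phenotype clusters (gap theta/4):", cl$n,
      " means:", paste(signif(cl$means, 3), collapse = ", "), "\n")
  invisible(x)
}
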