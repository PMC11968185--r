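#' Expected heterozygosity
#'
#' `2 p (1 - p)` for allele frequency `p`, vectorized.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @return Expected heterozygosity in `[0, 0.5]`.
#' @export
expected_heterozygosity <- function(p) {
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  2 * p * (1 - p)
}

#' Neutral heterozygosity baseline
#'
#' Monte-Carlo estimate of the stationary mean expected heterozygosity per
#' locus for the same architecture and demography but with selection turned
#' off (`c_m = c_f = 0`), together with the symmetric two-allele diffusion
#' prediction `4 N mu / (8 N mu + 1)` (stationary `Beta(4Nmu, 4Nmu)` allele
#' frequency).
#'
#' @param arch An [architecture()].
#' @param n Population size.
#' @param generations Generations per replicate run.
#' @param n_reps Number of replicate runs (>= 2, for a CI).
#' @param burn_in,sample_every Passed to [run_polygenic()].
#' @param seed Optional seed.
#' @return A list with `mean`, `se`, `ci` (95% normal CI across replicates),
#'   `closed_form`, and `per_rep`.
#' @export
neutral_baseline <- function(arch, n, generations, n_reps = 4,
                             burn_in = NULL, sample_every = 100,
                             seed = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2 to form a CI", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lp0 <- landscape_pair("power", theta = arch$theta, c_m = 0, c_f = 0,
                        b_m = 1, b_f = 1)
  per_rep <- vapply(seq_len(n_reps), function(i) {
    res <- run_polygenic(arch, lp0, n = n, generations = generations,
                         burn_in = burn_in, sample_every = sample_every,
                         pheno_sample_size = 2)
    mean(res$het[stationary_records(res), , drop = FALSE])
  }, numeric(1))
  m <- mean(per_rep)
  se <- stats::sd(per_rep) / sqrt(n_reps)
  list(mean = m, se = se, ci = m + c(-1.96, 1.96) * se,
       closed_form = 4 * n * arch$mu / (8 * n * arch$mu + 1),
       per_rep = per_rep)
}

# weighted per-sex allele frequencies among successful parents
parent_freqs <- function(parentage, weighted = TRUE) {
  dose_cols <- grep("^dose_", names(parentage))
  if (length(dose_cols) == 0) stop("no dose_* columns in parentage table",
                                   call. = FALSE)
  out <- lapply(c("M", "F"), function(s) {
    rows <- parentage$sex == s
    w <- if (weighted) parentage$offspring[rows] else
      as.numeric(parentage$offspring[rows] > 0)
    tot <- sum(w)
    if (tot <= 0)
      stop(sprintf("no successful parents of sex %s: FST undefined", s),
           call. = FALSE)
    colSums(parentage[rows, dose_cols, drop = FALSE] * w) / (2 * tot)
  })
  names(out) <- c("M", "F")
  out
}

#' Between-sex FST among successful parents
#'
#' Allele-frequency differentiation between the fathers and mothers of one
#' generation, the statistic used to screen for sexually antagonistic loci.
#' Parental allele frequencies in each sex are weighted by the number of
#' recruited offspring (set `weighted = FALSE` to use the unweighted set of
#' parents with at least one offspring). The estimator is Nei's
#' \eqn{(H_T - H_S)/H_T} with equal sex weights: `H_S` is the mean of the
#' within-sex expected heterozygosities and `H_T` uses the mean of the two
#' sex-specific frequencies. Loci with `H_T = 0` return `NA` (not 0).
#'
#' @param parentage A parentage table: data frame with columns `sex`
#'   (`"M"`/`"F"`), `offspring`, and `dose_1 ... dose_L` (copies of allele
#'   `A`), as produced by [step_generation()] or [run_polygenic()].
#' @param weighted Weight parents by offspring number (default `TRUE`).
#' @return Numeric vector of per-locus FST in `[0, 1]` (or `NA`).
#' @export
between_sex_fst <- function(parentage, weighted = TRUE) {
  pf <- parent_freqs(parentage, weighted = weighted)
  pbar <- (pf$M + pf$F) / 2
  ht <- expected_heterozygosity(pbar)
  hs <- (expected_heterozygosity(pf$M) + expected_heterozygosity(pf$F)) / 2
  fst <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  unname(fst)
}

#' Sex-specific fitness-association slopes
#'
#' Per-locus ordinary least-squares slopes of reproductive success (number
#' of recruited offspring) on within-individual frequency of allele `A`
#' (dose / 2, coded 0, 1/2, 1), fitted separately in males
#' (\eqn{\beta_{m,k}}) and females (\eqn{\beta_{f,k}}), with the absolute
#' sex difference \eqn{|\beta_{m,k} - \beta_{f,k}|} — the GWAS-style screen
#' for sexually antagonistic loci. A slope is `NA` when fewer than two
#' distinct dose values are present in that sex (constant regressor).
#'
#' @inheritParams between_sex_fst
#' @return Data frame with columns `locus`, `beta_m`, `beta_f`,
#'   `beta_absdiff`.
#' @export
fitness_association <- function(parentage) {
  dose_cols <- grep("^dose_", names(parentage))
  L <- length(dose_cols)
  slope <- function(x, y) {
    if (length(unique(x)) < 2) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }
  bm <- bf <- numeric(L)
  m <- parentage$sex == "M"
  for (k in seq_len(L)) {
    x <- parentage[[dose_cols[k]]] / 2
    bm[k] <- slope(x[m], parentage$offspring[m])
    bf[k] <- slope(x[!m], parentage$offspring[!m])
  }
  data.frame(locus = seq_len(L), beta_m = bm, beta_f = bf,
             beta_absdiff = abs(bm - bf))
}

#' Permuted-sex control for signature statistics
#'
#' Returns a copy of the parentage table with the sex of each individual
#' randomly reassigned (labels permuted), the control used to calibrate
#' [between_sex_fst()] and [fitness_association()] against their
#' finite-sample null.
#'
#' @inheritParams between_sex_fst
#' @return The parentage table with permuted `sex`.
#' @export
permute_sex <- function(parentage) {
  parentage$sex <- sample(parentage$sex)
  parentage
}

#' Sex-averaged fecundity load
#'
#' `1 - (mean(w_m)/K_m + mean(w_f)/K_f) / 2`: the reduction in sex-averaged
#' mean fecundity relative to each sex's maximum, caused by unresolved
#' sexual antagonism.
#'
#' @param mean_wm,mean_wf Mean male and female fecundities (scalars or
#'   equal-length vectors, e.g. per-generation series).
#' @param lp The [landscape_pair()] providing `K_m`, `K_f`.
#' @return Load in `[0, 1]`, vectorized.
#' @export
sex_load <- function(mean_wm, mean_wf, lp) {
  stopifnot(inherits(lp, "landscape_pair"))
  1 - 0.5 * (mean_wm / lp$K_m + mean_wf / lp$K_f)
}

#' Count stably balanced loci
#'
#' Number of loci whose expected heterozygosity stays at or above
#' `het_threshold` in every sampled generation of the trailing window — the
#' operational definition of a stably maintained balanced polymorphism
#' (e.g. a "remainder" locus under stabilizing selection).
#'
#' @param het A records x L heterozygosity matrix (e.g. `res$het` from
#'   [run_polygenic()]).
#' @param het_threshold Minimum heterozygosity; default 0.25.
#' @param window Trailing fraction of records to examine (default 0.25) or,
#'   if >= 1, a count of trailing records.
#' @return Integer count of balanced loci.
#' @export
count_balanced_loci <- function(het, het_threshold = 0.25, window = 0.25) {
  het <- as.matrix(het)
  n_rec <- nrow(het)
  k <- if (window < 1) max(1L, ceiling(window * n_rec)) else
    min(as.integer(window), n_rec)
  tail_rows <- (n_rec - k + 1):n_rec
  sum(apply(het[tail_rows, , drop = FALSE] >= het_threshold, 2, all))
}

#' Fecundity variance across the sexes
#'
#' `Var[w_m(z)]/2 + Var[w_f(z)]/2`, with the male variance taken over male
#' phenotypes and the female variance over female phenotypes. Rises sharply
#' when diversifying selection establishes a polymorphism.
#'
#' @param z_m,z_f Phenotypes of males and of females.
#' @param lp A [landscape_pair()].
#' @return Non-negative scalar.
#' @export
fecundity_variance <- function(z_m, z_f, lp) {
  stats::var(fecundity(z_m, "male", lp)) / 2 +
    stats::var(fecundity(z_f, "female", lp)) / 2
}

#' Proportion of loci with common minor alleles
#'
#' Fraction of loci whose minor allele frequency exceeds `threshold`.
#'
#' @param freqs Per-locus allele frequencies.
#' @param threshold MAF threshold; default 0.05.
#' @return Proportion in `[0, 1]`.
#' @export
maf_proportion <- function(freqs, threshold = 0.05) {
  if (any(freqs < -1e-12 | freqs > 1 + 1e-12, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  mean(pmin(freqs, 1 - freqs) > threshold, na.rm = TRUE)
}

#' Summary statistics of a polygenic run
#'
#' Convenience wrapper assembling the scalar summaries of a
#' [run_polygenic()] result over its stationary records: mean
#' heterozygosity, mean between-sex FST (when parentage was recorded), sex
#' load, phenotypic and fecundity variance, MAF proportion, and the number
#' of balanced loci.
#'
#' @param res A `polygenic_result`.
#' @param het_threshold,window Passed to [count_balanced_loci()].
#' @param maf_threshold Passed to [maf_proportion()].
#' @return A list of scalar summaries and per-locus vectors.
#' @export
summarize_run <- function(res, het_threshold = 0.25, window = 0.25,
                          maf_threshold = 0.05) {
  keep <- stationary_records(res)
  het_st <- res$het[keep, , drop = FALSE]
  freq_st <- res$freq[keep, , drop = FALSE]
  fst <- NULL
  if (length(res$parentage) > 0) {
    tabs <- res$parentage[names(res$parentage) %in%
                            as.character(res$generations[keep])]
    if (length(tabs) == 0) tabs <- res$parentage
    fst_mat <- vapply(tabs, between_sex_fst, numeric(res$arch$L))
    fst <- rowMeans(as.matrix(fst_mat), na.rm = TRUE)
  }
  list(het_per_locus = colMeans(het_st),
       het_mean = mean(het_st),
       fst_per_locus = fst,
       fst_mean = if (!is.null(fst)) mean(fst, na.rm = TRUE) else NA_real_,
       sex_load = mean(sex_load(res$series$mean_wm[keep],
                                res$series$mean_wf[keep], res$lp)),
       pheno_var = mean(res$series$pheno_var[keep]),
       fec_var = mean(res$series$fec_var[keep]),
       maf_prop = maf_proportion(colMeans(freq_st), maf_threshold),
       n_balanced = count_balanced_loci(res$het, het_threshold, window))
}
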