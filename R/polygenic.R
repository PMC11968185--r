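#' Genetic architecture of a polygenic diallelic trait
#'
#' Describes `L` diallelic loci with additive, fully sex-concordant effects.
#' At locus `k` the trait-increasing allele `A_k` contributes `+delta_k` and
#' `a_k` contributes `-delta_k` per copy, so the phenotype of a diploid
#' genotype is the sum of its `2L` allelic effects and ranges over
#' `[-theta, theta]` with `theta = 2 * sum(delta)`. The male and female
#' optima are taken to coincide with the phenotypic extremes (`-theta` and
#' `+theta`), so any landscape paired with an architecture must have
#' `lp$theta == arch$theta`.
#'
#' Inheritance modes:
#' * `"autosome"`: ordinary diploid transmission; offspring sex assigned to
#'   fill equal numbers per sex.
#' * `"x_hemizygous"`: loci sit on the non-recombining X; males carry a
#'   single expressed copy (inherited from the mother) whose alleles each
#'   count twice in the phenotype, keeping both sexes on the same trait
#'   scale.
#' * `"par"`: loci sit in the pseudoautosomal region, linked to the
#'   sex-determining region (SDR) with per-meiosis recombination probability
#'   `r_sdr`; the paternal gamete's SDR allele (X or Y) determines offspring
#'   sex.
#'
#' @param L Locus count (>= 1).
#' @param delta Per-locus effect sizes (`delta_k > 0`, trait units); a scalar
#'   is recycled to length `L`. Default 1.
#' @param mu Per-allele per-generation flip probability (A <-> a); default
#'   5e-6.
#' @param r_adjacent Recombination probability between adjacent loci, in
#'   `[0, 0.5]`; default 0.5 (free recombination).
#' @param mode Inheritance mode; see Details.
#' @param r_sdr Recombination probability between the SDR and the locus
#'   block (`"par"` mode only), in `[0, 0.5]`; default 0.5.
#' @return An object of class `architecture` with derived field
#'   `theta = 2 * sum(delta)`.
#' @export
architecture <- function(L, delta = 1, mu = 5e-6, r_adjacent = 0.5,
                         mode = c("autosome", "x_hemizygous", "par"),
                         r_sdr = 0.5) {
  mode <- match.arg(mode)
  check_scalar(L, "L", lower = 1)
  L <- as.integer(L)
  if (length(delta) == 1) delta <- rep(delta, L)
  if (length(delta) != L || any(!is.finite(delta)) || any(delta <= 0))
    stop("delta must be a positive vector of length L", call. = FALSE)
  check_scalar(mu, "mu", lower = 0, upper = 1)
  check_scalar(r_adjacent, "r_adjacent", lower = 0, upper = 0.5)
  check_scalar(r_sdr, "r_sdr", lower = 0, upper = 0.5)
  structure(list(L = L, delta = as.numeric(delta), mu = mu,
                 r_adjacent = r_adjacent, mode = mode, r_sdr = r_sdr,
                 theta = 2 * sum(delta)),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("<architecture>", x$L, "loci, mode:", x$mode, "\n")
  cat("  delta:", paste(signif(x$delta, 3), collapse = " "),
      " theta = 2*sum(delta) =", x$theta, "\n")
  cat("  mu:", x$mu, " r_adjacent:", x$r_adjacent,
      if (x$mode == "par") paste(" r_sdr:", x$r_sdr) else "", "\n")
  invisible(x)
}

#' Polygenic population state
#'
#' Holds the genotypes of `N` diploid individuals at the `L` loci of an
#' [architecture()]. Haplotypes are 0/1 matrices (1 = trait-increasing allele
#' `A`); `h1` is the paternally inherited homolog and `h2` the maternally
#' inherited one. Males occupy the first `N/2` rows. In `"x_hemizygous"` mode
#' a male's single X is stored mirrored in both homolog slots; in `"par"`
#' mode `sdr1`/`sdr2` give each homolog's sex-determining allele (0 = X,
#' 1 = Y), with males carrying exactly one Y (paternal side at birth).
#'
#' @param h1,h2 Integer 0/1 matrices, `N x L`.
#' @param arch The [architecture()].
#' @param sdr1,sdr2 Optional integer vectors of SDR alleles (`"par"` mode).
#' @param generation Generation counter.
#' @return An object of class `population_state`.
#' @export
population_state <- function(h1, h2, arch, sdr1 = NULL, sdr2 = NULL,
                             generation = 0) {
  stopifnot(inherits(arch, "architecture"))
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  N <- nrow(h1)
  if (N < 2 || N %% 2 != 0)
    stop("population size must be even and >= 2", call. = FALSE)
  if (ncol(h1) != arch$L || !identical(dim(h1), dim(h2)))
    stop("haplotype matrices must be N x L", call. = FALSE)
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
    stop("haplotype entries must be 0 or 1", call. = FALSE)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  n_male <- N %/% 2L
  if (arch$mode == "par") {
    if (is.null(sdr1) || is.null(sdr2))
      stop("par mode requires sdr1 and sdr2", call. = FALSE)
    sdr1 <- as.integer(sdr1); sdr2 <- as.integer(sdr2)
    ym <- sdr1[seq_len(n_male)] + sdr2[seq_len(n_male)]
    yf <- sdr1[n_male + seq_len(n_male)] + sdr2[n_male + seq_len(n_male)]
    if (any(ym != 1L) || any(yf != 0L))
      stop("males must carry exactly one Y and females none", call. = FALSE)
  } else {
    sdr1 <- integer(N); sdr2 <- integer(N)
    if (arch$mode == "x_hemizygous" &&
        !identical(h1[seq_len(n_male), , drop = FALSE],
                   h2[seq_len(n_male), , drop = FALSE]))
      stop("x_hemizygous mode stores a male's single X mirrored in h1 and h2",
           call. = FALSE)
  }
  structure(list(h1 = h1, h2 = h2, sdr1 = sdr1, sdr2 = sdr2,
                 n_male = n_male,
                 sex = rep(c("M", "F"), each = n_male),
                 generation = as.integer(generation)),
            class = "population_state")
}

#' Random initial population
#'
#' Draws haplotypes with independent allele frequency `p0` at every locus
#' (default 0.5, maximal standing variation). In `"x_hemizygous"` mode male
#' X's are mirrored; in `"par"` mode males start with the Y on the paternal
#' homolog.
#'
#' @param n Total population size (even; half male, half female).
#' @param arch An [architecture()].
#' @param p0 Initial frequency of allele `A` at each locus.
#' @return A [population_state()].
#' @export
init_population <- function(n, arch, p0 = 0.5) {
  stopifnot(inherits(arch, "architecture"))
  check_scalar(n, "n", lower = 2)
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("n must be even", call. = FALSE)
  check_scalar(p0, "p0", lower = 0, upper = 1)
  L <- arch$L
  h1 <- matrix(as.integer(stats::runif(n * L) < p0), n, L)
  h2 <- matrix(as.integer(stats::runif(n * L) < p0), n, L)
  n_male <- n %/% 2L
  sdr1 <- sdr2 <- NULL
  if (arch$mode == "x_hemizygous") {
    h1[seq_len(n_male), ] <- h2[seq_len(n_male), ]
  } else if (arch$mode == "par") {
    sdr1 <- c(rep(1L, n_male), rep(0L, n_male))
    sdr2 <- integer(n)
  }
  population_state(h1, h2, arch, sdr1 = sdr1, sdr2 = sdr2)
}

#' Phenotypes of a population
#'
#' Applies the additive genotype-phenotype map: each allele contributes
#' `+delta_k` (allele `A`) or `-delta_k` (allele `a`), summed over both
#' homologs and all loci. In `"x_hemizygous"` mode males carry mirrored
#' copies, so their single X allele counts twice, keeping phenotypes on
#' `[-theta, theta]` in both sexes.
#'
#' @param state A [population_state()].
#' @param arch The matching [architecture()].
#' @return Numeric vector of phenotypes `z`, one per individual.
#' @export
phenotype <- function(state, arch) {
  stopifnot(inherits(state, "population_state"), inherits(arch, "architecture"))
  if (ncol(state$h1) != arch$L)
    stop("state does not conform to architecture: wrong locus count",
         call. = FALSE)
  drop((state$h1 + state$h2 - 1) %*% (2 * arch$delta))
}

#' Generate one gamete from a parent genotype
#'
#' Reference R implementation of meiosis used in tests and small examples
#' (the simulation engine applies the identical draw order in compiled
#' code): a uniformly chosen start homolog, a crossover between the SDR and
#' the locus block with probability `r_sdr` (PAR mode), an independent
#' crossover in each adjacent-locus interval with probability `r_adjacent`,
#' then a mutation flip of each transmitted allele with probability `mu`.
#'
#' @param h1,h2 The parent's two haplotypes (0/1 vectors of length `L`).
#' @param arch An [architecture()].
#' @param sdr Length-2 vector of the parent's SDR alleles (`"par"` mode).
#' @return Integer vector of `L` transmitted alleles; in `"par"` mode the
#'   transmitted SDR allele is attached as attribute `"sdr"`.
#' @export
make_gamete <- function(h1, h2, arch, sdr = c(0L, 0L)) {
  stopifnot(inherits(arch, "architecture"))
  L <- arch$L
  cur <- if (stats::runif(1) < 0.5) 1L else 2L
  out_sdr <- NULL
  if (arch$mode == "par") {
    out_sdr <- sdr[cur]
    if (stats::runif(1) < arch$r_sdr) cur <- 3L - cur
  }
  g <- integer(L)
  for (k in seq_len(L)) {
    if (k > 1 && stats::runif(1) < arch$r_adjacent) cur <- 3L - cur
    g[k] <- if (cur == 1L) h1[k] else h2[k]
  }
  flip <- stats::runif(L) < arch$mu
  g[flip] <- 1L - g[flip]
  if (!is.null(out_sdr)) attr(g, "sdr") <- out_sdr
  g
}

#' Advance a polygenic population by one or more generations
#'
#' Runs the two-sex life cycle: every offspring draws a father with
#' probability proportional to `w_m(z)` and a mother proportional to
#' `w_f(z)`; gametes are formed by [make_gamete()]'s process; offspring sex
#' is assigned to fill `N/2` per sex (autosome and X modes) or determined by
#' the paternal gamete's SDR allele with quota rejection (`"par"` mode).
#'
#' @param state A [population_state()].
#' @param arch An [architecture()].
#' @param lp A [landscape_pair()] with `lp$theta == arch$theta`.
#' @param n_gens Generations to advance (default 1).
#' @param record_parentage If `TRUE`, attach a parentage table (attribute
#'   `"parentage"`) for the adults present on entry: their sex, fecundity,
#'   number of recruited offspring in the first advanced generation, and
#'   per-locus allele dose. See [between_sex_fst()].
#' @return The new `population_state`; attributes `mean_wm`/`mean_wf` hold
#'   per-generation mean fecundities over the span.
#' @export
step_generation <- function(state, arch, lp, n_gens = 1,
                            record_parentage = FALSE) {
  stopifnot(inherits(state, "population_state"),
            inherits(arch, "architecture"),
            inherits(lp, "landscape_pair"))
  if (abs(lp$theta - arch$theta) > 1e-9)
    stop("landscape theta must equal the architecture's 2*sum(delta)",
         call. = FALSE)
  entry <- state
  res <- .wf_chunk(state$h1, state$h2, state$sdr1, state$sdr2, state$n_male,
                   as.integer(n_gens), unclass(arch), unclass(lp),
                   isTRUE(record_parentage))
  out <- population_state(res$h1, res$h2, arch,
                          sdr1 = if (arch$mode == "par") res$sdr1,
                          sdr2 = if (arch$mode == "par") res$sdr2,
                          generation = state$generation + n_gens)
  attr(out, "mean_wm") <- res$mean_wm
  attr(out, "mean_wf") <- res$mean_wf
  if (isTRUE(record_parentage))
    attr(out, "parentage") <- parentage_table(entry, arch,
                                              offspring = res$entry_count,
                                              fecundity = res$entry_w)
  out
}

# assemble the successful-parents table consumed by sumstats
parentage_table <- function(state, arch, offspring, fecundity) {
  dose <- state$h1 + state$h2
  colnames(dose) <- paste0("dose_", seq_len(arch$L))
  df <- data.frame(sex = state$sex, fecundity = fecundity,
                   offspring = as.integer(offspring),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(dose))
}

#' Run a polygenic two-sex Wright-Fisher simulation
#'
#' Forward simulation of an `L`-locus diallelic trait under sex-specific
#' fecundity selection. Records, on the cadence `sample_every`: per-locus
#' allele frequencies and expected heterozygosities, a phenotype sample by
#' sex, population fecundity variance, and (optionally) parentage tables for
#' the genomic-signature statistics. Deterministic given the seed.
#'
#' @param arch An [architecture()].
#' @param lp A [landscape_pair()] with `lp$theta == arch$theta`.
#' @param n Total population size (even); default 2000.
#' @param generations Number of generations.
#' @param burn_in Generations discarded by downstream stationary summaries
#'   (recorded but flagged); default `generations %/% 2`.
#' @param sample_every Recording cadence in generations; default 100.
#' @param pheno_sample_size Individuals sampled per sex per record for the
#'   phenotype sample; default 100.
#' @param parentage `"none"`, `"last"` (final record only), or `"all"`
#'   (every record): whether to keep parentage tables.
#' @param init_freq Initial allele frequency at every locus; default 0.5.
#' @param seed Optional integer seed applied with `set.seed()`.
#' @return An object of class `polygenic_result`: list with `generations`
#'   (sampled generations), `freq` (records x L allele-frequency matrix),
#'   `het` (records x L expected heterozygosity), `pheno_samples` (data
#'   frame `generation`, `sex`, `z`), `series` (per-record `mean_wm`,
#'   `mean_wf`, `fec_var`, `pheno_var`), `parentage` (list of tables, named
#'   by generation), `final` (`population_state`), `burn_in`, `arch`, `lp`,
#'   and `n`.
#' @export
run_polygenic <- function(arch, lp, n = 2000, generations = 10000,
                          burn_in = NULL, sample_every = 100,
                          pheno_sample_size = 100,
                          parentage = c("none", "last", "all"),
                          init_freq = 0.5, seed = NULL) {
  parentage <- match.arg(parentage)
  stopifnot(inherits(arch, "architecture"), inherits(lp, "landscape_pair"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- generations %/% 2
  state <- init_population(n, arch, p0 = init_freq)

  breaks <- chunk_sizes(generations, sample_every)
  gens_at <- cumsum(breaks)
  n_rec <- length(breaks)
  L <- arch$L
  freq <- matrix(NA_real_, n_rec, L)
  series <- data.frame(generation = gens_at, mean_wm = NA_real_,
                       mean_wf = NA_real_, fec_var = NA_real_,
                       pheno_var = NA_real_)
  pheno_samples <- vector("list", n_rec)
  partabs <- list()
  # the parentage table for the adults sampled at record j requires the next
  # generation to be produced, so it is collected during chunk j + 1 (or by
  # one extra generation after the final record)
  for (i in seq_len(n_rec)) {
    close_prev <- parentage == "all" && i > 1
    state <- step_generation(state, arch, lp, breaks[i],
                             record_parentage = close_prev)
    if (close_prev)
      partabs[[as.character(gens_at[i - 1])]] <- attr(state, "parentage")
    mwm <- attr(state, "mean_wm"); mwf <- attr(state, "mean_wf")
    series$mean_wm[i] <- mwm[length(mwm)]
    series$mean_wf[i] <- mwf[length(mwf)]
    freq[i, ] <- colMeans((state$h1 + state$h2) / 2)
    z <- phenotype(state, arch)
    n_male <- state$n_male
    zm <- z[seq_len(n_male)]; zf <- z[n_male + seq_len(n_male)]
    series$fec_var[i] <- stats::var(fecundity(zm, "male", lp)) / 2 +
      stats::var(fecundity(zf, "female", lp)) / 2
    series$pheno_var[i] <- stats::var(z)
    ssz <- min(pheno_sample_size, n_male)
    pheno_samples[[i]] <- data.frame(
      generation = gens_at[i], sex = rep(c("M", "F"), each = ssz),
      z = c(zm[sample.int(n_male, ssz)], zf[sample.int(n_male, ssz)]))
  }
  if (parentage != "none") {
    closed <- step_generation(state, arch, lp, 1, record_parentage = TRUE)
    partabs[[as.character(gens_at[n_rec])]] <- attr(closed, "parentage")
  }

  structure(list(generations = gens_at, freq = freq,
                 het = 2 * freq * (1 - freq),
                 pheno_samples = do.call(rbind, pheno_samples),
                 series = series, parentage = partabs, final = state,
                 burn_in = burn_in, arch = arch, lp = lp, n = n),
            class = "polygenic_result")
}

#' @export
print.polygenic_result <- function(x, ...) {
  cat("<polygenic_result>", max(x$generations), "generations, N =", x$n,
      ", L =", x$arch$L, ", mode:", x$arch$mode, "\n")
  keep <- x$generations > x$burn_in
  if (any(keep))
    cat("  stationary mean heterozygosity:",
        signif(mean(x$het[keep, , drop = FALSE]), 4), "\n")
  invisible(x)
}

#' Stationary records of a polygenic run
#'
#' Indices of sampled generations after the burn-in.
#'
#' @param res A `polygenic_result`.
#' @return Integer vector of record indices.
#' @export
stationary_records <- function(res) {
  which(res$generations > res$burn_in)
}
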