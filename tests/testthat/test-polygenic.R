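arch10 <- architecture(L = 10, delta = 1, mu = 5e-6)

test_that("the additive genotype-phenotype map hits its extremes and midpoint", {
  n <- 4
  all_A <- matrix(1L, n, 10)
  all_a <- matrix(0L, n, 10)
  st <- population_state(all_A, all_A, arch10)
  expect_equal(phenotype(st, arch10), rep(20, n)) # theta = 2 * sum(delta)
  st <- population_state(all_a, all_a, arch10)
  expect_equal(phenotype(st, arch10), rep(-20, n))
  st <- population_state(all_A, all_a, arch10)
  expect_equal(phenotype(st, arch10), rep(0, n))
  # unequal effect sizes enter through 2 * sum over loci
  archv <- architecture(L = 3, delta = c(0.5, 1, 2), mu = 0)
  st <- population_state(matrix(c(1L, 0L, 1L), 2, 3, byrow = TRUE),
                         matrix(c(1L, 0L, 0L), 2, 3, byrow = TRUE), archv)
  # doses (2, 0, 1) with deltas (0.5, 1, 2): 2*0.5 - 2*1 + 0 = -1
  expect_equal(phenotype(st, archv), rep(-1, 2))
})

test_that("meiosis transmits haplotypes per the recombination and mutation model", {
  set.seed(401)
  # no recombination, no mutation: parental haplotypes pass intact
  arch0 <- architecture(L = 5, delta = 1, mu = 0, r_adjacent = 0)
  h1 <- c(1L, 1L, 0L, 0L, 1L); h2 <- c(0L, 0L, 1L, 1L, 0L)
  for (i in 1:20) {
    g <- make_gamete(h1, h2, arch0)
    expect_true(identical(g, h1) || identical(g, h2))
  }
  # free recombination, doubly heterozygous 2-locus parent: all four
  # haplotypes near frequency 1/4
  arch2 <- architecture(L = 2, delta = 1, mu = 0, r_adjacent = 0.5)
  gams <- replicate(4000, paste(make_gamete(c(1L, 1L), c(0L, 0L), arch2),
                                collapse = ""))
  counts <- table(factor(gams, levels = c("00", "01", "10", "11")))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  # mutation saturation: mu = 0.5 makes the transmitted allele uniform
  archm <- architecture(L = 1, delta = 1, mu = 0.5)
  gm <- replicate(4000, make_gamete(1L, 1L, archm)[1])
  expect_lt(abs(mean(gm) - 0.5), 0.03)
})

test_that("population size, sex ratio, and Y carriage are conserved", {
  lp <- symmetric_power(0.6, 1.5, theta = 20)
  set.seed(402)
  for (mode in c("autosome", "x_hemizygous", "par")) {
    arch <- architecture(L = 10, delta = 1, mu = 1e-4, mode = mode,
                         r_sdr = 0.1)
    st <- init_population(100, arch)
    for (i in 1:3) {
      st <- step_generation(st, arch, lp, 5)
      expect_equal(nrow(st$h1), 100)
      expect_identical(st$sex, rep(c("M", "F"), each = 50))
      if (mode == "par") {
        y <- st$sdr1 + st$sdr2
        expect_identical(y, rep(c(1L, 0L), each = 50))
      }
      if (mode == "x_hemizygous") {
        expect_identical(st$h1[1:50, ], st$h2[1:50, ]) # mirrored male X
      }
    }
    expect_identical(st$generation, 15L)
  }
})

test_that("neutral transmission preserves allele frequencies in expectation", {
  lp0 <- symmetric_power(0, 1, theta = 2)
  arch <- architecture(L = 1, delta = 1, mu = 0)
  set.seed(403)
  h <- matrix(as.integer(runif(200) < 0.37), 200, 1)
  p0 <- mean(h)
  dp <- replicate(150, {
    st <- population_state(h, h[sample(200), , drop = FALSE], arch)
    st <- step_generation(st, arch, lp0, 1)
    mean(st$h1 + st$h2) / 2 - p0
  })
  expect_lt(abs(mean(dp)), 4 * sd(dp) / sqrt(length(dp)))
})

test_that("with one locus the engine matches the deterministic two-sex recursion", {
  # strong asymmetric selection, large N: one generation of the simulator
  # against the exact genotype-frequency recursion
  delta <- 1; mu <- 1e-3
  arch <- architecture(L = 1, delta = delta, mu = mu)
  lp <- landscape_pair("power", theta = 2, c_m = 0.4, c_f = 0.15,
                       b_m = 2, b_f = 2)
  N <- 100000
  # exact composition at p = 0.6, Hardy-Weinberg rounded to counts
  n_AA <- round(0.36 * N); n_Aa <- round(0.48 * N)
  geno <- c(rep(2L, n_AA), rep(1L, n_Aa), rep(0L, N - n_AA - n_Aa))
  h1 <- matrix(as.integer(geno >= 1), N, 1)
  h2 <- matrix(as.integer(geno == 2), N, 1)
  set.seed(404)
  ord <- sample(N) # mix genotypes across the sex split
  st <- population_state(h1[ord, , drop = FALSE], h2[ord, , drop = FALSE],
                         arch)
  g0 <- c(sum(geno == 0), sum(geno == 1), sum(geno == 2)) / N
  pred <- oracle_l1_recursion(g0, lp, delta, mu)
  st1 <- step_generation(st, arch, lp, 1)
  d <- st1$h1[, 1] + st1$h2[, 1]
  obs <- c(mean(d == 0), mean(d == 1), mean(d == 2))
  # multinomial sampling noise is O(N^-1/2)
  expect_lt(max(abs(obs - pred)), 5 * sqrt(0.25 / N) + 1e-3)
})

test_that("PAR with free SDR recombination behaves like an autosome", {
  # with r_sdr = 0.5 the SDR decouples from the locus block, so the
  # distribution of stationary heterozygosity matches the autosomal model
  lp <- symmetric_power(0.4, 1.5, theta = 4)
  set.seed(405)
  hets <- lapply(c("autosome", "par"), function(mode) {
    arch <- architecture(L = 2, delta = 1, mu = 5e-3, mode = mode,
                         r_sdr = 0.5)
    vapply(1:12, function(i)
      mean(run_polygenic(arch, lp, n = 200, generations = 300,
                         sample_every = 50,
                         pheno_sample_size = 2)$het[4:6, ]),
      numeric(1))
  })
  expect_gt(stats::ks.test(hets[[1]], hets[[2]])$p.value, 0.01)
})

test_that("neutral polygenic heterozygosity matches the diffusion prediction", {
  # symmetric two-allele mutation: stationary E[H] = 4 N mu / (8 N mu + 1)
  arch <- architecture(L = 10, delta = 1, mu = 2.5e-4)
  nb <- neutral_baseline(arch, n = 100, generations = 20000, n_reps = 3,
                         sample_every = 200, seed = 406)
  expect_lt(abs(nb$mean - nb$closed_form),
            4 * nb$se + 0.1 * nb$closed_form)
})

test_that("the phenotype distribution smooths as the locus number grows", {
  # under diversifying selection, Mendelian shuffling of more (smaller,
  # relative to theta) loci spreads phenotypes over more classes: the
  # entropy of the scaled phenotype histogram rises from L = 2 to L = 10
  entropy_L <- function(L, seed) {
    arch <- architecture(L = L, delta = 1, mu = 1e-4)
    lp <- symmetric_power(0.9, 1.5, theta = 2 * L)
    r <- run_polygenic(arch, lp, n = 500, generations = 2000,
                       sample_every = 500, pheno_sample_size = 250,
                       seed = seed)
    z <- r$pheno_samples$z[r$pheno_samples$generation == 2000] / (2 * L)
    p <- tabulate(cut(z, seq(-1, 1, length.out = 22), labels = FALSE), 21)
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  }
  for (s in 1:2) expect_gt(entropy_L(10, s + 10), entropy_L(2, s))
})

test_that("runs are reproducible from the seed", {
  lp <- symmetric_power(0.6, 1.5, theta = 10)
  arch <- architecture(L = 5, delta = 1, mu = 1e-4)
  r1 <- run_polygenic(arch, lp, n = 100, generations = 200, sample_every = 50,
                      parentage = "last", seed = 99)
  r2 <- run_polygenic(arch, lp, n = 100, generations = 200, sample_every = 50,
                      parentage = "last", seed = 99)
  expect_identical(r1$freq, r2$freq)
  expect_identical(r1$parentage, r2$parentage)
  expect_identical(r1$final$h1, r2$final$h1)
})

test_that("landscape and architecture trait scales must agree", {
  lp <- symmetric_power(0.5, 1.5, theta = 2)
  expect_error(run_polygenic(arch10, lp, n = 50, generations = 10),
               "theta")
})
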