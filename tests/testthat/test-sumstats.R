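test_that("expected heterozygosity follows 2p(1-p)", {
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(0.1), 0.18)
  expect_error(expected_heterozygosity(1.2), "frequencies")
})

test_that("between-sex FST reproduces hand calculations", {
  # equal weighted frequencies in both sexes: no differentiation
  t1 <- toy_parentage(rep(c("M", "F"), each = 4), rep(1, 8),
                      cbind(rep(c(0, 1, 1, 2), 2)))
  expect_equal(between_sex_fst(t1), 0)
  # fixed difference: FST = 1
  t2 <- toy_parentage(c("M", "M", "F", "F"), rep(1, 4), cbind(c(2, 2, 0, 0)))
  expect_equal(between_sex_fst(t2), 1)
  # p_m = 0.6, p_f = 0.4: H_T = 0.5, H_S = 0.48, FST = 0.04
  t3 <- toy_parentage(rep(c("M", "F"), each = 5), rep(1, 10),
                      cbind(c(2, 2, 1, 1, 0, 0, 0, 1, 1, 2)))
  expect_equal(between_sex_fst(t3), 0.04)
  # offspring weighting shifts the parental frequencies
  t4 <- toy_parentage(c("M", "M", "F"), c(3, 1, 2), cbind(c(2, 0, 1)))
  # weighted p_m = (3*2 + 1*0) / (2*4) = 0.75, p_f = 0.5
  pm <- 0.75; pf <- 0.5; pb <- (pm + pf) / 2
  expect_equal(between_sex_fst(t4),
               (2 * pb * (1 - pb) - (2 * pm * (1 - pm) + 2 * pf * (1 - pf)) / 2) /
                 (2 * pb * (1 - pb)))
  # monomorphic locus: missing, not zero
  t5 <- toy_parentage(c("M", "F"), c(1, 1), cbind(c(2, 2), c(1, 1)))
  expect_true(is.na(between_sex_fst(t5)[1]))
  expect_false(is.na(between_sex_fst(t5)[2]))
  # a sex without any offspring makes the statistic undefined
  t6 <- toy_parentage(c("M", "F"), c(2, 0), cbind(c(1, 1)))
  expect_error(between_sex_fst(t6), "successful parents")
})

test_that("FST stays within [0, 1] on random parentage tables", {
  set.seed(501)
  for (i in 1:50) {
    n <- 20
    tab <- toy_parentage(rep(c("M", "F"), each = n / 2),
                         rpois(n, 2), cbind(sample(0:2, n, TRUE),
                                            sample(0:2, n, TRUE)))
    if (sum(tab$offspring[tab$sex == "M"]) == 0 ||
        sum(tab$offspring[tab$sex == "F"]) == 0) next
    fst <- between_sex_fst(tab)
    expect_true(all(is.na(fst) | (fst >= 0 & fst <= 1)))
  }
})

test_that("fitness-association slopes are OLS on within-individual allele frequency", {
  # exact line in males: offspring = 1 + dose, i.e. slope 2 per unit frequency
  tb <- toy_parentage(c("M", "M", "M", "F", "F", "F"),
                      c(1, 2, 3, 2, 2, 2), cbind(c(0, 1, 2, 0, 1, 2)))
  fa <- fitness_association(tb)
  expect_equal(fa$beta_m, 2)
  expect_equal(fa$beta_f, 0)
  expect_equal(fa$beta_absdiff, 2)
  # constant regressor: slope is missing
  tc <- toy_parentage(c("M", "M", "F", "F"), c(1, 2, 1, 2),
                      cbind(c(1, 1, 0, 2)))
  fac <- fitness_association(tc)
  expect_true(is.na(fac$beta_m))
  expect_false(is.na(fac$beta_f))
})

test_that("sex permutation gives a null centered at zero for slope differences", {
  set.seed(502)
  n <- 200
  dose <- sample(0:2, n, TRUE)
  off <- rpois(n, 2 + dose) # fitness association identical in both sexes
  tab <- toy_parentage(rep(c("M", "F"), each = n / 2), off, cbind(dose))
  diffs <- replicate(500, fitness_association(permute_sex(tab))$beta_m -
                       fitness_association(permute_sex(tab))$beta_f)
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
  # and the observed (unpermuted) difference sits inside the null spread
  obs <- fitness_association(tab)$beta_m - fitness_association(tab)$beta_f
  expect_lt(abs(obs), stats::quantile(abs(diffs), 0.999))
})

test_that("sex load interpolates between no-cost and worst-case populations", {
  lp <- landscape_pair("power", theta = 2, c_m = 0.8, c_f = 0.3,
                       b_m = 1.5, b_f = 1.5)
  # no selection: no load
  lp0 <- symmetric_power(0, 1.2)
  expect_equal(sex_load(1, 1, lp0), 0)
  # monomorphic at the female optimum: males at their worst, load = c_m / 2
  expect_equal(sex_load(fecundity(2, "male", lp), fecundity(2, "female", lp),
                        lp), lp$c_m / 2)
  # mixed toy population, against direct averaging
  zs <- c(-1, 0.5, 2)
  expect_equal(sex_load(mean(fecundity(zs, "male", lp)),
                        mean(fecundity(zs, "female", lp)), lp),
               1 - 0.5 * (mean(fecundity(zs, "male", lp)) +
                            mean(fecundity(zs, "female", lp))))
})

test_that("balanced-locus counting applies the threshold over the trailing window", {
  het <- cbind(rep(0, 20), rep(0.5, 20), c(rep(0.5, 15), rep(0.1, 5)))
  expect_equal(count_balanced_loci(het), 1) # only the pinned locus survives
  expect_equal(count_balanced_loci(het * 0), 0)
  expect_equal(count_balanced_loci(het, window = 20), 1)
  expect_equal(count_balanced_loci(cbind(rep(0.3, 10)), het_threshold = 0.25),
               1)
})

test_that("fecundity variance is zero for monomorphic and exact for toy data", {
  lp <- symmetric_power(0.9, 1.5, theta = 2)
  expect_equal(fecundity_variance(rep(0.4, 6), rep(0.4, 6), lp), 0)
  zm <- c(-2, 0); zf <- c(0, 2)
  expect_equal(fecundity_variance(zm, zf, lp),
               var(fecundity(zm, "male", lp)) / 2 +
                 var(fecundity(zf, "female", lp)) / 2)
})

test_that("MAF proportion counts loci with common minor alleles", {
  expect_equal(maf_proportion(c(0, 1, 0, 1)), 0)
  expect_equal(maf_proportion(rep(0.5, 4)), 1)
  expect_equal(maf_proportion(c(0.01, 0.2, 0.5, 0.96)), 0.5)
})

test_that("neutral baseline requires replicates and vanishes without mutation", {
  arch <- architecture(L = 2, delta = 1, mu = 0)
  expect_error(neutral_baseline(arch, n = 20, generations = 10, n_reps = 1),
               "n_reps")
  nb <- neutral_baseline(arch, n = 20, generations = 60, n_reps = 2,
                         sample_every = 20, seed = 503)
  expect_equal(nb$closed_form, 0)
  expect_lt(nb$mean, 0.5) # het decays from the p0 = 0.5 start under drift
})
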