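test_that("a resident allele is exactly neutral against itself", {
  set.seed(201)
  for (i in seq_len(30)) {
    lp <- landscape_pair("power", theta = runif(1, 1, 5),
                         c_m = runif(1, 0, 0.95), c_f = runif(1, 0, 0.95),
                         b_m = runif(1, 0.2, 3), b_f = runif(1, 0.2, 3))
    x <- runif(1, -0.45, 0.45) * lp$theta
    expect_identical(invasion_fitness(x, x, lp), 1)
  }
})

test_that("invasion fitness matches hand evaluation and mirror symmetry", {
  lp <- symmetric_power(0.9, 1.5, theta = 2)
  # independent route: ratios of directly evaluated power fecundities
  w_or <- function(z, s) oracle_power_w(z, s, 2, 1, 0.9, 1.5)
  expect_equal(invasion_fitness(0.1, 0, lp),
               0.5 * w_or(0.1, "male") / w_or(0, "male") +
                 0.5 * w_or(0.1, "female") / w_or(0, "female"),
               tolerance = 1e-12)
  expect_equal(invasion_fitness(0.1, 0, lp), 1.00071, tolerance = 1e-5)
  # sex-exchange mirror symmetry of a symmetric pair
  for (x in c(0.05, 0.2, 0.4))
    expect_equal(invasion_fitness(-x, 0, lp), invasion_fitness(x, 0, lp),
                 tolerance = 1e-12)
  # degenerate resident: c = 1 makes one sex's fecundity vanish at z = theta
  lp1 <- symmetric_power(1, 1.5, theta = 2)
  expect_error(invasion_fitness(0.9, 1, lp1), "degenerate resident")
})

test_that("selection gradient matches finite differences of invasion fitness", {
  set.seed(202)
  for (i in seq_len(20)) {
    lp <- landscape_pair("power", theta = 2,
                         c_m = runif(1, 0.05, 0.95), c_f = runif(1, 0.05, 0.95),
                         b_m = runif(1, 0.3, 3), b_f = runif(1, 0.3, 3))
    x <- runif(1, -0.4, 0.4)
    expect_equal(selection_gradient(x, lp), fd_selection_gradient(x, lp),
                 tolerance = 1e-6)
  }
  # symmetric pair: gradient vanishes at the midpoint
  expect_equal(selection_gradient(0, symmetric_power(0.4, 1.3)), 0)
  # directional example: above z* selection pushes toward the female optimum
  expect_gt(selection_gradient(0.15, symmetric_power(0.05, 1.5)), 0)
})

test_that("singular values are located, classified, and symmetric", {
  # symmetric costs put the attracting singular value halfway between the
  # optima (strong costs also create flanking repellors near the boundaries,
  # where the disfavored sex's fitness collapses)
  sa <- find_singular(symmetric_power(0.6, 1.5))
  att <- sa$roots[sa$roots$s_prime < 0, ]
  expect_equal(nrow(att), 1)
  expect_equal(att$z_star, 0, tolerance = 1e-8)
  expect_equal(sa$regime, "diversifying")
  # swapping male and female parameters negates z* and keeps the regime
  lp_a <- landscape_pair("power", theta = 2, c_m = 0.3, c_f = 0.6,
                         b_m = 0.5, b_f = 0.5)
  lp_b <- landscape_pair("power", theta = 2, c_m = 0.6, c_f = 0.3,
                         b_m = 0.5, b_f = 0.5)
  sa_a <- find_singular(lp_a); sa_b <- find_singular(lp_b)
  expect_equal(sa_a$roots$z_star, -rev(sa_b$roots$z_star), tolerance = 1e-8)
  expect_identical(sa_a$regime, sa_b$regime)
  # no selection at all: flagged neutral, not classified
  sn <- find_singular(symmetric_power(0, 1.5))
  expect_true(sn$neutral)
  expect_identical(sn$regime, "neutral")
  # the power family yields at most one attracting interior root
  set.seed(203)
  for (i in seq_len(25)) {
    lp <- landscape_pair("power", theta = 2,
                         c_m = runif(1, 0.02, 0.95), c_f = runif(1, 0.02, 0.95),
                         b_m = runif(1, 0.3, 3), b_f = runif(1, 0.3, 3))
    r <- find_singular(lp)$roots
    expect_lte(sum(r$s_prime < 0), 1)
  }
})

test_that("numeric z* converges to the small-cost closed form as O(c^2)", {
  # b = 0.5 with a 1:4 cost ratio: closed form z* = (15/17) theta
  err <- vapply(c(0.08, 0.04, 0.02), function(cf) {
    lp <- landscape_pair("power", theta = 2, c_m = cf / 4, c_f = cf,
                         b_m = 0.5, b_f = 0.5)
    abs(find_singular(lp)$roots$z_star - z_star_small_cost(lp))
  }, numeric(1))
  expect_equal(z_star_small_cost(
    landscape_pair("power", theta = 2, c_m = 0.02, c_f = 0.08,
                   b_m = 0.5, b_f = 0.5)), 2 * 15 / 17)
  # halving the costs should shrink the error about fourfold
  expect_lt(err[2], err[1] / 2)
  expect_lt(err[3], err[2] / 2)
})

test_that("regime classification reproduces the three canonical examples", {
  expect_identical(classify_regime(symmetric_power(0.9, 1.5)), "diversifying")
  expect_identical(classify_regime(symmetric_power(0.05, 0.5)), "stabilizing")
  expect_identical(classify_regime(symmetric_power(0.05, 1.5)), "directional")
})

test_that("critical cost matches a brute-force scan of the classifier", {
  for (b in c(1.2, 1.5, 2.5)) {
    expect_equal(critical_cost(b), scan_critical_cost(b), tolerance = 1e-4)
  }
  expect_equal(critical_cost(1.5), 0.586, tolerance = 1e-3)
  # boundary collapses toward c = 0 as b approaches 1 from above
  expect_lt(critical_cost(1.01), 0.05)
  expect_equal(critical_cost(1.01), scan_critical_cost(1.01),
               tolerance = 1e-4)
  expect_error(critical_cost(1), "b <= 1")
  expect_error(critical_cost(0.8), "b <= 1")
})
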