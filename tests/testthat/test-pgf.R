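# linear-fractional pgf algebra: parameters, pmf, Moebius maps, iterates

test_that("parameter constraints are enforced with informative errors", {
  expect_error(lf_params(0.2, 1), "0 < p < 1")
  expect_error(lf_params(0.2, 0), "0 < p < 1")
  expect_error(lf_params(0, 0.5), "b > 0")
  expect_error(lf_params(-0.1, 0.5), "b > 0")
  expect_error(lf_params(0.6, 0.5), "b \\+ p <= 1")
  # the zero-death boundary b + p = 1 is legal
  expect_s3_class(lf_params(0.139, 0.861), "lf_params")
  expect_s3_class(lf_params(0.5, 0.5), "lf_params")
})

test_that("pgf evaluates to 1 at s = 1 and to p0 at s = 0", {
  for (th in list(lf_params(0.016, 0.983), lf_params(0.139, 0.861),
                  lf_params(0.3, 0.2), lf_params(0.05, 0.9))) {
    f <- lf_pgf(th)
    expect_equal(mobius_eval(f, 1), 1, tolerance = 1e-12)
    expect_equal(mobius_eval(f, 0), 1 - th$b/(1 - th$p), tolerance = 1e-12)
  }
  # frozen closed-form value: p0 = 1 - 0.016/0.017
  expect_equal(mobius_eval(lf_pgf(lf_params(0.016, 0.983)), 0),
               0.058824, tolerance = 1e-5)
})

test_that("pgf derivative at 1 equals the mean b/(1-p)^2", {
  th <- lf_params(0.139, 0.861)
  f <- lf_pgf(th)
  expect_equal(mean_offspring(th), 7.1942, tolerance = 1e-4)
  expect_equal(num_deriv(function(s) mobius_eval(f, s), 1),
               mean_offspring(th), tolerance = 1e-6)
  # mean by direct pmf summation
  pk <- offspring_pmf(th, 4000)
  expect_equal(sum((0:4000) * pk), mean_offspring(th), tolerance = 1e-8)
})

test_that("offspring pmf has the closed geometric form and sums to 1", {
  th1 <- lf_params(0.016, 0.983)
  expect_equal(unname(offspring_pmf(th1, 1)[2]), 0.016)
  th2 <- lf_params(0.139, 0.861)
  expect_equal(unname(offspring_pmf(th2, 2)[3]), 0.119679)
  for (th in list(th1, th2, lf_params(0.4, 0.3))) {
    k_max <- 3000L
    pk <- offspring_pmf(th, k_max)
    expect_true(all(pk >= 0))
    expect_lte(sum(pk), 1 + 1e-12)
    remainder <- th$b * th$p^k_max/(1 - th$p)
    expect_equal(sum(pk), 1, tolerance = remainder + 1e-12)
  }
  expect_error(offspring_pmf(th1, -1))
})

test_that("supercriticality criterion is b > (1-p)^2", {
  expect_true(is_supercritical(lf_params(0.143, 0.856)))
  expect_false(is_supercritical(lf_params(0.01, 0.85)))
  th_crit <- lf_params((1 - 0.7)^2, 0.7)
  expect_equal(mean_offspring(th_crit), 1)
  expect_false(is_supercritical(th_crit))
  # thinning pushes a marginally supercritical law below the boundary
  th_edge <- lf_params((1 - 0.7)^2 * (1 + 1e-8), 0.7)
  expect_true(is_supercritical(th_edge))
  expect_false(is_supercritical(th_edge, mu = 1e-4))
})

test_that("mutation thinning is the affine substitution with mean m(1-mu)", {
  f <- lf_pgf(lf_params(0.139, 0.861))
  expect_equal(unclass(mutation_thin(f, 0)), unclass(f))
  H <- mutation_thin(f, 1e-6)
  expect_equal(mobius_eval(H, 1), 1, tolerance = 1e-12)
  expect_equal(num_deriv(function(s) mobius_eval(H, s), 1),
               7.1942446 * (1 - 1e-6), tolerance = 1e-6)
  # functional identity H(s) = f(mu + (1-mu)s) on a grid
  s <- seq(0, 1, by = 0.1)
  mu <- 0.37
  H2 <- mutation_thin(f, mu)
  expect_equal(mobius_eval(H2, s), mobius_eval(f, mu + (1 - mu) * s),
               tolerance = 1e-12)
  expect_error(mutation_thin(f, 1), "\\[0, 1\\)")
  expect_error(mutation_thin(f, -0.1), "\\[0, 1\\)")
})

test_that("coefficient-matrix iteration matches nested evaluation", {
  s_grid <- seq(0, 1, by = 0.1)
  for (th in list(lf_params(0.139, 0.861), lf_params(0.016, 0.983),
                  lf_params(0.3, 0.4))) {
    H <- mutation_thin(lf_pgf(th), 1e-6)
    for (r in 0:20) {
      it <- mobius_iterate(H, r)
      expect_lt(max(abs(mobius_eval(it, s_grid) -
                          vapply(s_grid, function(s) nested_eval(H, r, s),
                                 numeric(1)))), 1e-10)
    }
    # pgf normalization survives long iteration
    for (r in c(35, 50))
      expect_equal(mobius_eval(mobius_iterate(H, r), 1), 1,
                   tolerance = 1e-10)
  }
  expect_error(mobius_iterate(lf_pgf(lf_params(0.2, 0.5)), -1), ">= 0")
})

test_that("iterate r = 0 is the identity and r = 1 the map itself", {
  f <- lf_pgf(lf_params(0.2, 0.7))
  expect_equal(unclass(mobius_iterate(f, 0)), unclass(mobius_identity()))
  expect_equal(unclass(mobius_iterate(f, 1)), unclass(f))
  s <- c(0, 0.3, 0.99, 1)
  expect_equal(mobius_eval(mobius_identity(), s), s)
})

test_that("thinning at mu = 0 commutes with iteration exactly", {
  f <- lf_pgf(lf_params(0.05, 0.9))
  expect_equal(unclass(mobius_iterate(mutation_thin(f, 0), 7)),
               unclass(mobius_iterate(f, 7)))
})

test_that("iterate_pmf gives exact coefficients (FFT extraction oracle)", {
  # identity iterate: unit mass at j = 1
  pmf0 <- iterate_pmf(mobius_identity(), 5)
  expect_equal(unname(pmf0), c(0, 1, 0, 0, 0, 0))
  th <- lf_params(0.016, 0.983)
  # one iterate of the un-thinned pgf reproduces the offspring pmf
  expect_equal(iterate_pmf(lf_pgf(th), 50), offspring_pmf(th, 50),
               ignore_attr = TRUE, tolerance = 1e-12)
  # higher iterates against the independent FFT coefficient oracle
  for (r in c(2, 3, 7)) {
    it <- mobius_iterate(mutation_thin(lf_pgf(lf_params(0.139, 0.861)),
                                       1e-6), r)
    expect_equal(unname(iterate_pmf(it, 30)), fft_coefficients(it, 30),
                 tolerance = 1e-9)
  }
})

test_that("iterate_pmf partial sums are monotone and bounded by 1", {
  # supercritical law: mass keeps escaping to larger sizes with r
  it <- mobius_iterate(mutation_thin(lf_pgf(lf_params(0.2, 0.75)), 1e-3), 6)
  sums <- vapply(c(1, 5, 20, 100, 400), function(jm) sum(iterate_pmf(it, jm)),
                 numeric(1))
  expect_true(all(diff(sums) >= 0))
  expect_true(all(sums <= 1 + 1e-12))
  # subcritical law: generation-6 sizes are almost surely small, so the
  # truncated sum captures the full mass
  it_sub <- mobius_iterate(lf_pgf(lf_params(0.02, 0.7)), 6)
  expect_equal(sum(iterate_pmf(it_sub, 400)), 1, tolerance = 1e-9)
})

test_that("generation-3 clone-size pmf agrees with forward simulation", {
  # 1e5 three-generation clones of a single non-mutant founder; compare
  # P[Z_3 = j] for small j against the closed-form iterate coefficients
  th <- lf_params(0.139, 0.861)
  mu <- 1e-6
  set.seed(401)
  n_clones <- 1e5L
  z <- rep(1L, n_clones)
  for (g in 1:3) {
    tot <- sum(z)
    owner <- rep.int(seq_along(z), z)
    off <- rlinfrac(tot, th)
    keep <- off - stats::rbinom(tot, off, mu)   # non-mutant offspring
    z <- integer(n_clones)
    agg <- rowsum(keep, owner)
    z[as.integer(rownames(agg))] <- agg[, 1L]
  }
  h3 <- iterate_pmf(mobius_iterate(mutation_thin(lf_pgf(th), mu), 3), 10)
  for (j in 0:10) {
    phat <- mean(z == j)
    se <- sqrt(max(phat * (1 - phat), 1e-12)/n_clones)
    expect_lt(abs(phat - h3[[as.character(j)]]), 3 * se + 1e-4)
  }
})

test_that("degenerate Moebius maps are rejected", {
  expect_error(mobius_map(1, 2, 2, 4), "degenerate")
  expect_s3_class(mobius_map(2, 1, 1, 2), "mobius")
})
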