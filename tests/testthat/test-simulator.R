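# forward Galton-Watson simulator with infinite-allele mutation

test_that("without mutation exactly one allele ever exists", {
  cen <- simulate_gp(lf_params(0.139, 0.861), mu = 0, generations = 6,
                     seed = 1)
  expect_length(cen$birth_gen, 1)
  for (g in cen$generations) expect_lte(length(g$id), 1)
  emp <- empirical_spectrum(cen)
  expect_length(emp[emp > 0], 1)
})

test_that("population never decreases when zero offspring is impossible", {
  # b + p = 1 makes p0 = 0, so every particle leaves at least one child
  cen <- simulate_gp(lf_params(0.139, 0.861), mu = 0, generations = 7,
                     seed = 2)
  expect_true(all(diff(cen$totals) >= 0))
})

test_that("mutation relabels particles but conserves their number", {
  cen <- simulate_gp(lf_params(0.25, 0.65), mu = 0.05, generations = 10,
                     seed = 3, pop_cap = 1e6)
  k <- length(cen$offspring_totals)
  expect_equal(cen$totals[1 + seq_len(k)], cen$offspring_totals)
})

test_that("allele identifiers are unique across a run", {
  cen <- simulate_gp(lf_params(0.3, 0.55), mu = 0.1, generations = 8,
                     seed = 4)
  ids <- as.integer(names(cen$birth_gen))
  expect_false(any(duplicated(ids)))
  expect_length(ids, length(cen$birth_gen))
  for (g in cen$generations) expect_false(any(duplicated(g$id)))
})

test_that("mean population growth follows E[Z_n] = m^n", {
  th <- lf_params(0.139, 0.861)
  m <- mean_offspring(th)
  set.seed(505)
  z5 <- vapply(1:3000, function(i)
    simulate_gp(th, mu = 0, generations = 5)$totals[6], numeric(1))
  se <- stats::sd(z5)/sqrt(length(z5))
  expect_lt(abs(mean(z5) - m^5), 3 * se)
})

test_that("generation-size law matches the pgf iterate without mutation", {
  th <- lf_params(0.2, 0.55)            # p0 > 0, extinction possible
  set.seed(506)
  z3 <- vapply(1:4000, function(i)
    simulate_gp(th, mu = 0, generations = 3)$totals[4], numeric(1))
  h3 <- iterate_pmf(mobius_iterate(lf_pgf(th), 3), 8)
  for (j in 0:8) {
    phat <- mean(z3 == j)
    se <- sqrt(max(phat * (1 - phat), 1e-12)/length(z3))
    expect_lt(abs(phat - h3[[as.character(j)]]), 3 * se + 2e-3)
  }
})

test_that("subcritical runs die out", {
  th <- lf_params(0.01, 0.85)           # m = 0.44
  set.seed(507)
  extinct <- vapply(1:300, function(i) {
    simulate_gp(th, mu = 0, generations = 25)$totals[26] == 0
  }, logical(1))
  expect_gt(mean(extinct), 0.98)
})

test_that("runs stop early and are flagged when the population cap hits", {
  cen <- simulate_gp(lf_params(0.139, 0.861), mu = 0, generations = 30,
                     init_copies = 10, pop_cap = 5000, seed = 8)
  expect_true(cen$capped)
  expect_lt(length(cen$generations), 31)
  expect_error(simulate_gp(lf_params(0.2, 0.7), mu = 0, generations = 2,
                           init_copies = 10, pop_cap = 5))
})

test_that("empirical_spectrum tabulates alive alleles", {
  cen <- simulate_gp(lf_params(0.25, 0.6), mu = 0.02, generations = 10,
                     seed = 11)
  last <- cen$generations[[length(cen$generations)]]
  if (length(last$copies)) {
    emp <- empirical_spectrum(cen)
    expect_equal(sum(emp), 1, tolerance = 1e-12)
    expect_equal(unname(emp[7]),
                 mean(last$copies == 7) * length(last$copies)/
                   sum(last$copies >= 1), tolerance = 1e-12)
  }
  # extinct run yields an empty, flagged spectrum
  ext <- simulate_gp(lf_params(0.01, 0.85), mu = 0, generations = 20,
                     seed = 12)
  expect_warning(out <- empirical_spectrum(ext), "extinct")
  expect_length(out, 0)
})

test_that("generate_counts is reproducible and validates input", {
  th <- lf_params(0.10, 0.88)
  a <- generate_counts(th, n_alleles = 2000, seed = 31)
  b <- generate_counts(th, n_alleles = 2000, seed = 31)
  expect_identical(a$class, b$class)
  expect_identical(a$count, b$count)
  expect_equal(n_alleles(a), 2000)
  expect_error(generate_counts(th, n_alleles = 0), "positive")
  expect_error(generate_counts(lf_params(0.01, 0.85), n_alleles = 10),
               "supercritical")
})

test_that("generated singleton fraction matches psi_1 binomially", {
  th <- lf_params(0.10, 0.88)
  psi1 <- limit_spectrum(th, j_max = 1)$psi[1]
  n <- 50000
  ct <- generate_counts(th, n_alleles = n, seed = 32)
  prop1 <- ct$count[ct$class == 1]/n
  se <- sqrt(psi1 * (1 - psi1)/n)
  expect_lt(abs(prop1 - psi1), 3 * se)
})
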