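# independent oracles shared across test files

# power-series coefficients of a Moebius pgf by Cauchy-integral / FFT
# extraction on a circle of radius rho (independent of the closed-form
# partial-fraction path in iterate_pmf)
fft_coefficients <- function(map, j_max, rho = 0.9, n_grid = 512L) {
  z <- rho * exp(2i * pi * seq(0L, n_grid - 1L)/n_grid)
  vals <- (map[["n1"]] * z + map[["n0"]])/(map[["d1"]] * z + map[["d0"]])
  co <- Re(stats::fft(vals))/n_grid
  co[seq_len(j_max + 1L)]/rho^(0:j_max)
}

# nested functional evaluation of the r-th iterate at a point
nested_eval <- function(map, r, s) {
  for (i in seq_len(r)) s <- mobius_eval(map, s)
  s
}

# central-difference derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h))/(2 * h)

# pooled empirical spectrum over independent simulator runs, ancestral
# allele excluded, with cluster (per-run) delta-method standard errors
pooled_spectrum <- function(params, mu, generations, runs, j_max,
                            pop_cap = 5e6) {
  Aj <- matrix(0, runs, j_max)
  At <- numeric(runs)
  for (i in seq_len(runs)) {
    cen <- simulate_gp(params, mu, generations, pop_cap = pop_cap)
    last <- cen$generations[[length(cen$generations)]]
    cp <- last$copies[last$id != 1L]
    cp <- cp[cp >= 1]
    At[i] <- length(cp)
    if (length(cp)) Aj[i, ] <- tabulate(cp, nbins = max(j_max, max(cp)))[seq_len(j_max)]
  }
  pooled <- colSums(Aj)/sum(At)
  se <- vapply(seq_len(j_max), function(j) {
    stats::sd((Aj[, j] - pooled[j] * At)/mean(At))/sqrt(runs)
  }, numeric(1))
  list(prop = pooled, se = se, n_alleles = sum(At))
}

# a tiny hand-made frequency spectrum for arithmetic checks
fake_spectrum <- function(psi, tail_mass) {
  structure(list(psi = psi, tail_mass = tail_mass,
                 params = lf_params(0.25, 0.6), mu = 0,
                 j_max = length(psi), r_tol = 1e-9, r_used = 0L),
            class = "freq_spectrum")
}
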