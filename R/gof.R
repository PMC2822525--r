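#' Chi-square distance between a count table and a spectrum
#'
#' Bins the observed allele-class counts into explicit classes
#' `1..B` plus one combined tail bin for classes above `B`, computes
#' expected counts `E = n * (binned spectrum probabilities)` (the tail bin
#' receives all spectrum mass beyond `B`, including `tail_mass`), and
#' returns \eqn{\sum_{\mathrm{bins}} (O-E)^2/E}. Every bin has positive
#' expected count because \eqn{\Psi_j > 0} for all `j` under a
#' supercritical linear-fractional law.
#'
#' @param counts A [class_counts()] object.
#' @param spectrum A `"freq_spectrum"` from [limit_spectrum()] with
#'   `j_max >= B`.
#' @param B Number of explicit bins (default: largest observed class).
#' @return The chi-square statistic (nonnegative scalar).
#' @examples
#' sp <- limit_spectrum(lf_params(0.016, 0.983), j_max = 30)
#' chi2_spectrum(alu_counts("Ya1"), sp)
#' @export
chi2_spectrum <- function(counts, spectrum, B = NULL) {
  stopifnot(inherits(counts, "class_counts"),
            inherits(spectrum, "freq_spectrum"))
  if (is.null(B)) B <- max(counts$class)
  stopifnot(B >= 1L, B == floor(B))
  if (spectrum$j_max < B)
    stop("chi2_spectrum: spectrum j_max (", spectrum$j_max,
         ") smaller than B (", B, ")", call. = FALSE)
  pr <- bin_probs(spectrum, B)
  if (any(pr <= 0))
    stop("chi2_spectrum: zero-probability bin; increase spectrum accuracy",
         call. = FALSE)
  O <- bin_counts(counts, B)
  n <- sum(O)
  E <- n * pr
  sum((O - E)^2/E)
}

# explicit bins 1..B plus combined tail; shared by observed and simulated
bin_probs <- function(spectrum, B) {
  psi <- spectrum$psi[seq_len(B)]
  c(psi, 1 - sum(psi))
}

bin_counts <- function(counts, B) {
  O <- numeric(B + 1L)
  idx <- pmin(counts$class, B + 1L)
  for (i in seq_along(idx)) O[idx[i]] <- O[idx[i]] + counts$count[i]
  O
}

#' Simulated null distribution of the chi-square statistic
#'
#' Draws `reps` samples of `n` alleles from the binned spectrum and
#' computes the chi-square statistic of each against the same expected
#' counts, yielding the parametric-bootstrap null distribution. The
#' default draws one multinomial sample per replicate, which is
#' distributionally identical to placing `n` independent uniform draws
#' into bins by the cumulative probabilities; `method = "uniform"` runs
#' that literal (slower) construction for equivalence checking.
#'
#' @param spectrum A `"freq_spectrum"` from [limit_spectrum()].
#' @param n Sample size (number of alleles) per replicate.
#' @param B Number of explicit bins (tail bin appended).
#' @param reps Number of replicates (`>= 1`).
#' @param seed Optional RNG seed for reproducibility.
#' @param method `"multinomial"` (default) or `"uniform"`.
#' @return Numeric vector of `reps` chi-square values.
#' @export
simulate_null_chi2 <- function(spectrum, n, B, reps, seed = NULL,
                               method = c("multinomial", "uniform")) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == floor(n))
  stopifnot(is.numeric(reps), length(reps) == 1L, reps == floor(reps))
  if (reps < 1) stop("simulate_null_chi2: 'reps' must be >= 1",
                     call. = FALSE)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  pr <- bin_probs(spectrum, B)
  E <- n * pr
  if (method == "multinomial") {
    O <- stats::rmultinom(reps, size = n, prob = pr)
    colSums((O - E)^2/E)
  } else {
    edges <- cumsum(pr)
    vapply(seq_len(reps), function(i) {
      u <- stats::runif(n)
      O <- tabulate(findInterval(u, edges) + 1L, nbins = length(pr))
      sum((O - E)^2/E)
    }, numeric(1))
  }
}

#' Parametric-bootstrap goodness-of-fit test for a spectrum fit
#'
#' The simulation-based test of the neutral branching-process model:
#' the chi-square distance between the observed class counts and the
#' fitted spectrum is located within a null distribution obtained by
#' repeatedly sampling count tables of the same size from the fitted
#' spectrum itself. The crude empirical p-value uses the add-one rule
#' `(1 + #{sim >= obs}) / (1 + reps)`, so it is never exactly zero.
#' Expected counts in both the observed and the simulated statistics come
#' from the fitted model, never from the resampled tables.
#'
#' @param counts A [class_counts()] object.
#' @param fit A [fit_gp()] object for these counts, or `NULL` to fit
#'   internally with `mu`.
#' @param mu Mutation probability used when `fit` is `NULL`.
#' @param B Number of explicit bins (default: largest observed class).
#' @param reps Number of null replicates (default 10000).
#' @param seed Optional RNG seed.
#' @param j_max Spectrum truncation for binning (default
#'   `max(100, B + 1)`).
#' @return An object of class `"gp_gof"`: a list with `chi2_obs`,
#'   `sim_max`, `sim_quantiles`, `p_value`, `n_reps`, `seed`, `B`, `fit`.
#' @examples
#' \donttest{
#' gof_test(alu_counts("Ya8"), reps = 2000, seed = 1)
#' }
#' @export
gof_test <- function(counts, fit = NULL, mu = 1e-6, B = NULL,
                     reps = 10000L, seed = NULL, j_max = NULL) {
  stopifnot(inherits(counts, "class_counts"))
  if (reps < 1) stop("gof_test: 'reps' must be >= 1", call. = FALSE)
  if (is.null(fit)) fit <- fit_gp(counts, mu = mu)
  stopifnot(inherits(fit, "gp_fit"))
  if (is.null(B)) B <- max(counts$class)
  if (is.null(j_max)) j_max <- max(100L, B + 1L)
  sp <- limit_spectrum(lf_params(fit$b_hat, fit$p_hat), mu = fit$mu,
                       j_max = j_max, r_tol = fit$r_tol, r_max = fit$r_max)
  obs <- chi2_spectrum(counts, sp, B = B)
  null <- simulate_null_chi2(sp, n = n_alleles(counts), B = B,
                             reps = reps, seed = seed)
  structure(list(chi2_obs = obs,
                 sim_max = max(null),
                 sim_quantiles = stats::quantile(null,
                                                 c(0.5, 0.9, 0.99, 0.999)),
                 p_value = (1 + sum(null >= obs))/(1 + reps),
                 n_reps = as.integer(reps), seed = seed, B = as.integer(B),
                 fit = fit),
            class = "gp_gof")
}

#' @export
print.gp_gof <- function(x, ...) {
  cat("Parametric-bootstrap chi-square goodness-of-fit",
      if (!is.null(x$fit$counts$label)) paste0(" [", x$fit$counts$label, "]"),
      "\n", sep = "")
  cat(sprintf("  observed chi-square: %.4f  (bins 1..%d + tail)\n",
              x$chi2_obs, x$B))
  cat(sprintf("  null: %d replicates, max %.4f, median %.3f\n",
              x$n_reps, x$sim_max, x$sim_quantiles[[1]]))
  cat(sprintf("  crude p-value: %.3g%s\n", x$p_value,
              if (x$chi2_obs > x$sim_max)
                "  (observed exceeds all simulated values)" else ""))
  invisible(x)
}
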