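#' Multinomial log-likelihood of a count table under the limit spectrum
#'
#' The sampling model treats the observed alleles as independent draws
#' from the limit frequency spectrum \eqn{\{\Psi_j\}}, giving the
#' multinomial kernel
#' \deqn{\ell(b, p) = \sum_j n_j \log \Psi_j(b, p, \mu)}
#' over the observed classes (constant terms omitted). There is no closed
#' form; each evaluation computes the spectrum numerically. Parameter
#' values outside the supercritical region return `-Inf` so the function
#' can be handed to penalized optimizers.
#'
#' @param counts A [class_counts()] object.
#' @param params An [lf_params()] object, or anything accepted by
#'   `lf_params()` via a length-2 numeric `c(b, p)`.
#' @param mu Mutation probability (default `1e-6`).
#' @param r_tol,r_max Spectrum truncation controls, see [limit_spectrum()].
#' @return The log-likelihood kernel (finite, or `-Inf` outside the
#'   parameter domain).
#' @examples
#' ll <- loglik_spectrum(alu_counts("Ya1"), lf_params(0.016, 0.983))
#' @export
loglik_spectrum <- function(counts, params, mu = 1e-6,
                            r_tol = 1e-9, r_max = 10000L) {
  stopifnot(inherits(counts, "class_counts"))
  if (is.numeric(params) && length(params) == 2L) {
    params <- tryCatch(lf_params(params[1L], params[2L]),
                       error = function(e) NULL)
    if (is.null(params)) return(-Inf)
  }
  stopifnot(inherits(params, "lf_params"))
  k <- psi_kernel(params$b, params$p, mu, j = counts$class,
                  r_tol = r_tol, r_max = as.integer(r_max))
  if (!k$ok) return(-Inf)
  psi <- k$psi[1L, ]
  if (any(!is.finite(psi)) || any(psi <= 0)) return(-Inf)
  sum(counts$count * log(psi))
}

#' Fit the branching-process spectrum to a count table by maximum likelihood
#'
#' Estimates the linear-fractional offspring parameters `(b, p)` from an
#' allele-class count table under the Griffiths-Pakes limit spectrum with
#' the mutation probability `mu` held fixed. The search is constrained to
#' the supercritical region
#' \deqn{\{0 < p < 1,\ 0 < b \le 1 - p,\ b > (1-p)^2\}}
#' and runs in two stages: a coarse grid (step `grid_step`, ties broken by
#' smaller `b` then smaller `p`) followed by local refinement with
#' box-constrained quasi-Newton iterations on the reparametrization
#' `(p, t)` with `b = (1-p)(1-p + p t)`, `t` in `(0, 1]`, which turns both
#' curved constraint boundaries into coordinate bounds (the likelihood
#' maximum frequently sits exactly on `b + p = 1`, i.e. `t = 1`). The
#' procedure is deterministic.
#'
#' @param counts A [class_counts()] object.
#' @param mu Fixed mutation probability (default `1e-6`; never estimated).
#' @param grid_step Coarse grid step for stage one (default 0.005).
#' @param refine Run the local refinement stage (default `TRUE`).
#' @param r_tol,r_max Spectrum truncation controls, see [limit_spectrum()].
#' @return An object of class `"gp_fit"` with components `b_hat`, `p_hat`,
#'   `loglik`, `n_alleles`, `mu`, `counts`, `converged` and a `trace` list
#'   (grid size, best grid cell, optimizer diagnostics). Methods:
#'   [coef()], [logLik()], [predict.gp_fit()], [residuals.gp_fit()],
#'   [simulate.gp_fit()], [plot.gp_fit()], `print()`, `summary()`.
#' @examples
#' \donttest{
#' fit <- fit_gp(alu_counts("Ya5"))
#' coef(fit)
#' }
#' @export
fit_gp <- function(counts, mu = 1e-6, grid_step = 0.005, refine = TRUE,
                   r_tol = 1e-9, r_max = 10000L) {
  stopifnot(inherits(counts, "class_counts"))
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu < 1)
  stopifnot(grid_step > 0, grid_step < 0.5)

  # stage 1: coarse grid over the constrained region
  pg <- seq(grid_step, 1 - grid_step, by = grid_step)
  cells <- lapply(pg, function(p) {
    b <- seq(grid_step, 1 - p + 1e-12, by = grid_step)
    b <- b[b > (1 - p)^2 & b/(1 - p)^2 * (1 - mu) > 1]
    if (length(b)) cbind(b = b, p = p)
  })
  cells <- do.call(rbind, cells)
  if (is.null(cells) || !nrow(cells))
    stop("fit_gp: no valid grid cell; decrease grid_step", call. = FALSE)
  k <- psi_kernel(cells[, "b"], cells[, "p"], mu, j = counts$class,
                  r_tol = r_tol, r_max = as.integer(r_max))
  ll <- as.vector(log(k$psi) %*% counts$count)
  ll[!k$ok] <- -Inf
  # deterministic tie-break: highest ll, then smaller b, then smaller p
  best <- order(-ll, cells[, "b"], cells[, "p"])[1L]
  b0 <- cells[best, "b"]; p0 <- cells[best, "p"]; ll0 <- ll[best]
  trace <- list(grid_cells = nrow(cells),
                grid_best = c(b = unname(b0), p = unname(p0)),
                grid_loglik = ll0)

  b_hat <- b0; p_hat <- p0; ll_hat <- ll0; converged <- TRUE
  if (refine) {
    nll <- function(par) {
      p <- par[1L]; t <- par[2L]
      b <- (1 - p) * (1 - p + p * t)
      v <- loglik_spectrum(counts, c(b, p), mu, r_tol = r_tol, r_max = r_max)
      if (!is.finite(v)) 1e12 else -v
    }
    t0 <- min(max((b0/(1 - p0) - (1 - p0))/p0, 1e-5), 1)
    opt <- stats::optim(c(p0, t0), nll, method = "L-BFGS-B",
                        lower = c(1e-4, 1e-6), upper = c(1 - 1e-7, 1),
                        control = list(factr = 1e7, maxit = 200))
    p_ref <- opt$par[1L]
    b_ref <- (1 - p_ref) * (1 - p_ref + p_ref * opt$par[2L])
    # never accept a refinement below the grid optimum
    if (-opt$value >= ll0) {
      b_hat <- b_ref; p_hat <- p_ref; ll_hat <- -opt$value
    }
    converged <- opt$convergence %in% c(0L, 52L) && -opt$value >= ll0
    trace$optim <- list(convergence = opt$convergence,
                        counts = opt$counts, message = opt$message)
  }
  structure(list(b_hat = unname(b_hat), p_hat = unname(p_hat),
                 loglik = unname(ll_hat), n_alleles = n_alleles(counts),
                 mu = mu, counts = counts, converged = converged,
                 trace = trace, r_tol = r_tol, r_max = r_max,
                 call = match.call()),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Griffiths-Pakes linear-fractional spectrum fit",
      if (!is.null(x$counts$label)) paste0(" [", x$counts$label, "]"),
      "\n", sep = "")
  cat(sprintf("  b = %.4f, p = %.4f  (mu fixed at %g)\n",
              x$b_hat, x$p_hat, x$mu))
  cat(sprintf("  log-likelihood kernel: %.3f on %d alleles%s\n",
              x$loglik, x$n_alleles,
              if (x$converged) "" else "  [optimizer did not converge]"))
  invisible(x)
}

#' @export
summary.gp_fit <- function(object, ...) {
  print(object)
  m <- object$b_hat/(1 - object$p_hat)^2
  cat(sprintf("  implied mean offspring m = %.3f; p0 = %.4f; b + p = %.4f\n",
              m, 1 - object$b_hat/(1 - object$p_hat),
              object$b_hat + object$p_hat))
  cat(sprintf("  grid: %d cells, best (b = %g, p = %g), ll = %.3f\n",
              object$trace$grid_cells, object$trace$grid_best["b"],
              object$trace$grid_best["p"], object$trace$grid_loglik))
  invisible(object)
}

#' @export
coef.gp_fit <- function(object, ...) {
  c(b = object$b_hat, p = object$p_hat)
}

#' @export
logLik.gp_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_alleles,
            class = "logLik")
}

#' Fitted spectrum and expected class counts
#'
#' @param object A [fit_gp()] object.
#' @param type `"spectrum"` for the fitted [limit_spectrum()] object,
#'   `"expected"` for expected allele counts `n * Psi_j` over
#'   `j = 1..j_max`.
#' @param j_max Largest class (default 100).
#' @param ... Unused.
#' @return A `"freq_spectrum"` object or a named numeric vector of
#'   expected counts.
#' @export
predict.gp_fit <- function(object, type = c("spectrum", "expected"),
                           j_max = 100L, ...) {
  type <- match.arg(type)
  sp <- limit_spectrum(lf_params(object$b_hat, object$p_hat), mu = object$mu,
                       j_max = j_max, r_tol = object$r_tol,
                       r_max = object$r_max)
  if (type == "spectrum") return(sp)
  stats::setNames(object$n_alleles * sp$psi, seq_len(j_max))
}

#' Pearson residuals of a spectrum fit
#'
#' Residuals `(O - E)/sqrt(E)` over the explicit classes `1..B` plus the
#' combined tail bin, with `B` the largest observed class.
#'
#' @param object A [fit_gp()] object.
#' @param ... Unused.
#' @return Named numeric vector of Pearson residuals; the last element is
#'   the tail bin.
#' @export
residuals.gp_fit <- function(object, ...) {
  B <- max(object$counts$class)
  sp <- predict(object, "spectrum", j_max = B)
  pr <- c(sp$psi, sp$tail_mass)
  O <- numeric(B + 1L)
  O[object$counts$class] <- object$counts$count
  E <- object$n_alleles * pr
  stats::setNames((O - E)/sqrt(E), c(seq_len(B), "tail"))
}

#' Simulate count tables from a fitted spectrum
#'
#' Draws `nsim` allele-class count tables of the same total size as the
#' data from the fitted limit spectrum (parametric bootstrap).
#'
#' @param object A [fit_gp()] object.
#' @param nsim Number of tables.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of [class_counts()] objects.
#' @export
simulate.gp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    generate_counts(lf_params(object$b_hat, object$p_hat), mu = object$mu,
                    n_alleles = object$n_alleles))
}

#' Plot data against the fitted spectrum
#'
#' Class frequencies of the data and the fitted \eqn{\{\Psi_j\}} on a
#' semi-logarithmic scale, the standard display for copy-number spectra.
#'
#' @param x A [fit_gp()] object.
#' @param j_max Largest class displayed (default: largest observed).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gp_fit <- function(x, j_max = NULL, ...) {
  if (is.null(j_max)) j_max <- max(x$counts$class)
  sp <- predict(x, "spectrum", j_max = j_max)
  obs <- numeric(j_max)
  obs[x$counts$class[x$counts$class <= j_max]] <-
    x$counts$count[x$counts$class <= j_max]
  obs <- obs/x$n_alleles
  ylim <- range(c(sp$psi, obs[obs > 0]))
  graphics::plot(seq_len(j_max), sp$psi, log = "y", type = "l", lwd = 2,
                 xlab = "copy-number class j", ylab = "class frequency",
                 ylim = ylim, ...)
  graphics::points(which(obs > 0), obs[obs > 0], pch = 16)
  graphics::legend("topright", c("fitted spectrum", "data"),
                   lty = c(1, NA), pch = c(NA, 16), bty = "n")
  invisible(x)
}
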