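# Vectorized workhorse behind limit_spectrum(), the likelihood grid and
# psi1_surface(). For each parameter pair (b[i], p[i]) it accumulates
#   Num_j = sum_r m^-r h_j^(r),   Den = sum_r m^-r (1 - h0^(r)),
# where h^(r) are the power-series coefficients of the r-th iterate of the
# mutation-thinned pgf H(s) = f(mu + (1-mu)s), and returns psi = Num/Den
# (an n_cell x length(j) matrix over the requested classes j) plus, when
# `tail_beyond` is set, the spectrum mass above that class. All cells are
# iterated in lockstep (one Moebius composition per generation, vectorized
# over cells); a cell retires once the generation's survival-weighted term
# falls below r_tol relative to its running denominator. Cells that are not
# supercritical after thinning, or fail to converge within r_max, come back
# as NA with ok = FALSE.
psi_kernel <- function(b, p, mu, j, r_tol = 1e-9, r_max = 10000L,
                       tail_beyond = NULL) {
  n <- length(b)
  j <- as.numeric(j)
  stopifnot(length(p) == n, n >= 1L, length(j) >= 1L, all(j >= 1))
  m <- b/(1 - p)^2
  ok <- is.finite(m) & (m * (1 - mu) > 1) & b > 0 & p > 0 & p < 1 &
    (b + p <= 1 + 1e-12)
  w_ratio <- ifelse(ok, 1/m, NA_real_)

  # thinned pgf H in canonical (d0 = 1) form, per cell
  p0 <- 1 - b/(1 - p)
  fn1 <- b - p * p0; fn0 <- p0; fd1 <- -p          # f, d0 = 1
  a <- 1 - mu
  hd0 <- 1 + fd1 * mu
  Hn1 <- (fn1 * a)/hd0; Hd1 <- (fd1 * a)/hd0
  Hn0 <- (Hd1 + 1) - Hn1              # exact unit sum: H(1) = 1

  # iterate state G = H^(r), starting at the identity (r = 0)
  Gn1 <- rep(1, n); Gn0 <- rep(0, n); Gd1 <- rep(0, n); Gd0 <- rep(1, n)
  w <- rep(1, n)
  one_col <- which(j == 1)                          # identity mass lands here
  Num <- matrix(0, n, length(j))
  Den <- numeric(n); Tail <- numeric(n)
  active <- ok
  r <- 0L
  while (any(active)) {
    i <- which(active)
    d1 <- Gd1[i]; d0 <- Gd0[i]; n1 <- Gn1[i]; n0 <- Gn0[i]
    aff <- abs(d1) < 1e-14 * abs(d0)
    q <- ifelse(aff, 0, -d1/d0)
    if (any(!aff & (q < 0 | q >= 1))) {            # numerically broken cell
      bad <- i[!aff & (q < 0 | q >= 1)]
      ok[bad] <- FALSE; active[bad] <- FALSE
      i <- which(active)
      if (!length(i)) break
      d1 <- Gd1[i]; d0 <- Gd0[i]; n1 <- Gn1[i]; n0 <- Gn0[i]
      aff <- abs(d1) < 1e-14 * abs(d0)
      q <- ifelse(aff, 0, -d1/d0)
    }
    C <- ifelse(aff, n1/d0, (n0 - n1 * d0/d1)/d0)
    surv <- ifelse(aff, C, C * q/(1 - q))          # 1 - h0^(r)
    wc <- w[i] * C
    # Num[i, ] += w C q^j ; affine rows carry their mass at j = 1
    add <- wc * outer(q, j, `^`)
    if (any(aff)) {
      add[aff, ] <- 0
      if (length(one_col)) add[aff, one_col] <- wc[aff]
    }
    Num[i, ] <- Num[i, ] + add
    if (!is.null(tail_beyond))
      Tail[i] <- Tail[i] +
        ifelse(aff, 0, wc * q^(tail_beyond + 1)/(1 - q))
    Den[i] <- Den[i] + w[i] * surv
    done <- r >= 2L & w[i] * surv < r_tol * Den[i]
    active[i[done]] <- FALSE
    i <- which(active)
    if (!length(i)) break
    r <- r + 1L
    if (r > r_max) {
      ok[i] <- FALSE
      break
    }
    # G <- H o G, canonicalized by the new d0
    nn1 <- Hn1[i] * Gn1[i] + Hn0[i] * Gd1[i]
    nn0 <- Hn1[i] * Gn0[i] + Hn0[i] * Gd0[i]
    nd1 <- Hd1[i] * Gn1[i] + Gd1[i]
    nd0 <- Hd1[i] * Gn0[i] + Gd0[i]
    Gn1[i] <- nn1/nd0
    Gd1[i] <- nd1/nd0; Gd0[i] <- 1
    Gn0[i] <- (Gd1[i] + 1) - Gn1[i]     # re-pin G(1) = 1 every step
    w[i] <- w[i] * w_ratio[i]
  }
  psi <- Num/Den
  tail_mass <- Tail/Den
  psi[!ok, ] <- NA_real_
  tail_mass[!ok] <- NA_real_
  list(psi = psi, tail_mass = tail_mass, ok = ok, r_used = r)
}

#' Limit allele frequency spectrum of the Griffiths-Pakes process
#'
#' Computes the long-run expected proportion \eqn{\Psi_j} of alleles
#' present in exactly `j` copies under the supercritical Galton-Watson
#' process with linear-fractional offspring law and infinite-allele
#' mutation at rate `mu` per particle per generation. The spectrum is the
#' ratio of two sums over clone ages `r`,
#' \deqn{\Psi_j = \frac{\sum_{r\ge 0} m^{-r}\, h_j^{(r)}}
#'                     {\sum_{r\ge 0} m^{-r}\, (1 - h_0^{(r)})},}
#' where \eqn{h_j^{(r)}} is the probability that a clone founded by a
#' single mutant has `j` members `r` generations later (coefficients of
#' the `r`-th iterate of the thinned pgf, exact in the linear-fractional
#' case) and the geometric weight \eqn{m^{-r}} reflects the growth rate of
#' the allele birth process. Both sums are truncated once a generation's
#' relative contribution falls below `r_tol`. Because
#' \eqn{\sum_{j\ge 1} h_j^{(r)} = 1 - h_0^{(r)}}, the spectrum sums to 1
#' exactly up to truncation; the mass beyond `j_max` is reported as
#' `tail_mass`.
#'
#' @param params An [lf_params()] object; must be supercritical after
#'   thinning (`m (1 - mu) > 1`).
#' @param mu Mutation probability per particle per generation
#'   (default `1e-6`).
#' @param j_max Largest copy-number class computed explicitly
#'   (default 100).
#' @param r_tol Relative truncation tolerance for the sums over clone age
#'   (default `1e-9`).
#' @param r_max Hard cap on the number of generations summed
#'   (default 10000).
#' @return An object of class `"freq_spectrum"`: a list with `psi`
#'   (vector of \eqn{\Psi_j}, `j = 1..j_max`), `tail_mass`
#'   (\eqn{1 - \sum_{j \le j_max} \Psi_j}), `params`, `mu` and the
#'   truncation settings.
#' @examples
#' sp <- limit_spectrum(lf_params(0.139, 0.861))
#' sp$psi[1:5]
#' sum(sp$psi) + sp$tail_mass   # 1 up to truncation tolerance
#' @export
limit_spectrum <- function(params, mu = 1e-6, j_max = 100L,
                           r_tol = 1e-9, r_max = 10000L) {
  stopifnot(inherits(params, "lf_params"))
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu < 1)
  stopifnot(j_max >= 1L, r_tol > 0, r_max >= 1L)
  if (!is_supercritical(params, mu))
    stop("limit_spectrum: process is not supercritical after thinning ",
         "(m(1-mu) <= 1); the limit spectrum requires b > (1-p)^2",
         call. = FALSE)
  k <- psi_kernel(params$b, params$p, mu, j = seq_len(j_max),
                  r_tol = r_tol, r_max = as.integer(r_max),
                  tail_beyond = j_max)
  if (!k$ok)
    stop("limit_spectrum: generation sums did not converge within r_max = ",
         r_max, " (last r = ", k$r_used, "); increase r_max or r_tol",
         call. = FALSE)
  structure(list(psi = drop(k$psi), tail_mass = k$tail_mass,
                 params = params, mu = mu, j_max = as.integer(j_max),
                 r_tol = r_tol, r_used = k$r_used),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("Limit allele frequency spectrum (b = %g, p = %g, mu = %g)\n",
              x$params$b, x$params$p, x$mu))
  show <- utils::head(x$psi, 8)
  cat("  Psi_1..:", paste(signif(show, 4), collapse = " "), "...\n")
  cat(sprintf("  classes 1..%d, tail mass beyond: %.3g\n",
              x$j_max, x$tail_mass))
  invisible(x)
}

#' @export
plot.freq_spectrum <- function(x, log = "y", xlab = "copy-number class j",
                               ylab = expression(Psi[j]), ...) {
  graphics::plot(seq_along(x$psi), x$psi, log = log, type = "b", pch = 16,
                 cex = 0.6, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Singleton-class probability over a parameter grid
#'
#' Evaluates \eqn{\Psi_1}, the limit proportion of single-copy alleles,
#' over a grid of `(b, p)` values, e.g. for contour plotting. Grid cells
#' outside the valid supercritical parameter region come back as `NA`
#' rather than raising an error.
#'
#' @param b_grid,p_grid Numeric vectors of grid coordinates in `(0, 1)`.
#' @param mu Mutation probability (default `1e-6`).
#' @param r_tol,r_max Truncation controls as in [limit_spectrum()].
#' @return A `length(b_grid) x length(p_grid)` matrix of \eqn{\Psi_1}
#'   values with `dimnames` carrying the grid coordinates.
#' @examples
#' psi1_surface(c(0.016, 0.139), c(0.861, 0.983))
#' @export
psi1_surface <- function(b_grid, p_grid, mu = 1e-6,
                         r_tol = 1e-9, r_max = 10000L) {
  stopifnot(is.numeric(b_grid), is.numeric(p_grid),
            length(b_grid) >= 1L, length(p_grid) >= 1L)
  bb <- rep(b_grid, times = length(p_grid))
  pp <- rep(p_grid, each = length(b_grid))
  k <- psi_kernel(bb, pp, mu, j = 1L, r_tol = r_tol,
                  r_max = as.integer(r_max))
  matrix(k$psi[, 1L], nrow = length(b_grid), ncol = length(p_grid),
         dimnames = list(b = format(b_grid), p = format(p_grid)))
}
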