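#' Moebius (linear-fractional) maps
#'
#' A Moebius map \eqn{s \mapsto (n_1 s + n_0)/(d_1 s + d_0)} represented by
#' its four coefficients. The linear-fractional offspring pgf, its mutation
#' thinning and all of its functional iterates belong to this family, which
#' is closed under composition (composition is the product of the 2x2
#' coefficient matrices), so generation-`r` clone-size distributions are
#' available in closed form.
#'
#' Maps are kept in a canonical form: coefficients are divided by `d0`
#' (or, if `d0` is negligible, by the largest-magnitude coefficient) so that
#' equality tests are well defined and repeated composition neither
#' overflows nor underflows.
#'
#' @param n1,n0,d1,d0 Real coefficients of the map.
#' @return An object of class `"mobius"`: a named numeric vector
#'   `c(n1, n0, d1, d0)` in canonical form.
#' @seealso [lf_pgf()], [mobius_compose()], [mobius_iterate()],
#'   [iterate_pmf()]
#' @examples
#' f <- lf_pgf(lf_params(0.139, 0.861))
#' mobius_eval(f, 1)       # pgf normalization: 1
#' mobius_eval(f, 0)       # p0
#' @export
mobius_map <- function(n1, n0, d1, d0) {
  co <- c(n1 = n1, n0 = n0, d1 = d1, d0 = d0)
  stopifnot(is.numeric(co), length(co) == 4L, all(is.finite(co)))
  det <- n1 * d0 - n0 * d1
  if (abs(det) <= 1e-14 * max(abs(co), 1))
    stop("mobius_map: degenerate map (determinant ~ 0)", call. = FALSE)
  mobius_canonical(co)
}

# divide through by d0, or by the largest coefficient when |d0| ~ 0
mobius_canonical <- function(co) {
  scale <- co[["d0"]]
  if (abs(scale) < 1e-12 * max(abs(co))) scale <- co[[which.max(abs(co))]]
  structure(co / scale, class = "mobius")
}

#' @export
print.mobius <- function(x, ...) {
  cat(sprintf("Moebius map: s -> (%g s + %g) / (%g s + %g)\n",
              x[["n1"]], x[["n0"]], x[["d1"]], x[["d0"]]))
  invisible(x)
}

#' Evaluate a Moebius map
#'
#' Maps flagged as pgfs (as produced by [lf_pgf()], [mutation_thin()] and
#' [mobius_iterate()] of a pgf) return exactly 1 at `s = 1`: mass
#' conservation is an exact analytic property of every pgf, while for
#' strongly supercritical maps under many iterations the four-coefficient
#' representation cannot resolve the repelling fixed point at 1 in double
#' precision (its signature decays like `m^-r`).
#'
#' @param f A `"mobius"` object.
#' @param s Numeric vector of arguments.
#' @return `(n1*s + n0) / (d1*s + d0)`, vectorized over `s`.
#' @export
mobius_eval <- function(f, s) {
  stopifnot(inherits(f, "mobius"), is.numeric(s))
  out <- (f[["n1"]] * s + f[["n0"]]) / (f[["d1"]] * s + f[["d0"]])
  if (isTRUE(attr(f, "pgf"))) out[s == 1] <- 1
  out
}

# is this map (numerically) a probability generating function?
is_pgf_map <- function(f) {
  isTRUE(attr(f, "pgf")) || {
    v <- (f[["n1"]] + f[["n0"]]) / (f[["d1"]] + f[["d0"]])
    is.finite(v) && abs(v - 1) < 1e-9
  }
}

flag_pgf <- function(f) {
  attr(f, "pgf") <- TRUE
  f
}

#' Compose two Moebius maps
#'
#' Returns the map `s -> f(g(s))`, computed exactly at the coefficient
#' level as the product of the two 2x2 coefficient matrices, then
#' canonicalized.
#'
#' @param f,g `"mobius"` objects.
#' @return The composite `"mobius"` map.
#' @export
mobius_compose <- function(f, g) {
  stopifnot(inherits(f, "mobius"), inherits(g, "mobius"))
  mobius_canonical(c(
    n1 = f[["n1"]] * g[["n1"]] + f[["n0"]] * g[["d1"]],
    n0 = f[["n1"]] * g[["n0"]] + f[["n0"]] * g[["d0"]],
    d1 = f[["d1"]] * g[["n1"]] + f[["d0"]] * g[["d1"]],
    d0 = f[["d1"]] * g[["n0"]] + f[["d0"]] * g[["d0"]]))
}

#' The identity Moebius map
#' @return The `"mobius"` map `s -> s` (the pgf of a unit point mass).
#' @export
mobius_identity <- function() {
  flag_pgf(structure(c(n1 = 1, n0 = 0, d1 = 0, d0 = 1), class = "mobius"))
}

#' Offspring pgf of the linear-fractional law as a Moebius map
#'
#' The pgf \deqn{f(s) = 1 - \frac{b}{1-p} + \frac{b s}{1 - p s}} whose
#' power-series coefficients are the [offspring_pmf()] and whose derivative
#' at 1 is the mean \eqn{b/(1-p)^2}.
#'
#' @param params An [lf_params()] object.
#' @return A `"mobius"` object representing the pgf.
#' @export
lf_pgf <- function(params) {
  stopifnot(inherits(params, "lf_params"))
  b <- params$b; p <- params$p
  p0 <- 1 - b/(1 - p)
  # (1 - ps) * p0 + b s over (1 - ps); n0 is pinned so that the unit-sum
  # identity n1 + n0 = d1 + d0 (i.e. f(1) = 1) holds exactly in floating
  # point -- s = 1 is a repelling fixed point of supercritical pgfs, so a
  # one-ulp violation would be amplified by m^r under iteration
  n1 <- b - p * p0
  flag_pgf(pgf_repin(mobius_canonical(c(n1 = n1, n0 = p0, d1 = -p,
                                        d0 = 1))))
}

# pin n0 so that n1 + n0 == d1 + d0 exactly in floating point (pgf maps
# only); moves n0 by at most one ulp but keeps s = 1 an exact fixed point
pgf_repin <- function(g) {
  g[["n0"]] <- (g[["d1"]] + g[["d0"]]) - g[["n1"]]
  g
}

#' Mutation thinning of an offspring pgf
#'
#' Under infinite-allele mutation each offspring keeps the parental allele
#' independently with probability `1 - mu`, so the pgf of same-allele
#' descendants is the affine substitution `H(s) = f(mu + (1 - mu) s)`,
#' again a Moebius map (exact, coefficient level). Its mean is
#' `M = m (1 - mu)`.
#'
#' @param f A `"mobius"` pgf.
#' @param mu Per-particle, per-generation mutation probability in `[0, 1)`.
#' @return The thinned pgf as a `"mobius"` object.
#' @export
mutation_thin <- function(f, mu) {
  stopifnot(inherits(f, "mobius"))
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (mu < 0 || mu >= 1)
    stop("mutation_thin: 'mu' must lie in [0, 1)", call. = FALSE)
  a <- 1 - mu
  out <- mobius_canonical(c(n1 = f[["n1"]] * a,
                            n0 = f[["n0"]] + f[["n1"]] * mu,
                            d1 = f[["d1"]] * a,
                            d0 = f[["d0"]] + f[["d1"]] * mu))
  # a pgf input keeps s = 1 an exact fixed point (see pgf_repin)
  if (is_pgf_map(f)) out <- flag_pgf(pgf_repin(out))
  out
}

#' Functional iterate of a Moebius map
#'
#' Computes the `r`-fold composition `f^(r)` exactly via repeated
#' coefficient-matrix multiplication with canonical rescaling at every
#' step. `r = 0` gives the identity map. For a pgf this is the pgf of the
#' generation-`r` clone size.
#'
#' @param f A `"mobius"` object.
#' @param r Nonnegative integer number of iterations.
#' @return The iterated `"mobius"` map.
#' @export
mobius_iterate <- function(f, r) {
  stopifnot(inherits(f, "mobius"))
  stopifnot(is.numeric(r), length(r) == 1L, r == floor(r))
  if (r < 0) stop("mobius_iterate: 'r' must be >= 0", call. = FALSE)
  g <- mobius_identity()
  if (r == 0) return(g)
  # for pgfs, re-pin f(1) = 1 after every composition: s = 1 is a
  # repelling fixed point of supercritical maps and a one-ulp violation
  # would otherwise grow like m^r along the iteration
  is_pgf <- is_pgf_map(f)
  for (i in seq_len(r)) {
    g <- mobius_compose(f, g)
    if (is_pgf) g <- pgf_repin(g)
  }
  if (is_pgf) g <- flag_pgf(g)
  g
}

#' Power-series coefficients of a Moebius pgf
#'
#' For a probability generating function in Moebius form the power series
#' is an atom at zero plus a geometric tail, obtained exactly by
#' partial-fraction expansion:
#' \deqn{g(s) = \frac{n_1}{d_1} + \frac{\beta}{d_1 s + d_0}
#'  \;\Rightarrow\; h_0 = n_1/d_1 + \beta/d_0,\quad
#'  h_j = (\beta/d_0)\, q^j,\ q = -d_1/d_0.}
#' Affine maps (`d1 = 0`, e.g. the identity iterate) are handled as a
#' two-point mass on `{0, 1}`.
#'
#' @param f_r A `"mobius"` pgf (typically an iterate from
#'   [mobius_iterate()]).
#' @param j_max Largest population size to tabulate (`>= 0`).
#' @return Numeric vector of probabilities `P[Z_r = j]` for
#'   `j = 0, ..., j_max`.
#' @examples
#' th <- lf_params(0.139, 0.861)
#' # one iterate reproduces the offspring pmf
#' all.equal(iterate_pmf(lf_pgf(th), 6), unname(offspring_pmf(th, 6)))
#' @export
iterate_pmf <- function(f_r, j_max) {
  stopifnot(inherits(f_r, "mobius"))
  stopifnot(is.numeric(j_max), length(j_max) == 1L, j_max >= 0,
            j_max == floor(j_max))
  co <- mobius_series(f_r)
  out <- numeric(j_max + 1L)
  out[1L] <- co$h0
  if (j_max >= 1L) {
    if (co$affine) out[2L] <- co$C
    else out[1L + seq_len(j_max)] <- co$C * co$q^seq_len(j_max)
  }
  names(out) <- 0:j_max
  out
}

# atom/geometric decomposition shared by iterate_pmf and the spectrum kernel
mobius_series <- function(g) {
  n1 <- g[["n1"]]; n0 <- g[["n0"]]; d1 <- g[["d1"]]; d0 <- g[["d0"]]
  if (abs(d1) < 1e-14 * abs(d0)) {
    list(h0 = n0/d0, C = n1/d0, q = 0, affine = TRUE)
  } else {
    q <- -d1/d0
    if (q >= 1) {
      # ratio collapsed to 1: the map has numerically degenerated to its
      # constant limit (high iterate of a supercritical pgf); the mass not
      # at zero is spread over unboundedly large sizes
      return(list(h0 = n0/d0, C = 0, q = 0, affine = TRUE))
    }
    if (q < 0)
      stop("mobius_series: map is not a pgf (geometric ratio ", format(q),
           " negative)", call. = FALSE)
    C <- (n0 - n1 * d0/d1)/d0
    list(h0 = n1/d1 + C, C = C, q = q, affine = FALSE)
  }
}
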