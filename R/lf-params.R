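#' Linear-fractional offspring-law parameters
#'
#' Constructs and validates the parameter pair of the linear-fractional
#' (geometric-tail) Galton-Watson offspring distribution
#' \deqn{p_0 = 1 - b/(1-p), \qquad p_k = b\,p^{k-1} \quad (k \ge 1).}
#' `b` is the probability weight of the geometric tail and `p` its common
#' ratio. A proper distribution requires `0 < p < 1`, `b > 0` and
#' `b + p <= 1` (so that `p_0 >= 0`). The boundary `b + p = 1` (no
#' zero-offspring mass) is allowed; `p = 1` and `b = 0` are rejected as
#' degenerate.
#'
#' @param b Probability weight of the geometric tail, `0 < b <= 1 - p`.
#' @param p Geometric ratio, `0 < p < 1`.
#'
#' @return An object of class `"lf_params"`: a named list with elements
#'   `b` and `p`.
#' @seealso [mean_offspring()], [offspring_pmf()], [lf_pgf()]
#' @examples
#' th <- lf_params(b = 0.139, p = 0.861)
#' mean_offspring(th)       # b / (1-p)^2
#' is_supercritical(th)
#' @export
lf_params <- function(b, p) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(p), length(p) == 1L)
  if (!is.finite(b) || !is.finite(p))
    stop("lf_params: 'b' and 'p' must be finite", call. = FALSE)
  if (p <= 0 || p >= 1)
    stop("lf_params: constraint 0 < p < 1 violated (p = ", format(p), ")",
         call. = FALSE)
  if (b <= 0)
    stop("lf_params: constraint b > 0 violated (b = ", format(b), ")",
         call. = FALSE)
  if (b + p > 1 + 1e-12)
    stop("lf_params: constraint b + p <= 1 violated (b + p = ",
         format(b + p), ")", call. = FALSE)
  structure(list(b = b, p = p), class = "lf_params")
}

#' @export
print.lf_params <- function(x, ...) {
  m <- mean_offspring(x)
  cat("Linear-fractional offspring law\n")
  cat(sprintf("  b = %g, p = %g  (p0 = %g)\n", x$b, x$p, 1 - x$b/(1 - x$p)))
  cat(sprintf("  mean offspring m = %g (%s)\n", m,
              if (m > 1) "supercritical" else if (m == 1) "critical"
              else "subcritical"))
  invisible(x)
}

#' Mean offspring number of the linear-fractional law
#'
#' The mean is \eqn{m = b/(1-p)^2}; the process is supercritical
#' (\eqn{m > 1}) exactly when \eqn{b > (1-p)^2}.
#'
#' @param params An [lf_params()] object.
#' @return The mean offspring number, a positive scalar.
#' @export
mean_offspring <- function(params) {
  stopifnot(inherits(params, "lf_params"))
  params$b / (1 - params$p)^2
}

#' Is the offspring law supercritical?
#'
#' @param params An [lf_params()] object.
#' @param mu Optional mutation probability; when supplied the criterion is
#'   applied to the mutation-thinned mean `M = m * (1 - mu)`.
#' @return `TRUE` iff the (thinned) mean offspring number exceeds 1.
#' @export
is_supercritical <- function(params, mu = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu < 1)
  mean_offspring(params) * (1 - mu) > 1
}

#' Offspring probability mass function
#'
#' Closed-form pmf of the linear-fractional law: an atom
#' `p0 = 1 - b/(1-p)` at zero and a geometric tail `p_k = b p^(k-1)` for
#' `k >= 1`. The partial sum approaches 1 with geometric remainder
#' `b p^k_max / (1 - p)`.
#'
#' @param params An [lf_params()] object.
#' @param k_max Largest offspring count to tabulate (`>= 0`).
#' @return Numeric vector of probabilities for `k = 0, ..., k_max`.
#' @examples
#' offspring_pmf(lf_params(0.139, 0.861), 5)
#' @export
offspring_pmf <- function(params, k_max) {
  stopifnot(inherits(params, "lf_params"))
  stopifnot(is.numeric(k_max), length(k_max) == 1L, k_max >= 0,
            k_max == floor(k_max))
  b <- params$b; p <- params$p
  pk <- c(1 - b/(1 - p), if (k_max >= 1) b * p^(seq_len(k_max) - 1))
  names(pk) <- 0:k_max
  pk
}
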