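#' Draw offspring counts from the linear-fractional law
#'
#' Exact inverse-CDF-free sampling using the law's mixture structure: an
#' atom at zero with probability `p0 = 1 - b/(1-p)` and, otherwise,
#' `1 + Geometric(1 - p)` (unbounded support, no truncation bias).
#'
#' @param n Number of draws.
#' @param params An [lf_params()] object.
#' @return Integer vector of offspring counts.
#' @export
rlinfrac <- function(n, params) {
  stopifnot(inherits(params, "lf_params"))
  p0 <- 1 - params$b/(1 - params$p)
  k <- integer(n)
  nz <- stats::runif(n) >= p0
  k[nz] <- 1L + stats::rgeom(sum(nz), 1 - params$p)
  k
}

#' Forward simulation of the branching process with infinite alleles
#'
#' Simulates the discrete-time Galton-Watson process with
#' linear-fractional offspring and infinite-allele mutation: every
#' particle draws an offspring count from the offspring law; each
#' offspring independently keeps the parental allele with probability
#' `1 - mu` or founds a brand-new, never-seen-before allele with
#' probability `mu`. The per-generation census of every allele's copy
#' number is recorded. Mutation relabels particles, so the total
#' offspring drawn in generation `t` equals the population size of
#' generation `t + 1` exactly.
#'
#' Runs whose population exceeds `pop_cap` stop early and are flagged
#' (`capped = TRUE`) with the census up to the last completed generation.
#'
#' @param params An [lf_params()] object.
#' @param mu Mutation probability per offspring particle in `[0, 1)`.
#' @param generations Number of generations to simulate (`>= 0`).
#' @param init_copies Founder particles of the ancestral allele
#'   (default 1).
#' @param pop_cap Abort threshold on total population size
#'   (default `1e6`).
#' @param seed Optional RNG seed.
#' @return An object of class `"allele_census"`: a list with
#'   `generations` (list, one element per recorded generation, each a
#'   list of integer vectors `id` and `copies` for alleles alive or just
#'   gone extinct), `birth_gen` (named by allele id), `totals` (total
#'   copies per generation), `offspring_totals` (total offspring drawn
#'   per transition), `capped`, `params`, `mu`.
#' @examples
#' cen <- simulate_gp(lf_params(0.25, 0.6), mu = 0.01, generations = 8,
#'                    seed = 1)
#' empirical_spectrum(cen)
#' @export
simulate_gp <- function(params, mu, generations, init_copies = 1L,
                        pop_cap = 1e6, seed = NULL) {
  stopifnot(inherits(params, "lf_params"))
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu < 1)
  stopifnot(generations >= 0, generations == floor(generations))
  stopifnot(init_copies >= 1, init_copies == floor(init_copies))
  stopifnot(pop_cap > init_copies)
  if (!is.null(seed)) set.seed(seed)

  ids <- 1L
  copies <- as.numeric(init_copies)
  birth_gen <- c(`1` = 0L)
  next_id <- 2L
  gens <- vector("list", generations + 1L)
  gens[[1L]] <- list(id = ids, copies = copies)
  totals <- sum(copies)
  off_totals <- numeric(0)
  capped <- FALSE

  for (g in seq_len(generations)) {
    tot <- sum(copies)
    if (tot == 0) {                       # extinct: empty censuses onward
      gens[[g + 1L]] <- list(id = integer(0), copies = numeric(0))
      totals <- c(totals, 0); off_totals <- c(off_totals, 0)
      next
    }
    if (tot > pop_cap) { capped <- TRUE; break }
    # one offspring draw per particle, grouped back by allele
    alive <- copies > 0
    owner <- rep.int(seq_along(copies)[alive], copies[alive])
    off <- rlinfrac(length(owner), params)
    off_by_allele <- numeric(length(copies))
    if (length(owner))
      off_by_allele[sort(unique(owner))] <-
        rowsum(as.numeric(off), owner)[, 1L]
    # each offspring mutates independently with probability mu
    mut <- stats::rbinom(length(copies), size = off_by_allele, prob = mu)
    copies <- off_by_allele - mut
    n_new <- sum(mut)
    if (n_new > 0) {
      new_ids <- seq.int(next_id, next_id + n_new - 1L)
      ids <- c(ids, new_ids)
      copies <- c(copies, rep(1, n_new))
      birth_gen <- c(birth_gen, stats::setNames(rep(g, n_new), new_ids))
      next_id <- next_id + n_new
    }
    keep <- copies > 0
    gens[[g + 1L]] <- list(id = ids[keep], copies = copies[keep])
    totals <- c(totals, sum(copies))
    off_totals <- c(off_totals, sum(off_by_allele) + 0) # == sum(off)
    # drop extinct alleles from the working state (ids never reused)
    ids <- ids[keep]; copies <- copies[keep]
  }
  gens <- gens[!vapply(gens, is.null, logical(1))]
  structure(list(generations = gens, birth_gen = birth_gen,
                 totals = totals, offspring_totals = off_totals,
                 capped = capped, params = params, mu = mu),
            class = "allele_census")
}

#' @export
print.allele_census <- function(x, ...) {
  ng <- length(x$generations) - 1L
  last <- x$generations[[length(x$generations)]]
  cat(sprintf("Allele census: %d generations%s\n", ng,
              if (x$capped) " (stopped at pop_cap)" else ""))
  cat(sprintf("  final population %g, alive alleles %d, alleles ever %d\n",
              x$totals[length(x$totals)], length(last$id),
              length(x$birth_gen)))
  invisible(x)
}

#' Empirical allele-class spectrum of a simulated census
#'
#' Proportion of currently-alive alleles (copy number >= 1) having
#' exactly `j` copies at a given generation; the simulator-side estimate
#' of the limit spectrum.
#'
#' @param census An `"allele_census"` from [simulate_gp()].
#' @param generation Generation to tabulate (default: last recorded).
#' @return Named numeric vector of class proportions for
#'   `j = 1..max(copies)`; length zero (with a warning) if no allele is
#'   alive.
#' @export
empirical_spectrum <- function(census, generation = NULL) {
  stopifnot(inherits(census, "allele_census"))
  ng <- length(census$generations) - 1L
  if (is.null(generation)) generation <- ng
  stopifnot(generation >= 0, generation <= ng)
  cp <- census$generations[[generation + 1L]]$copies
  cp <- cp[cp >= 1]
  if (!length(cp)) {
    warning("empirical_spectrum: no alive alleles (extinct run)")
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- tabulate(cp, nbins = max(cp))
  stats::setNames(tab/length(cp), seq_len(max(cp)))
}

#' Sample a synthetic count table from the limit spectrum
#'
#' Draws `n_alleles` independent classes from \eqn{\{\Psi_j\}} (one
#' multinomial draw over classes `1..j_max`, with `j_max` grown until the
#' tail mass is negligible) and returns the resulting allele-class count
#' table. Used for parameter-recovery and calibration experiments.
#'
#' @param params An [lf_params()] object (supercritical after thinning).
#' @param mu Mutation probability (default `1e-6`).
#' @param n_alleles Number of alleles to draw (`>= 1`).
#' @param seed Optional RNG seed.
#' @param label Optional label for the table.
#' @return A [class_counts()] object.
#' @examples
#' generate_counts(lf_params(0.10, 0.88), n_alleles = 1000, seed = 1)
#' @export
generate_counts <- function(params, mu = 1e-6, n_alleles, seed = NULL,
                            label = NULL) {
  stopifnot(inherits(params, "lf_params"))
  if (missing(n_alleles) || n_alleles < 1 || n_alleles != floor(n_alleles))
    stop("generate_counts: 'n_alleles' must be a positive integer",
         call. = FALSE)
  if (!is_supercritical(params, mu))
    stop("generate_counts: parameters not supercritical after thinning",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  j_max <- 200L
  repeat {
    sp <- limit_spectrum(params, mu = mu, j_max = j_max)
    if (sp$tail_mass < 1e-9 || j_max >= 20000L) break
    j_max <- j_max * 4L
  }
  pr <- c(sp$psi, sp$tail_mass)
  draw <- stats::rmultinom(1L, size = n_alleles, prob = pr)[, 1L]
  # an (astronomically rare) tail draw is recorded as class j_max + 1
  cls <- which(draw > 0)
  class_counts(cls, draw[cls], label = label)
}
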