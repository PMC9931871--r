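#' Solve for the critical fitness difference beta*
#'
#' The critical fitness difference of an accessibility setup is the unique
#' root in `t` of the divergence-weighted mean Gamma,
#' \deqn{\langle \Gamma_{a_l b_l}(\beta^*) \rangle_p = 0.}
#' Below `beta*` the expected number of quasi-accessible walks between the
#' endpoints decays exponentially in `L` and accessibility vanishes; above
#' it the expectation explodes, and for setups of regular type `beta*` is
#' the true percolation threshold. Because `beta*` is a quantile difference
#' of uniform fitness values it is only attainable when `beta* <= 1`; larger
#' roots mean the endpoint pair can never be accessible at linear distance,
#' which is reported via `accessible` (a flag, never a clamp).
#'
#' Strict monotonicity of the mean Gamma guarantees a unique root. The
#' solver brackets it starting from `t = 1` (halving the lower edge until
#' the mean is negative, doubling the upper until positive, with a cap of
#' 2^60), runs Brent's method, and polishes with Newton steps using the
#' analytic derivative until `|mean Gamma| <= 1e-12`.
#'
#' @param setup an [accessibility_setup()].
#' @param use_finite_L solve with the finite-`L` weights `M / L` instead of
#'   the divergence matrix, giving the finite-size root `beta_hat`
#'   (requires `M` in the setup).
#' @return An object of class `threshold_result`: a list with `beta_star`,
#'   `gamma_prime_star`, `gamma_double_prime_star`, `walk_length_factor`
#'   (`beta* x Gamma'*`, the expected number of mutational steps per locus
#'   on critical accessible walks), `beta_hat` (finite-`L` root or `NA`),
#'   `accessible` (`beta* <= 1`), `residual` and `delta`.
#' @examples
#' solve_beta_star(setup_hamming(graph_complete(2), delta = 1))
#' @export
solve_beta_star <- function(setup, use_finite_L = FALSE) {
  assert_setup(setup)
  weights <- if (use_finite_L) "finite" else "asymptotic"
  root <- mean_gamma_root(setup, weights)
  g1 <- mean_gamma(setup, root, order = 1, weights = weights)
  g2 <- mean_gamma(setup, root, order = 2, weights = weights)
  beta_hat <- NA_real_
  if (!is.null(setup$M)) {
    beta_hat <- if (use_finite_L) root else mean_gamma_root(setup, "finite")
  }
  structure(
    list(
      beta_star = root,
      gamma_prime_star = g1,
      gamma_double_prime_star = g2,
      walk_length_factor = root * g1,
      beta_hat = beta_hat,
      accessible = root <= 1,
      residual = mean_gamma(setup, root, order = 0, weights = weights),
      delta = setup$delta,
      setup = setup
    ),
    class = "threshold_result"
  )
}

mean_gamma_root <- function(setup, weights, tol = 1e-12) {
  f <- function(t) mean_gamma(setup, t, order = 0, weights = weights)
  lo <- 1
  hi <- 1
  it <- 0
  while (f(lo) >= 0) {
    lo <- lo / 2
    it <- it + 1
    if (it > 60) abort("root bracketing failed (lower edge).",
                       class = "accperc_numerical")
  }
  it <- 0
  while (f(hi) <= 0) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) abort("root bracketing failed (upper edge).",
                       class = "accperc_numerical")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  # Newton polish on the analytic derivative
  for (k in 1:8) {
    val <- f(root)
    if (abs(val) <= tol) break
    d <- mean_gamma(setup, root, order = 1, weights = weights)
    step <- val / d
    cand <- root - step
    if (!is.finite(cand) || cand <= 0) break
    root <- cand
  }
  if (abs(f(root)) > tol) {
    abort("root refinement did not reach tolerance.",
          class = "accperc_numerical")
  }
  root
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    paste0("<threshold_result>\n  beta* = %.6f (%s)\n  Gamma'* = %.6f, ",
           "Gamma''* = %.6f\n  walk-length factor beta* Gamma'* = %.6f\n"),
    x$beta_star,
    if (x$accessible) "accessible regime exists" else "> 1: never accessible",
    x$gamma_prime_star, x$gamma_double_prime_star, x$walk_length_factor))
  if (!is.na(x$beta_hat)) cat(sprintf("  finite-L root beta_hat = %.6f\n", x$beta_hat))
  invisible(x)
}

#' Closed-form thresholds for complete and no-return graphs
#'
#' For the complete graph on `n` alleles at full relative distance,
#' `exp(beta*)` is the unique root greater than 1 of the polynomial
#' \eqn{x^n - n x - 1 = 0}; `beta_star_complete_poly()` solves that
#' polynomial directly, independent of the matrix-exponential route. For the
#' complete graph with arrows into the wild type removed,
#' `beta_star_no_return()` returns the closed forms
#' \eqn{\beta^* = \ln(n - 1) / (n - 2)} and \eqn{\Gamma'^* = n - 1}, with
#' the biallelic limit `(1, 1)` (the directed hypercube, which is thus
#' marginally accessible).
#'
#' @param n allele count, at least 2.
#' @return `beta_star_complete_poly()`: a single number.
#'   `beta_star_no_return()`: named vector `c(beta_star, gamma_prime_star)`.
#' @examples
#' beta_star_complete_poly(2) # log(1 + sqrt(2))
#' beta_star_no_return(3)     # c(log(2), 2)
#' @export
beta_star_complete_poly <- function(n) {
  n <- check_allele_count(n)
  f <- function(x) x^n - n * x - 1
  hi <- 2
  while (f(hi) <= 0) hi <- hi * 2
  x <- uniroot(f, c(1, hi), tol = 1e-15)$root
  # Newton polish
  for (k in 1:6) x <- x - (x^n - n * x - 1) / (n * x^(n - 1) - n)
  log(x)
}

#' @rdname beta_star_complete_poly
#' @export
beta_star_no_return <- function(n) {
  n <- check_allele_count(n)
  if (n == 2L) {
    c(beta_star = 1, gamma_prime_star = 1)
  } else {
    c(beta_star = log(n - 1) / (n - 2), gamma_prime_star = n - 1)
  }
}

#' Finite-size threshold function c_L
#'
#' Location of the accessibility transition at `L` loci,
#' \deqn{c_L = \hat\beta - \Gamma'(\hat\beta)^{-1} \ln L / L,}
#' where `beta_hat` is the finite-`L` root when a counting matrix is
#' attached to the setup and the asymptotic root `beta*` otherwise (in which
#' case this is the bounded-remainder form `beta* - Gamma'*^{-1} (ln L)/L`
#' up to the order-1/L window). The transition window around `c_L` is of
#' order `1/L`, so `c_L -> beta*` and no sharper error is resolved.
#'
#' @param setup an [accessibility_setup()].
#' @param L number of loci, at least 2.
#' @return A single number.
#' @examples
#' threshold_c_L(setup_hamming(graph_complete(2), delta = 1), L = 100)
#' @export
threshold_c_L <- function(setup, L) {
  assert_setup(setup)
  L <- as.integer(L)
  if (is.na(L) || L < 2L) {
    abort("`L` must be an integer >= 2.", class = "accperc_domain")
  }
  use_finite <- !is.null(setup$M)
  weights <- if (use_finite) "finite" else "asymptotic"
  root <- mean_gamma_root(setup, weights)
  g1 <- mean_gamma(setup, root, order = 1, weights = weights)
  root - log(L) / (g1 * L)
}

#' Walk-length moments per locus
#'
#' At fitness difference `beta` the lengths of quasi-accessible walks
#' concentrate (per locus) around
#' \deqn{\mu = \beta\,\Gamma'(\beta), \qquad
#'       \sigma^2 = \beta\,\Gamma'(\beta) + \beta^2\,\Gamma''(\beta),}
#' with `Gamma` the divergence-weighted mean. At the critical point the
#' total walk length is `mu * L` with fluctuations of order `sqrt(L)`; the
#' excess of `mu` over the per-locus distance is the fraction of reversions
#' and sideways steps.
#'
#' @param setup an [accessibility_setup()].
#' @param beta fitness difference, strictly positive.
#' @return A one-row tibble with columns `beta`, `mu_per_locus` and
#'   `sigma2_per_locus`.
#' @examples
#' s <- setup_hamming(graph_complete(2), delta = 1)
#' walk_length_moments(s, beta = solve_beta_star(s)$beta_star)
#' @export
walk_length_moments <- function(setup, beta) {
  assert_setup(setup)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    abort("`beta` must be a single positive number.", class = "accperc_domain")
  }
  g1 <- mean_gamma(setup, beta, order = 1)
  g2 <- mean_gamma(setup, beta, order = 2)
  tibble(
    beta = beta,
    mu_per_locus = beta * g1,
    sigma2_per_locus = beta * g1 + beta^2 * g2
  )
}
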