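#' Expected number of quasi-accessible walks
#'
#' Quasi-accessible walks are walks counted with revisited genotypes
#' re-randomized, which makes their expectation exactly summable: a walk of
#' length `N` is quasi-accessible with probability
#' \eqn{\beta^{N-1}/(N-1)!}, and summing over all walks between the
#' endpoints yields the closed form
#' \deqn{E[\tilde Z] = L\, \Gamma'(\beta)\, e^{L \Gamma(\beta)}}
#' with `Gamma` the locus-averaged (divergence- or counting-weighted) log
#' matrix-exponential entry. Existence of a quasi-accessible walk is
#' equivalent to existence of an accessible (self-avoiding) path, so this
#' expectation controls the lower side of the percolation threshold.
#'
#' @param setup an [accessibility_setup()].
#' @param L number of loci. Ignored when `pair` is given (then `L` is the
#'   pair's length).
#' @param beta fitness difference, strictly positive.
#' @param pair optional [genotype_pair()]; when supplied the locus average
#'   uses the pair's exact counting matrix instead of the setup's divergence
#'   matrix.
#' @return A single number.
#' @examples
#' s <- setup_hamming(graph_complete(2), delta = 1)
#' expected_quasi_accessible(s, L = 1, beta = 1) # = cosh(1)
#' @export
expected_quasi_accessible <- function(setup, L, beta, pair = NULL) {
  assert_setup(setup)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    abort("`beta` must be a single positive number.", class = "accperc_domain")
  }
  if (!is.null(pair)) {
    setup <- accessibility_setup(setup$graph, pair = pair)
    L <- pair$L
    weights <- "finite"
  } else {
    weights <- "asymptotic"
  }
  L <- as.integer(L)
  if (is.na(L) || L < 1L) {
    abort("`L` must be a positive integer.", class = "accperc_domain")
  }
  g0 <- mean_gamma(setup, beta, order = 0, weights = weights)
  g1 <- mean_gamma(setup, beta, order = 1, weights = weights)
  L * g1 * exp(L * g0)
}

#' Brute-force walk-enumeration oracle for the quasi-accessible expectation
#'
#' Evaluates the defining series of the quasi-accessible walk expectation by
#' explicit dynamic programming on the Cartesian power genotype space: the
#' number of walks of each length `N <= n_max` from `a` to `b` is counted by
#' propagating along product-graph arrows, and each count is weighted by
#' \eqn{\beta^{N-1}/(N-1)!}. This is deliberately independent of the
#' matrix-exponential closed form and converges to it monotonically from
#' below as `n_max` grows (all terms are nonnegative);
#' [quasi_tail_bound()] bounds the truncation error.
#'
#' @param graph an [allele_graph()].
#' @param pair a [genotype_pair()] on the graph's alphabet.
#' @param beta fitness difference, strictly positive.
#' @param n_max maximum walk length included (default 40, capped at 60).
#' @param max_genotypes refuse when the genotype space exceeds this size
#'   (default `1e4`).
#' @return A single number (the partial sum).
#' @examples
#' g <- graph_complete(2)
#' pr <- genotype_pair(c(1, 1), c(2, 2))
#' enumerate_walk_expectation_oracle(g, pr, beta = 0.5, n_max = 2) # 2 * 0.5
#' @export
enumerate_walk_expectation_oracle <- function(graph, pair, beta, n_max = 40,
                                              max_genotypes = 1e4) {
  assert_graph(graph)
  stopifnot(inherits(pair, "genotype_pair"))
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L || n_max > 60L) {
    abort("`n_max` must be between 1 and 60.", class = "accperc_domain")
  }
  n <- graph$n
  L <- pair$L
  G <- n^L
  if (G > max_genotypes) {
    abort(sprintf("genotype space too large for enumeration (%g > %g).",
                  G, max_genotypes),
          class = "accperc_resource_cap")
  }
  ai <- vertex_index(graph, pair$a)
  bi <- vertex_index(graph, pair$b)
  a_id <- genotype_id(ai, n)
  b_id <- genotype_id(bi, n)

  Tm <- product_transition_matrix(graph, L)
  cur <- numeric(G)
  cur[a_id] <- 1
  total <- 0
  log_wt <- 0 # log(beta^{N-1}/(N-1)!)
  for (N in seq_len(n_max)) {
    cur <- as.numeric(Matrix::crossprod(Tm, cur))
    if (N > 1) log_wt <- log_wt + log(beta) - log(N - 1)
    total <- total + cur[b_id] * exp(log_wt)
  }
  total
}

# genotype as 1-based index; locus 1 is the least-significant digit
genotype_id <- function(digits, n) {
  sum((digits - 1L) * n^(seq_along(digits) - 1L)) + 1L
}

genotype_digits <- function(id, n, L) {
  ((id - 1L) %/% n^(0:(L - 1L))) %% n + 1L
}

# sparse adjacency of the Cartesian power graph
product_transition_matrix <- function(graph, L) {
  n <- graph$n
  G <- n^L
  arrows <- which(graph$adjacency == 1L, arr.ind = TRUE)
  from <- integer(0)
  to <- integer(0)
  ids <- seq_len(G)
  for (l in seq_len(L)) {
    digit <- ((ids - 1L) %/% n^(l - 1L)) %% n + 1L
    for (k in seq_len(nrow(arrows))) {
      cc <- arrows[k, 1]
      dd <- arrows[k, 2]
      sel <- ids[digit == cc]
      from <- c(from, sel)
      to <- c(to, sel + (dd - cc) * n^(l - 1L))
    }
  }
  Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(G, G))
}

#' @rdname enumerate_walk_expectation_oracle
#' @details `quasi_tail_bound()` returns an upper bound on the mass of the
#'   terms beyond `n_max`: with `D = L * Delta` an upper bound on the
#'   product-graph out-degree, the tail of the series is at most
#'   \eqn{D\, (\beta D)^{n_{max}} / n_{max}!\; e^{\beta D}}.
#' @param L number of loci (for the tail bound).
#' @export
quasi_tail_bound <- function(graph, L, beta, n_max = 40) {
  assert_graph(graph)
  D <- L * graph$max_degree
  exp(log(D) + n_max * log(beta * D) - lfactorial(n_max) + beta * D)
}
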