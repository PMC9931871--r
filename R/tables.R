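#' Critical-threshold table for complete allele graphs
#'
#' Solves the critical fitness difference, the derivative of the mean Gamma
#' at the critical point and the per-locus walk-length factor for complete
#' allele graphs at full relative distance, one row per allele count. For
#' the complete graph the threshold is equivalently the logarithm of the
#' positive root of `x^n - n x - 1 = 0`; the table is computed through the
#' generic matrix-exponential solver, which the polynomial serves to
#' cross-check.
#'
#' @param alleles integer vector of allele counts (default
#'   `c(2, 3, 4, 21)`).
#' @return A tibble with columns `alleles`, `beta_star`,
#'   `gamma_prime_star` and `walk_length_factor`.
#' @examples
#' complete_graph_thresholds(c(2, 3))
#' @export
complete_graph_thresholds <- function(alleles = c(2, 3, 4, 21)) {
  purrr::map_dfr(alleles, function(n) {
    fit <- solve_beta_star(setup_hamming(graph_complete(n), delta = 1))
    tibble(
      alleles = as.integer(n),
      beta_star = fit$beta_star,
      gamma_prime_star = fit$gamma_prime_star,
      walk_length_factor = fit$walk_length_factor
    )
  })
}

#' Critical fitness difference as a function of relative distance
#'
#' Sweeps the relative endpoint distance `delta` on the complete allele
#' graph and solves the threshold at each value. On the complete graph the
#' setup is fully determined by `delta` (the relative Hamming distance), so
#' this curve captures the whole behaviour; in the biallelic case the
#' solved roots satisfy `sinh(beta)^delta * cosh(beta)^(1-delta) = 1`.
#'
#' @param n allele count.
#' @param delta numeric vector of relative distances in `(0, 1]`.
#' @return A tibble with columns `alleles`, `delta`, `beta_star` and
#'   `walk_length_factor`, classed `accperc_delta_curve` for
#'   [autoplot()][ggplot2::autoplot].
#' @examples
#' threshold_vs_distance(2, delta = c(0.25, 0.5, 1))
#' @export
threshold_vs_distance <- function(n, delta = seq(0.05, 1, by = 0.05)) {
  if (any(delta <= 0 | delta > 1)) {
    abort("`delta` values must lie in (0, 1].", class = "accperc_domain")
  }
  g <- graph_complete(n)
  out <- purrr::map_dfr(delta, function(d) {
    fit <- solve_beta_star(setup_hamming(g, delta = d))
    tibble(alleles = as.integer(n), delta = d,
           beta_star = fit$beta_star,
           walk_length_factor = fit$walk_length_factor)
  })
  class(out) <- c("accperc_delta_curve", class(out))
  out
}

#' Thresholds between homopolymer amino-acid sequences
#'
#' For every ordered pair of distinct amino acids (X, Y) on the
#' genetic-code allele graph, solves the critical fitness difference and
#' walk-length factor of the homopolymer setup `X^L -> Y^L` (all divergence
#' weight on the pair), and records the graph distance. Walk lengths grow
#' with pair distance; the unique distance-3 pair is Tyr/Met.
#'
#' @param include_stop keep stop as a 21st vertex (default `TRUE`).
#' @param pairs optional two-column matrix/data frame of (source, target)
#'   one-letter codes to restrict the computation.
#' @return A tibble with columns `source`, `target`, `distance`,
#'   `beta_star`, `gamma_prime_star` and `walk_length_factor`.
#' @examples
#' amino_acid_thresholds(pairs = cbind("Y", "M"))
#' @export
amino_acid_thresholds <- function(include_stop = TRUE, pairs = NULL) {
  g <- graph_amino_acid(include_stop = include_stop)
  aa <- setdiff(g$labels, "*")
  if (is.null(pairs)) {
    pairs <- expand.grid(source = aa, target = aa,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs) <- c("source", "target")
  }
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "directed")
  dmat <- igraph::distances(ig, mode = "out")
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    src <- pairs$source[k]
    tgt <- pairs$target[k]
    fit <- solve_beta_star(setup_homopolymer(g, from = src, to = tgt))
    tibble(
      source = src, target = tgt,
      distance = dmat[src, tgt],
      beta_star = fit$beta_star,
      gamma_prime_star = fit$gamma_prime_star,
      walk_length_factor = fit$walk_length_factor
    )
  })
}

#' Threshold scan by Monte-Carlo simulation
#'
#' Estimates beta-accessibility on a grid of fitness differences and locus
#' counts between "all-`from`" and "all-`to`" homopolymer endpoint
#' genotypes. As `L` grows the empirical crossing sharpens around the
#' finite-size threshold `c_L` for regular setups.
#'
#' @param graph an [allele_graph()].
#' @param L_list integer vector of locus counts.
#' @param beta_grid numeric vector of fitness differences in `(0, 1]`.
#' @param reps replicates per grid point.
#' @param seed master seed (each grid point derives its own replicate
#'   streams; the same fitness draws are shared across `beta` values at
#'   fixed `L`, coupling the curves monotonically).
#' @param from,to allele labels or indices of the homopolymer endpoints
#'   (defaults: first and second vertex).
#' @return A tibble in long format with columns `L`, `beta`, `p_hat`,
#'   `ci_low`, `ci_high`, `hits`, `reps` and `mean_path_length`, classed
#'   `accperc_scan` for [autoplot()][ggplot2::autoplot].
#' @examples
#' threshold_scan(graph_complete(2), L_list = c(4, 6),
#'                beta_grid = c(0.6, 0.9), reps = 200, seed = 1)
#' @export
threshold_scan <- function(graph, L_list, beta_grid, reps, seed,
                           from = 1, to = 2) {
  assert_graph(graph)
  grid <- expand.grid(L = as.integer(L_list), beta = beta_grid)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    L <- grid$L[k]
    beta <- grid$beta[k]
    pair <- genotype_pair(rep(vertex_index(graph, from), L),
                          rep(vertex_index(graph, to), L))
    sm <- estimate_accessibility(graph, pair, beta = beta, reps = reps,
                                 seed = seed + L)
    tibble(
      L = L, beta = beta, p_hat = sm$p_hat,
      ci_low = sm$ci_low, ci_high = sm$ci_high,
      hits = sm$hits, reps = sm$reps,
      mean_path_length = if (sm$hits > 0) mean(sm$path_lengths) else NA_real_
    )
  })
  class(out) <- c("accperc_scan", class(out))
  out
}
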