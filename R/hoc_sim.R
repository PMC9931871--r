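#' Draw a House-of-Cards landscape with conditioned endpoints
#'
#' Realizes one House-of-Cards fitness landscape on the `L`-fold Cartesian
#' power of the allele graph: every genotype receives an i.i.d. standard
#' uniform fitness value, and the landscape is conditioned on the endpoint
#' fitness difference by pinning `F(a) = 0` and `F(b) = beta` (shifting all
#' values modulo 1 leaves the HoC distribution invariant, so this
#' conditioning is equivalent to conditioning on the difference alone).
#'
#' @param graph an [allele_graph()].
#' @param pair a [genotype_pair()]; its length sets the number of loci.
#' @param beta conditioned fitness difference in `(0, 1]`.
#' @param seed integer seed; identical inputs and seed give identical
#'   landscapes. The caller's RNG state is left untouched.
#' @param max_genotypes refusal cap on the genotype-space size
#'   (default `1e6`).
#' @return An object of class `hoc_landscape`: list with `graph`, `L`,
#'   `pair`, `beta`, `seed` and `fitness` (vector of length `n^L` indexed by
#'   mixed-radix genotype id, locus 1 least significant).
#' @examples
#' g <- graph_complete(2)
#' ls <- draw_landscape(g, genotype_pair(c(1, 1), c(2, 2)), beta = 0.8,
#'                      seed = 1)
#' is_accessible(ls)$accessible
#' @export
draw_landscape <- function(graph, pair, beta, seed, max_genotypes = 1e6) {
  assert_graph(graph)
  stopifnot(inherits(pair, "genotype_pair"))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1) {
    abort("`beta` must lie in (0, 1].", class = "accperc_domain")
  }
  n <- graph$n
  L <- pair$L
  G <- n^L
  if (G > max_genotypes) {
    abort(sprintf("genotype space too large (%g > %g).", G, max_genotypes),
          class = "accperc_resource_cap")
  }
  ai <- vertex_index(graph, pair$a)
  bi <- vertex_index(graph, pair$b)
  a_id <- genotype_id(ai, n)
  b_id <- genotype_id(bi, n)
  if (a_id == b_id) {
    abort("endpoint genotypes must differ.", class = "accperc_invalid_setup")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fitness <- runif(G)
  fitness[a_id] <- 0
  fitness[b_id] <- beta
  out <- hoc_landscape(graph, pair, fitness)
  out$seed <- as.integer(seed)
  out
}

#' @rdname draw_landscape
#' @param fitness explicit fitness vector of length `n^L`, indexed by
#'   mixed-radix genotype id (locus 1 least significant); for
#'   `hoc_landscape()`, which wraps a user-supplied landscape (for example
#'   a hand-constructed ordering) for [is_accessible()].
#' @export
hoc_landscape <- function(graph, pair, fitness) {
  assert_graph(graph)
  stopifnot(inherits(pair, "genotype_pair"))
  n <- graph$n
  L <- pair$L
  if (length(fitness) != n^L) {
    abort(sprintf("`fitness` must have length %d.", n^L),
          class = "accperc_domain")
  }
  ai <- vertex_index(graph, pair$a)
  bi <- vertex_index(graph, pair$b)
  a_id <- genotype_id(ai, n)
  b_id <- genotype_id(bi, n)
  if (a_id == b_id) {
    abort("endpoint genotypes must differ.", class = "accperc_invalid_setup")
  }
  structure(
    list(graph = graph, L = L, pair = pair,
         beta = fitness[b_id] - fitness[a_id],
         seed = NA_integer_, fitness = as.numeric(fitness),
         a_id = a_id, b_id = b_id),
    class = "hoc_landscape"
  )
}

#' @export
print.hoc_landscape <- function(x, ...) {
  cat(sprintf("<hoc_landscape: %d alleles ^ %d loci (%d genotypes), beta = %.3f, seed = %d>\n",
              x$graph$n, x$L, length(x$fitness), x$beta, x$seed))
  invisible(x)
}

#' Exact accessibility check on one landscape
#'
#' Decides whether the final genotype is accessible from the initial one,
#' i.e. whether a directed path exists along which fitness strictly
#' increases. Genotypes are processed in increasing fitness order while
#' propagating reachability along product-graph arrows, so each genotype is
#' examined once; a witness path is reconstructed from predecessor pointers
#' and is always simple (fitness increases strictly along it).
#'
#' @param landscape a [draw_landscape()] result, or any list with the same
#'   fields.
#' @return A list with `accessible` (flag) and `path` (integer genotype ids
#'   from `a` to `b`; empty when inaccessible). Decode ids with
#'   [genotype_alleles()].
#' @export
is_accessible <- function(landscape) {
  stopifnot(inherits(landscape, "hoc_landscape"))
  check_accessible_cpp(landscape$graph$adjacency, landscape$L,
                       landscape$fitness, landscape$a_id, landscape$b_id)
}

#' @rdname is_accessible
#' @param id genotype id (1-based mixed-radix integer).
#' @param graph an [allele_graph()].
#' @param L number of loci.
#' @return `genotype_alleles()` returns the length-`L` vector of allele
#'   labels encoded by `id`.
#' @export
genotype_alleles <- function(id, graph, L) {
  assert_graph(graph)
  graph$labels[genotype_digits(as.integer(id), graph$n, as.integer(L))]
}

#' Monte-Carlo estimate of beta-accessibility
#'
#' Estimates the probability that the final genotype is accessible from the
#' initial one in the House-of-Cards model conditioned on endpoint fitness
#' difference `beta`, by seeded replicate simulation. Two estimators are
#' available: the default conditioned-uniform draw (`F(a) = 0`,
#' `F(b) = beta`, interior i.i.d. uniform) and the equivalent Bernoulli site
#' thinning (each interior genotype survives with probability `beta` and
#' only fitness ranks decide accessibility), which serves as an independent
#' cross-check of the conditioning.
#'
#' Replicates use one counter-based random stream each, derived from
#' `(seed, replicate index)`: results are independent of evaluation order
#' and, for the conditioned estimator, the interior fitness draws are
#' identical across `beta` values, giving a monotone coupling in `beta`.
#'
#' @inheritParams draw_landscape
#' @param reps number of replicates (at least 1).
#' @param method `"conditioned"` (default) or `"thinning"`.
#' @return An object of class `sim_summary`: list with `reps`, `hits`,
#'   `p_hat`, `ci_low`, `ci_high` (Wilson 95% interval), `beta`, `L`,
#'   `method`, `seed` and `path_lengths` (witness lengths, one per
#'   accessible replicate).
#' @examples
#' g <- graph_complete(2)
#' estimate_accessibility(g, genotype_pair(c(1, 1), c(2, 2)), beta = 0.5,
#'                        reps = 1000, seed = 7)
#' @export
estimate_accessibility <- function(graph, pair, beta, reps, seed,
                                   method = c("conditioned", "thinning"),
                                   max_genotypes = 1e6) {
  assert_graph(graph)
  stopifnot(inherits(pair, "genotype_pair"))
  method <- match.arg(method)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) {
    abort("`reps` must be a positive integer.", class = "accperc_domain")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1) {
    abort("`beta` must lie in (0, 1].", class = "accperc_domain")
  }
  n <- graph$n
  if (n^pair$L > max_genotypes) {
    abort("genotype space too large; lower `L` or raise `max_genotypes`.",
          class = "accperc_resource_cap")
  }
  ai <- vertex_index(graph, pair$a)
  bi <- vertex_index(graph, pair$b)
  lens <- simulate_accessibility_cpp(
    graph$adjacency, pair$L, genotype_id(ai, n), genotype_id(bi, n),
    beta, reps, as.double(seed), if (method == "conditioned") 0L else 1L)
  hits <- sum(lens >= 0)
  ci <- wilson_ci(hits, reps)
  structure(
    list(reps = reps, hits = hits, p_hat = hits / reps,
         ci_low = ci[1], ci_high = ci[2], beta = beta, L = pair$L,
         method = method, seed = as.integer(seed),
         path_lengths = as.integer(lens[lens >= 0])),
    class = "sim_summary"
  )
}

wilson_ci <- function(hits, reps, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- hits / reps
  denom <- 1 + z^2 / reps
  centre <- (p + z^2 / (2 * reps)) / denom
  half <- z * sqrt(p * (1 - p) / reps + z^2 / (4 * reps^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf(
    "<sim_summary: p_hat = %.4f [%.4f, %.4f] (%d/%d reps, beta = %.3f, %s)>\n",
    x$p_hat, x$ci_low, x$ci_high, x$hits, x$reps, x$beta, x$method))
  invisible(x)
}

#' Exact accessibility probability for small instances
#'
#' Computes the beta-accessibility probability exactly by
#' inclusion-exclusion over the simple paths from `a` to `b` on the product
#' graph. For a subset of paths whose interiors form the vertex set `U`
#' (size `m`) with the partial order given by the union of the paths' chain
#' orders, the probability that every path in the subset is simultaneously
#' accessible is
#' \deqn{\beta^m \; e(\mathrm{poset}) / m!,}
#' with `e` the number of linear extensions (0 when the union of chains is
#' cyclic). Linear extensions are counted by dynamic programming over
#' predecessor-closed subsets. This serves as an independent oracle for
#' [estimate_accessibility()]; it refuses (rather than approximates) when
#' the instance exceeds the caps.
#'
#' @inheritParams estimate_accessibility
#' @param max_paths refuse when more simple paths exist (default 12).
#' @param max_interior refuse when the union of path interiors exceeds this
#'   size (default 10).
#' @return A single probability.
#' @examples
#' g <- graph_complete(2)
#' exact_accessibility_small(g, genotype_pair(c(1, 1), c(2, 2)), beta = 0.5)
#' # = 2 * 0.5 - 0.5^2
#' @export
exact_accessibility_small <- function(graph, pair, beta,
                                      max_paths = 12, max_interior = 10) {
  assert_graph(graph)
  stopifnot(inherits(pair, "genotype_pair"))
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1) {
    abort("`beta` must lie in [0, 1].", class = "accperc_domain")
  }
  n <- graph$n
  L <- pair$L
  if (n^L > 4096) {
    abort("genotype space too large for exact path enumeration.",
          class = "accperc_resource_cap")
  }
  ai <- vertex_index(graph, pair$a)
  bi <- vertex_index(graph, pair$b)
  a_id <- genotype_id(ai, n)
  b_id <- genotype_id(bi, n)
  paths <- enumerate_simple_paths(graph, L, a_id, b_id, max_paths)
  if (length(paths) == 0) return(0)

  interiors <- sort(unique(unlist(lapply(paths, function(p) {
    p[-c(1, length(p))]
  }))))
  if (length(interiors) > max_interior) {
    abort("too many interior vertices for exact inclusion-exclusion.",
          class = "accperc_resource_cap")
  }

  total <- 0
  np <- length(paths)
  for (mask in seq_len(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) != 0)
    pr <- subset_joint_probability(paths[sel], interiors, beta)
    total <- total + (-1)^(length(sel) + 1) * pr
  }
  total
}

# P[all paths in `paths` accessible]: beta^m * e / m! with e the number of
# linear extensions of the union of the paths' interior chains.
subset_joint_probability <- function(paths, interiors, beta) {
  ints <- sort(unique(unlist(lapply(paths, function(p) p[-c(1, length(p))]))))
  m <- length(ints)
  if (m == 0) return(1) # direct arrows only: accessible by the conditioning
  # predecessor bitmasks from each path's chain order on its own interiors
  pred_mask <- integer(m)
  for (p in paths) {
    pint <- match(p[-c(1, length(p))], ints)
    if (length(pint) >= 2) {
      for (j in 2:length(pint)) {
        pred_mask[pint[j]] <- bitwOr(pred_mask[pint[j]],
                                     sum(2^(pint[seq_len(j - 1)] - 1)))
      }
    }
  }
  e <- count_linear_extensions(pred_mask, m)
  exp(m * log(beta) - lfactorial(m)) * e
}

# DP over predecessor-closed subsets; returns 0 for cyclic relations.
count_linear_extensions <- function(pred_mask, m) {
  full <- 2^m - 1
  counts <- numeric(2^m)
  counts[1] <- 1 # empty set (offset by 1)
  for (S in 0:(full - 1)) {
    cS <- counts[S + 1]
    if (cS == 0) next
    for (j in seq_len(m)) {
      bit <- 2^(j - 1)
      if (bitwAnd(S, bit) != 0) next
      if (bitwAnd(pred_mask[j], S) == pred_mask[j]) {
        counts[bitwOr(S, bit) + 1] <- counts[bitwOr(S, bit) + 1] + cS
      }
    }
  }
  counts[full + 1]
}

# brute-force linear-extension count; tiny-m oracle for the DP
count_linear_extensions_bruteforce <- function(pred_mask, m) {
  if (m == 0) return(1)
  perms <- all_permutations(m)
  good <- 0
  for (k in seq_len(nrow(perms))) {
    ord <- perms[k, ]
    placed <- 0
    ok <- TRUE
    for (j in ord) {
      if (bitwAnd(pred_mask[j], placed) != pred_mask[j]) {
        ok <- FALSE
        break
      }
      placed <- bitwOr(placed, 2^(j - 1))
    }
    if (ok) good <- good + 1
  }
  good
}

all_permutations <- function(m) {
  if (m == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(m - 1)
  out <- NULL
  for (k in seq_len(m)) {
    rest <- setdiff(seq_len(m), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# all simple directed paths a -> b on the product graph (DFS); errors past cap
enumerate_simple_paths <- function(graph, L, a_id, b_id, max_paths) {
  n <- graph$n
  out_nbrs <- function(id) {
    digs <- genotype_digits(id, n, L)
    nb <- integer(0)
    for (l in seq_len(L)) {
      to <- which(graph$adjacency[digs[l], ] == 1L)
      nb <- c(nb, id + (to - digs[l]) * n^(l - 1L))
    }
    nb
  }
  paths <- list()
  visit <- function(cur, path, on_path) {
    if (cur == b_id) {
      if (length(paths) >= max_paths) {
        abort("number of simple paths exceeds `max_paths`.",
              class = "accperc_resource_cap")
      }
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nb in out_nbrs(cur)) {
      if (nb != a_id && !(nb %in% on_path)) {
        visit(nb, c(path, nb), c(on_path, nb))
      }
    }
  }
  visit(a_id, a_id, a_id)
  paths
}
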