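#' Accessibility setups
#'
#' An accessibility setup bundles an allele graph with the asymptotic
#' "direction" between the endpoint genotypes: the divergence matrix `p`,
#' whose entry `p[v, w]` is the limiting fraction of loci that must move
#' from allele `v` to allele `w`. Optionally a concrete finite-`L` allele
#' counting matrix `M` (and its remainder `R = M - L p`) can be attached,
#' which enables the finite-size root `beta_hat` and the finite-size
#' threshold function.
#'
#' A setup is *well-behaved* when (1) `p[v, w] = 0` wherever no walk of
#' non-zero length leads from `v` to `w`, (2) the endpoints differ, (3) the
#' divergence limit exists (taken as given when `p` is supplied directly) and
#' (4) the off-diagonal mass `delta = sum of p[v, w], v != w` is positive so
#' that the endpoint distance grows linearly in `L`. Use [validate_setup()]
#' for a per-condition report.
#'
#' @param graph an [allele_graph()].
#' @param p square nonnegative divergence matrix over the graph's alleles,
#'   summing to 1. Rows/columns may be named with allele labels (reordered to
#'   the graph's order) or given in the graph's vertex order.
#' @param M optional allele counting matrix for a concrete number of loci
#'   (nonnegative integers summing to `L`). When supplied without `p`, the
#'   divergence matrix defaults to `M / L`.
#' @param pair optional [genotype_pair()] from which `M` is derived.
#' @param check validate the setup and error on failure (default `TRUE`).
#' @return An object of class `accessibility_setup` with fields `graph`,
#'   `p`, `M` (or `NULL`), `L` (or `NULL`), `R` (or `NULL`) and `delta`.
#' @examples
#' s <- setup_hamming(graph_complete(3), delta = 1)
#' s$delta
#' @export
accessibility_setup <- function(graph, p = NULL, M = NULL, pair = NULL,
                                check = TRUE) {
  assert_graph(graph)
  n <- graph$n
  if (!is.null(pair)) {
    if (!is.null(M)) {
      abort("give either `pair` or `M`, not both.",
            class = "accperc_invalid_setup")
    }
    M <- counting_matrix(pair, graph)
  }
  L <- NULL
  if (!is.null(M)) {
    M <- align_allele_matrix(M, graph, "M")
    if (any(M < 0) || any(M != round(M))) {
      abort("`M` entries must be nonnegative integers.",
            class = "accperc_invalid_setup")
    }
    L <- as.integer(sum(M))
  }
  if (is.null(p)) {
    if (is.null(M)) {
      abort("supply a divergence matrix `p`, a counting matrix `M`, or a `pair`.",
            class = "accperc_invalid_setup")
    }
    p <- M / L
  } else {
    p <- align_allele_matrix(p, graph, "p")
  }
  if (any(p < 0)) {
    abort("`p` entries must be nonnegative.", class = "accperc_invalid_setup")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("`p` must sum to 1.", class = "accperc_invalid_setup")
  }
  R <- if (!is.null(M)) M - L * p else NULL
  setup <- structure(
    list(
      graph = graph,
      p = p,
      M = M,
      L = L,
      R = R,
      delta = sum(p) - sum(diag(p))
    ),
    class = "accessibility_setup"
  )
  if (check) {
    rep <- validate_setup(setup)
    if (!all(rep$pass)) {
      abort(paste0("accessibility setup is not well-behaved: ",
                   paste(rep$condition[!rep$pass], collapse = "; ")),
            class = "accperc_invalid_setup")
    }
  }
  setup
}

align_allele_matrix <- function(m, graph, what) {
  m <- as.matrix(m)
  if (nrow(m) != graph$n || ncol(m) != graph$n) {
    abort(sprintf("`%s` must be a %d x %d matrix over the graph's alleles.",
                  what, graph$n, graph$n),
          class = "accperc_invalid_setup")
  }
  if (!is.null(rownames(m))) {
    if (!setequal(rownames(m), graph$labels) ||
        !setequal(colnames(m), graph$labels)) {
      abort(sprintf("dimnames of `%s` must match the graph's labels.", what),
            class = "accperc_invalid_setup")
    }
    m <- m[graph$labels, graph$labels, drop = FALSE]
  } else {
    dimnames(m) <- list(graph$labels, graph$labels)
  }
  m
}

#' @export
print.accessibility_setup <- function(x, ...) {
  cat(sprintf("<accessibility_setup: %d alleles, delta = %.4g%s>\n",
              x$graph$n, x$delta,
              if (!is.null(x$L)) sprintf(", finite L = %d", x$L) else ""))
  invisible(x)
}

assert_setup <- function(setup) {
  if (!inherits(setup, "accessibility_setup")) {
    abort("expected an `accessibility_setup` object.",
          class = "accperc_invalid_setup")
  }
  invisible(setup)
}

#' Convenience setup constructors
#'
#' `setup_hamming()` builds the symmetric complete-graph-style setup fully
#' determined by the relative Hamming distance `delta`: a fraction `delta` of
#' loci move between one fixed ordered pair of distinct alleles and the rest
#' stay put. `setup_homopolymer()` concentrates all divergence weight on a
#' single ordered allele pair `(from, to)`, the setup for homopolymer
#' endpoint sequences `from^L -> to^L`.
#'
#' @param graph an [allele_graph()].
#' @param delta relative endpoint distance in `(0, 1]`.
#' @param from,to allele labels or indices (defaults: first and second
#'   vertex).
#' @return An [accessibility_setup()].
#' @examples
#' setup_hamming(graph_complete(2), delta = 0.5)
#' setup_homopolymer(graph_path(3), from = 1, to = 3)
#' @export
setup_hamming <- function(graph, delta, from = 1, to = 2) {
  assert_graph(graph)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    abort("`delta` must be a single value in (0, 1].",
          class = "accperc_invalid_setup")
  }
  fi <- vertex_index(graph, from)
  ti <- vertex_index(graph, to)
  if (fi == ti) {
    abort("`from` and `to` must differ.", class = "accperc_invalid_setup")
  }
  p <- matrix(0, graph$n, graph$n,
              dimnames = list(graph$labels, graph$labels))
  p[fi, ti] <- delta
  p[fi, fi] <- 1 - delta
  accessibility_setup(graph, p = p)
}

#' @rdname setup_hamming
#' @export
setup_homopolymer <- function(graph, from, to) {
  setup_hamming(graph, delta = 1, from = from, to = to)
}

#' Validate an accessibility setup
#'
#' Checks the well-behavedness conditions one by one and reports them as a
#' tibble rather than erroring, listing the offending allele pairs where a
#' condition fails.
#'
#' @param setup an [accessibility_setup()] (constructed with
#'   `check = FALSE` if you expect failures).
#' @return A tibble with columns `condition`, `pass` and `detail`.
#' @examples
#' g <- graph_path(3)
#' p <- matrix(0, 3, 3); p[1, 3] <- 1
#' validate_setup(accessibility_setup(g, p = p, check = FALSE))
#' @export
validate_setup <- function(setup) {
  assert_setup(setup)
  reach <- reachability_matrix(setup$graph)
  labs <- setup$graph$labels

  bad_weight <- which(setup$p > 0 & !reach, arr.ind = TRUE)
  bad_pairs <- if (nrow(bad_weight) > 0) {
    paste(sprintf("(%s,%s)", labs[bad_weight[, 1]], labs[bad_weight[, 2]]),
          collapse = ", ")
  } else ""
  cond1 <- nrow(bad_weight) == 0

  # endpoints differ: with only p given this is delta > 0; with M given the
  # pair is identical iff all mass sits on the diagonal
  if (!is.null(setup$M)) {
    cond2 <- sum(setup$M) - sum(diag(setup$M)) > 0
  } else {
    cond2 <- setup$delta > 0
  }

  cond3 <- abs(sum(setup$p) - 1) <= 1e-8 && all(setup$p >= 0)
  cond4 <- setup$delta > 0

  tibble(
    condition = c(
      "weighted pairs reachable by non-zero-length walks",
      "endpoint genotypes differ",
      "divergence matrix is a probability matrix",
      "off-diagonal divergence delta > 0"
    ),
    pass = c(cond1, cond2, cond3, cond4),
    detail = c(
      if (cond1) "" else paste("unreachable weighted pairs:", bad_pairs),
      if (cond2) "" else "all counting/divergence mass on the diagonal",
      if (cond3) "" else sprintf("sum(p) = %.6g", sum(setup$p)),
      sprintf("delta = %.6g", setup$delta)
    )
  )
}
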