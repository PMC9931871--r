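#' Martinsson's function
#'
#' A refined, three-segment version of the mean Gamma used to detect
#' clustering of accessible walks. Each candidate walk is split into an
#' initial, middle and final segment spanning fitness `beta*(1-s)*r`,
#' `beta*s` and `beta*(1-s)*(1-r)` respectively; for each weighted endpoint
#' pair `(a, b)` the function averages the middle-segment growth rate
#' `Gamma_{xy}(beta*s)` over intermediate allele pairs `(x, y)`, weighted by
#' \deqn{e^{\Gamma_{ax}(\beta \bar s r) + \Gamma_{xy}(\beta s) +
#'       \Gamma_{yb}(\beta \bar s \bar r)},}
#' and the result is averaged over `(a, b)` with the divergence weights.
#' Terms whose middle-segment matrix-exponential entry is zero (unreachable
#' pair, or `s = 0` off the diagonal) contribute 0 to both numerator and
#' denominator (the `Gamma e^Gamma = 0` convention).
#'
#' A positive interior value at `beta*` means the quasi-accessible walks
#' cluster on few initial/final segments, so the first-moment threshold need
#' not be sharp; the sign pattern defines the regularity classes, see
#' [classify_setup()].
#'
#' @param setup an [accessibility_setup()].
#' @param s,r segmentation coordinates in `[0, 1]` (vectorized: `s` and `r`
#'   are recycled to a common length).
#' @param beta fitness difference, strictly positive.
#' @return A numeric vector of function values.
#' @examples
#' s <- setup_hamming(graph_complete(3), delta = 1)
#' martinsson(s, s = 1, r = 0.5, beta = 0.7) # equals mean_gamma(s, 0.7)
#' @export
martinsson <- function(setup, s, r, beta) {
  assert_setup(setup)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    abort("`beta` must be a single positive number.", class = "accperc_domain")
  }
  if (any(s < 0 | s > 1) || any(r < 0 | r > 1)) {
    abort("`s` and `r` must lie in [0, 1].", class = "accperc_domain")
  }
  m <- max(length(s), length(r))
  s <- rep_len(s, m)
  r <- rep_len(r, m)
  vapply(seq_len(m), function(i) {
    martinsson_point(setup, s[i], r[i], beta)
  }, numeric(1))
}

martinsson_point <- function(setup, s, r, beta) {
  be <- graph_backend(setup$graph)
  n <- setup$graph$n
  expm_at <- function(t) if (t == 0) diag(1, n) else be$expm(t)
  E1 <- expm_at(beta * (1 - s) * r)       # a -> x
  E2 <- expm_at(beta * s)                 # x -> y
  E3 <- expm_at(beta * (1 - s) * (1 - r)) # y -> b
  G2 <- suppressWarnings(log(E2))

  W <- setup$p
  idx <- which(W > 0, arr.ind = TRUE)
  total <- 0
  for (k in seq_len(nrow(idx))) {
    a <- idx[k, 1]
    b <- idx[k, 2]
    wts <- outer(E1[a, ], E3[, b]) * E2 # (x, y) weights
    pos <- wts > 0
    den <- sum(wts[pos])
    if (den == 0) {
      abort("all three-segment weights vanish for a weighted pair.",
            class = "accperc_invalid_setup")
    }
    num <- sum(wts[pos] * G2[pos]) # wts > 0 implies E2 > 0, Gamma finite
    total <- total + W[a, b] * num / den
  }
  total
}

#' Classify an accessibility setup as regular / semi-regular / irregular
#'
#' Evaluates the limiting Martinsson function on an `(s, r)` lattice at the
#' solved critical point `beta*` and classifies by sign: the setup is
#' *irregular* when the function is positive somewhere in the interior
#' (beyond `tol`), *semi-regular* when it is nonpositive everywhere, and
#' *regular* when it is strictly negative on all interior lattice points and
#' the one-sided derivative in `s` at `s = 1` is bounded away from zero. For
#' regular setups the first-moment threshold `c_L` is sharp and `beta*` is
#' the true critical fitness difference; for irregular setups the true
#' threshold exceeds `beta*`.
#'
#' The classification is numerical, at the stated lattice resolution; sign
#' violations finer than the grid or the tolerance cannot be detected, which
#' is the same caveat that applies to any grid-based regularity test.
#'
#' @param setup an [accessibility_setup()].
#' @param grid_n lattice resolution per axis (default 200, minimum 10).
#' @param tol sign tolerance (default `1e-9`).
#' @param beta evaluation point; defaults to the solved `beta*`.
#' @return An object of class `martinsson_eval`: list with `classification`
#'   (`"regular"`, `"semi_regular"` or `"irregular"`), `beta`,
#'   `max_interior`, `ds_at_1` (most conservative over the `r` grid), `tol`,
#'   `grid_n` and `grid` (a tibble with columns `s`, `r`, `value`).
#' @examples
#' classify_setup(setup_hamming(graph_complete(2), delta = 1), grid_n = 40)
#' @export
classify_setup <- function(setup, grid_n = 200, tol = 1e-9, beta = NULL) {
  assert_setup(setup)
  grid_n <- max(10L, as.integer(grid_n))
  if (is.null(beta)) {
    beta <- solve_beta_star(setup)$beta_star
  }
  svals <- seq(0, 1, length.out = grid_n)
  rvals <- seq(0, 1, length.out = grid_n)
  vals <- matrix(NA_real_, grid_n, grid_n)
  for (j in seq_along(rvals)) {
    vals[, j] <- martinsson(setup, svals, rvals[j], beta)
  }
  # the sign conditions exempt only the s = 0 and s = 1 faces; the r
  # boundary is part of the domain
  interior <- vals[-c(1, grid_n), , drop = FALSE]
  max_interior <- max(interior)

  # one-sided finite difference of M* in s at s = 1, per r; the value at
  # s = 1 is Gamma(beta) itself (independent of r)
  h <- 1e-5
  at1 <- martinsson(setup, 1, rvals[1], beta)
  ds <- vapply(rvals, function(r) {
    (at1 - martinsson(setup, 1 - h, r, beta)) / h
  }, numeric(1))
  ds_at_1 <- ds[which.min(abs(ds))]

  classification <- if (max_interior > tol) {
    "irregular"
  } else if (max(interior) < -tol && min(abs(ds)) > tol) {
    "regular"
  } else {
    "semi_regular"
  }

  structure(
    list(
      classification = classification,
      beta = beta,
      max_interior = max_interior,
      ds_at_1 = ds_at_1,
      tol = tol,
      grid_n = grid_n,
      grid = tibble(
        s = rep(svals, times = grid_n),
        r = rep(rvals, each = grid_n),
        value = as.vector(vals)
      )
    ),
    class = "martinsson_eval"
  )
}

#' @export
print.martinsson_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<martinsson_eval: %s at beta = %.6f>\n",
           "  interior max %.3e, d/ds at s=1: %.6f (grid %d, tol %.1e)\n"),
    x$classification, x$beta, x$max_interior, x$ds_at_1, x$grid_n, x$tol))
  invisible(x)
}

#' Search small digraphs for irregular accessibility setups
#'
#' Best-effort enumeration (exhaustive up to order 5, sampled beyond a
#' budget) of simple directed allele graphs with a designated endpoint pair
#' (first and last vertex, all divergence weight on that ordered pair),
#' keeping those whose setup is classified irregular with
#' `beta* <= beta_cap`. Graphs without a walk from the first to the last
#' vertex are skipped. The smallest graphs admitting irregularity have
#' order 4.
#'
#' @param max_vertices largest graph order to enumerate (2..5 exhaustive).
#' @param beta_cap keep only results with `beta* <= beta_cap`
#'   (default `Inf`).
#' @param budget cap on the number of candidate graphs examined; when
#'   exhausted, partial results are returned with attribute
#'   `budget_exhausted = TRUE`.
#' @param grid_n lattice resolution for classification (default 31; coarse
#'   by design, re-classify hits at higher resolution).
#' @param tol classification tolerance (default `1e-7`).
#' @return A tibble with columns `n_vertices`, `adjacency` (list column),
#'   `beta_star`, `max_interior` and `classification`, one row per
#'   irregular setup found.
#' @export
search_irregular <- function(max_vertices = 4, beta_cap = Inf, budget = Inf,
                             grid_n = 31, tol = 1e-7) {
  max_vertices <- as.integer(max_vertices)
  if (max_vertices > 5L) {
    abort("exhaustive search is capped at 5 vertices.",
          class = "accperc_resource_cap")
  }
  rows <- list()
  examined <- 0
  exhausted <- FALSE
  for (n in seq(2L, max_vertices)) {
    m <- n * (n - 1L) # off-diagonal slots
    offdiag <- which(diag(n) == 0)
    seen <- new.env(parent = emptyenv()) # canonical keys modulo middle-vertex relabeling
    mids <- if (n > 3L) all_permutations(n - 2L) + 1L else
      matrix(integer(0), 1, 0)
    for (code in 0:(2^m - 1)) {
      if (examined >= budget) {
        exhausted <- TRUE
        break
      }
      bits <- as.integer(intToBits(code))[seq_len(m)]
      if (sum(bits) == 0) next
      adj <- matrix(0L, n, n)
      adj[offdiag] <- bits
      # the endpoint pair is (1, n); interior vertices are interchangeable
      key <- canonical_key(adj, mids, n)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      examined <- examined + 1
      g <- allele_graph(adj, labels = default_labels(n), sort_labels = FALSE)
      reach <- reachability_matrix(g)
      if (!reach[1, n]) next
      res <- try({
        setup <- setup_homopolymer(g, from = 1, to = n)
        fit <- solve_beta_star(setup)
        if (fit$beta_star <= beta_cap) {
          # cheap screen; positive regions of M* are typically thin slivers
          # approaching the s = 1 face, so probe points lean that way
          pre_s <- c(0.15, 0.3, 0.5, 0.7, 0.85, 0.92, 0.96, 0.98)
          pre <- max(vapply(c(0, 0.5, 1), function(r) {
            max(martinsson(setup, pre_s, r, fit$beta_star))
          }, numeric(1)))
          if (pre > -6e-3) {
            cls <- classify_setup(setup, grid_n = grid_n, tol = tol,
                                  beta = fit$beta_star)
            if (cls$classification == "irregular") {
              rows[[length(rows) + 1]] <- tibble(
                n_vertices = n,
                adjacency = list(adj),
                beta_star = fit$beta_star,
                max_interior = cls$max_interior,
                classification = cls$classification
              )
            }
          }
        }
        NULL
      }, silent = TRUE)
    }
    if (exhausted) break
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble(n_vertices = integer(), adjacency = list(),
           beta_star = numeric(), max_interior = numeric(),
           classification = character())
  }
  attr(out, "budget_exhausted") <- exhausted
  out
}

# lexicographically minimal adjacency string over permutations of the
# interior vertices 2..(n-1), endpoints held fixed
canonical_key <- function(adj, mids, n) {
  if (ncol(mids) == 0) return(paste(adj, collapse = ""))
  best <- NULL
  for (k in seq_len(nrow(mids))) {
    perm <- c(1L, mids[k, ], n)
    cand <- paste(adj[perm, perm], collapse = "")
    if (is.null(best) || cand < best) best <- cand
  }
  best
}
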