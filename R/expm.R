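# Matrix-exponential backend.
#
# Everything analytic in the package reduces to entries of exp(t*A) for the
# (small, fixed) allele adjacency matrix A at many values of t, so the
# backend caches per graph:
#   - symmetric A: one eigendecomposition, then exp(t*A) = V diag(e^{t l}) V'
#     for any t at matrix-multiply cost;
#   - general A (possibly defective, e.g. nilpotent DAG adjacency): the
#     power series sum_k t^k A^k / k! with cached powers of A. Because A is
#     entrywise nonnegative and t > 0 every term is nonnegative, so the
#     series accumulates without cancellation; the truncation order adapts
#     to t * Delta so the neglected tail is far below machine precision
#     relative to every reachable entry.
# Structurally zero entries (v != w with no walk v -> w) are forced to exact
# zero so that reachability decisions never rest on floating-point dust.

expm_factory <- function(graph) {
  A <- graph$adjacency
  storage.mode(A) <- "double"
  reach <- reachability_matrix(graph)
  n <- graph$n
  mask_zero <- !reach & !diag(TRUE, n) # structural zeros of exp(tA), t > 0
  if (isSymmetric(unname(A))) {
    eig <- eigen(A, symmetric = TRUE)
    V <- eig$vectors
    lam <- eig$values
    f <- function(t) {
      E <- V %*% (exp(t * lam) * t(V))
      E[mask_zero] <- 0
      E[E < 0] <- 0 # rounding can leave tiny negatives in reachable entries
      E
    }
  } else {
    state <- new.env(parent = emptyenv())
    state$pows <- matrix(as.numeric(diag(1, n)), ncol = 1) # columns: vec(A^k)
    state$last <- diag(1, n)
    extend_to <- function(K) {
      while (ncol(state$pows) < K + 1L) {
        state$last <- state$last %*% A
        state$pows <- cbind(state$pows, as.numeric(state$last))
      }
    }
    f <- function(t) {
      K <- max(40L, ceiling(3 * t * max(1, graph$max_degree)) + 40L)
      extend_to(K)
      w <- numeric(K + 1L)
      w[1] <- 1
      for (k in seq_len(K)) w[k + 1L] <- w[k] * t / k
      E <- matrix(state$pows[, seq_len(K + 1L), drop = FALSE] %*% w, n, n)
      E[mask_zero] <- 0
      E[E < 0] <- 0
      E
    }
  }
  list(expm = f, A = A, reach = reach)
}

# memoized backend per graph (keyed by the adjacency pattern)
graph_cache <- new.env(parent = emptyenv())

graph_backend <- function(graph) {
  key <- paste0("g", paste(c(graph$n, graph$adjacency), collapse = ","))
  hit <- graph_cache[[key]]
  if (!is.null(hit)) return(hit)
  be <- expm_factory(graph)
  if (length(ls(graph_cache)) > 64) {
    rm(list = ls(graph_cache), envir = graph_cache)
  }
  graph_cache[[key]] <- be
  be
}

# Fixed-order truncated power-series evaluation of exp(t*A); used in tests as
# a second route alongside Matrix::expm when checking the backend.
expm_series <- function(A, t, terms = 60L) {
  n <- nrow(A)
  acc <- diag(1, n)
  term <- diag(1, n)
  for (k in seq_len(terms)) {
    term <- term %*% A * (t / k)
    acc <- acc + term
  }
  acc
}
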