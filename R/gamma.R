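#' Log matrix-exponential entries and their derivatives
#'
#' The central analytic object of the framework: for alleles `v`, `w` and
#' `t > 0`,
#' \deqn{\Gamma_{vw}(t) = \ln\left[(e^{tA})_{vw}\right],}
#' the logarithm of one entry of the matrix exponential of the allele-graph
#' adjacency matrix. `exp(L * Gamma)` is, per locus-averaged pair, the
#' expected number of quasi-accessible walks between the endpoint genotypes,
#' so `Gamma` is the exponential growth/decay rate that decides
#' accessibility. Its first two derivatives in `t`,
#' \deqn{\Gamma' = (A e^{tA})_{vw} / (e^{tA})_{vw}, \qquad
#'       \Gamma'' = (A^2 e^{tA})_{vw}/(e^{tA})_{vw} - (\Gamma')^2,}
#' feed the walk-length factor and the walk-length variance.
#'
#' For `v != w` with no directed walk `v -> w` the entry is structurally
#' zero and `Gamma` is undefined; this is reported via `reachable = FALSE`
#' (never as a large negative stand-in), and downstream code treats
#' `exp(Gamma)` as exactly 0. For `v == w` with no closed walk through `v`
#' the entry is identically 1 and `Gamma = 0` for all `t`.
#'
#' @param graph an [allele_graph()].
#' @param v,w allele labels or indices.
#' @param t evaluation point, strictly positive.
#' @param max_order highest derivative to compute (0, 1 or 2; default 2).
#' @return An object of class `gamma_eval`: a list with `value`,
#'   `first_deriv`, `second_deriv` (NA above `max_order`) and `reachable`.
#' @examples
#' g <- graph_complete(2)
#' gamma_vw(g, 1, 2, t = 1)$value # = log(sinh(1))
#' @export
gamma_vw <- function(graph, v, w, t, max_order = 2) {
  assert_graph(graph)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    abort("`t` must be a single positive number.", class = "accperc_domain")
  }
  vi <- vertex_index(graph, v)
  wi <- vertex_index(graph, w)
  be <- graph_backend(graph)
  reachable <- vi == wi || be$reach[vi, wi]
  out <- list(value = NA_real_, first_deriv = NA_real_,
              second_deriv = NA_real_, reachable = reachable)
  class(out) <- "gamma_eval"
  if (!reachable) return(out)
  E <- be$expm(t)
  e0 <- as.numeric(E[vi, wi])
  out$value <- log(e0)
  if (max_order >= 1) {
    AE <- be$A %*% E
    out$first_deriv <- as.numeric(AE[vi, wi]) / e0
    if (max_order >= 2) {
      A2E <- be$A %*% AE
      out$second_deriv <- as.numeric(A2E[vi, wi]) / e0 - out$first_deriv^2
    }
  }
  out
}

#' @export
print.gamma_eval <- function(x, ...) {
  if (!x$reachable) {
    cat("<gamma_eval: unreachable pair (exp(Gamma) = 0)>\n")
  } else {
    cat(sprintf("<gamma_eval: value %.6g, d/dt %.6g, d2/dt2 %.6g>\n",
                x$value, x$first_deriv, x$second_deriv))
  }
  invisible(x)
}

# Full matrices of Gamma and derivatives at t; entries of `value` are -Inf on
# structurally zero positions (callers mask via `reach`).
gamma_matrices <- function(graph, t, max_order = 2) {
  be <- graph_backend(graph)
  E <- be$expm(t)
  out <- list(reach = be$reach | diag(TRUE, graph$n), E = E,
              value = suppressWarnings(log(E)))
  if (max_order >= 1) {
    AE <- be$A %*% E
    out$first <- AE / E
    if (max_order >= 2) {
      A2E <- be$A %*% AE
      out$second <- A2E / E - out$first^2
    }
  }
  out
}

#' Divergence-weighted mean of Gamma over allele pairs
#'
#' The locus-averaged Gamma of a setup,
#' \deqn{\langle \Gamma^{(k)}_{vw}(t) \rangle = \sum_{v,w} p_{vw}\,
#'       \Gamma^{(k)}_{vw}(t),}
#' with weights taken from the divergence matrix `p` (asymptotic form) or
#' from `M / L` (finite-`L` form). Its unique root in `t` is the critical
#' fitness difference; its derivatives at the root give the walk-length
#' factor and variance.
#'
#' @param setup an [accessibility_setup()].
#' @param t evaluation point, strictly positive.
#' @param order derivative order: 0, 1 or 2.
#' @param weights `"asymptotic"` (use `p`) or `"finite"` (use `M / L`;
#'   requires `M`).
#' @return A single number.
#' @examples
#' s <- setup_hamming(graph_complete(2), delta = 1)
#' mean_gamma(s, t = 0.8814) # ~ 0 at the critical point
#' @export
mean_gamma <- function(setup, t, order = 0,
                       weights = c("asymptotic", "finite")) {
  assert_setup(setup)
  weights <- match.arg(weights)
  W <- setup_weights(setup, weights)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    abort("`t` must be a single positive number.", class = "accperc_domain")
  }
  gm <- gamma_matrices(setup$graph, t, max_order = order)
  sel <- W > 0
  if (any(sel & !gm$reach)) {
    abort("setup places weight on an unreachable allele pair.",
          class = "accperc_invalid_setup")
  }
  G <- switch(as.character(order),
              "0" = gm$value, "1" = gm$first, "2" = gm$second)
  # unreachable (weight-0) positions hold -Inf/NaN; keep them out of the sum
  sum(W[sel] * G[sel])
}

setup_weights <- function(setup, weights) {
  if (weights == "finite") {
    if (is.null(setup$M)) {
      abort("finite-L weights require a counting matrix `M` in the setup.",
            class = "accperc_invalid_setup")
    }
    setup$M / setup$L
  } else {
    setup$p
  }
}
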