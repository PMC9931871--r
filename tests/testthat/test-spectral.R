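test_that("gamma matches closed forms and the series oracle", {
  g2 <- graph_complete(2)
  for (t in c(0.3, 1, 2.5)) {
    ev <- gamma_vw(g2, 1, 2, t)
    expect_equal(ev$value, log(sinh(t)), tolerance = 1e-12)
    expect_equal(ev$first_deriv, cosh(t) / sinh(t), tolerance = 1e-12)
    expect_equal(ev$second_deriv, 1 - (cosh(t) / sinh(t))^2,
                 tolerance = 1e-10)
    dv <- gamma_vw(g2, 1, 1, t)
    expect_equal(dv$value, log(cosh(t)), tolerance = 1e-12)
  }

  # diagonal with no closed walk: identically zero
  nr <- graph_complete_no_return(2)
  for (t in c(0.1, 1, 5)) {
    expect_equal(gamma_vw(nr, 1, 1, t)$value, 0, tolerance = 1e-12)
  }

  # unreachable off-diagonal pair: explicit flag, not a large negative
  ev <- gamma_vw(nr, 2, 1, t = 1)
  expect_false(ev$reachable)
  expect_true(is.na(ev$value))

  # path(3) entry 1 -> 3 against an explicitly truncated series
  p3 <- graph_path(3)
  A <- unname(p3$adjacency)
  storage.mode(A) <- "double"
  series <- 0
  Ak <- diag(1, 3)
  for (k in 0:30) {
    series <- series + Ak[1, 3] / factorial(k) * 1^k
    Ak <- Ak %*% A
  }
  expect_equal(exp(gamma_vw(p3, 1, 3, 1)$value), series, tolerance = 1e-12)

  expect_error(gamma_vw(g2, 1, 2, t = 0), class = "accperc_domain")
  expect_error(gamma_vw(g2, 1, 2, t = -1), class = "accperc_domain")
})

test_that("expm backend agrees with Matrix::expm on random digraphs (log scale)", {
  set.seed(421)
  backend <- getFromNamespace("graph_backend", "accperc")
  for (rep in 1:8) {
    g <- random_digraph(5, p_edge = 0.5)
    be <- backend(g)
    A <- g$adjacency
    storage.mode(A) <- "double"
    for (t in c(0.05, 0.7, 3)) {
      E <- be$expm(t)
      Eref <- as.matrix(Matrix::expm(t * A))
      sel <- Eref > 1e-280 & E > 0
      expect_lt(max(abs(log(E[sel]) - log(Eref[sel]))), 1e-12)
    }
  }
})

test_that("gamma is strictly increasing in t for reachable pairs", {
  set.seed(77)
  tgrid <- exp(seq(log(0.05), log(5), length.out = 25))
  for (g in list(graph_complete(3), graph_path(4), random_digraph(4))) {
    reach <- getFromNamespace("reachability_matrix", "accperc")(g)
    for (v in seq_len(g$n)) for (w in seq_len(g$n)) {
      if (v != w && reach[v, w]) {
        vals <- vapply(tgrid, function(t) gamma_vw(g, v, w, t, 0)$value,
                       numeric(1))
        expect_true(all(diff(vals) > 0))
        expect_gt(gamma_vw(g, v, w, 1)$first_deriv, 0)
      }
    }
  }
})

test_that("mean gamma reduces correctly and matches the complete-graph closed form", {
  # single weighted pair equals the direct evaluation
  p3 <- graph_path(3)
  p <- matrix(0, 3, 3)
  p[1, 3] <- 1
  s <- accessibility_setup(p3, p = p)
  expect_equal(mean_gamma(s, 0.5), gamma_vw(p3, 1, 3, 0.5)$value,
               tolerance = 1e-14)

  closed <- function(n, d, b) {
    -log(n) - b + d * log(exp(n * b) - 1) + (1 - d) * log(n - 1 + exp(n * b))
  }
  for (n in c(2, 4, 6)) {
    for (d in c(0.25, 0.5, 1)) {
      s <- setup_hamming(graph_complete(n), delta = d)
      for (b in c(0.2, 0.63, 1.4)) {
        expect_equal(mean_gamma(s, b), closed(n, d, b), tolerance = 1e-10)
      }
    }
  }

  # sign structure: negative near 0, positive for large t
  s <- setup_hamming(graph_complete(3), delta = 0.5)
  expect_lt(mean_gamma(s, 1e-3), 0)
  expect_gt(mean_gamma(s, 10), 0)

  # weight on an unreachable pair errors
  oneway <- allele_graph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  pbad <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  sbad <- accessibility_setup(oneway, p = pbad, check = FALSE)
  expect_error(mean_gamma(sbad, 1), class = "accperc_invalid_setup")
})

test_that("solver root residuals meet tolerance across builders and distances", {
  for (g in list(graph_complete(2), graph_complete(4), graph_path(3))) {
    for (d in c(0.25, 0.5, 1)) {
      fit <- solve_beta_star(setup_hamming(g, delta = d))
      expect_lt(abs(fit$residual), 1e-10)
      expect_gt(fit$gamma_prime_star, 0)
      expect_equal(fit$walk_length_factor,
                   fit$beta_star * fit$gamma_prime_star, tolerance = 1e-14)
    }
  }
  # no-return graph: stationary loci must sit on a mutant allele (the wild
  # type has no closed walk, so diagonal weight there is ill-posed)
  g <- graph_complete_no_return(3)
  for (d in c(0.25, 0.5, 1)) {
    p <- matrix(0, 3, 3)
    p[1, 2] <- d
    p[2, 2] <- 1 - d
    fit <- solve_beta_star(accessibility_setup(g, p = p))
    expect_lt(abs(fit$residual), 1e-10)
    expect_gt(fit$gamma_prime_star, 0)
  }
  # and diagonal weight on the wild type is rejected by validation
  expect_error(setup_hamming(graph_complete_no_return(3), delta = 0.5),
               class = "accperc_invalid_setup")
})

test_that("generic solver agrees with the closed forms to 1e-10", {
  for (n in 2:10) {
    generic <- solve_beta_star(setup_hamming(graph_complete(n), delta = 1))
    expect_equal(generic$beta_star, beta_star_complete_poly(n),
                 tolerance = 1e-10)

    nr <- beta_star_no_return(n)
    g <- graph_complete_no_return(n, wildtype = 1)
    p <- matrix(0, n, n)
    p[1, 2:n] <- 1 / (n - 1)
    fit <- solve_beta_star(accessibility_setup(g, p = p))
    expect_equal(fit$beta_star, unname(nr["beta_star"]), tolerance = 1e-10)
    expect_equal(fit$gamma_prime_star, unname(nr["gamma_prime_star"]),
                 tolerance = 1e-9)
  }
  expect_equal(beta_star_complete_poly(2), log(1 + sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(beta_star_no_return(2)), c(1, 1))
  expect_equal(unname(beta_star_no_return(3)), c(log(2), 2))
})

test_that("biallelic roots satisfy the sinh-cosh relation over a delta grid", {
  g <- graph_complete(2)
  for (d in seq(0.1, 1, by = 0.1)) {
    b <- solve_beta_star(setup_hamming(g, delta = d))$beta_star
    expect_equal(sinh(b)^d * cosh(b)^(1 - d), 1, tolerance = 1e-10)
  }
})

test_that("large-allele-count expansion error stays bounded", {
  # beta* = ln(A)/A + (1+ln A)/A^2 + O(ln A / A^3): the scaled remainder
  # |err| * A^3 / ln A must stay of order one across A
  scaled <- vapply(seq(20, 200, by = 20), function(n) {
    err <- beta_star_complete_poly(n) - log(n) / n - (1 + log(n)) / n^2
    abs(err) * n^3 / log(n)
  }, numeric(1))
  expect_lt(max(scaled), 10)
  expect_lt(max(scaled) / min(scaled), 10) # no blow-up across the range
})

test_that("threshold function c_L behaves as the finite-size transition point", {
  s <- setup_hamming(graph_complete(2), delta = 1)
  bs <- log(1 + sqrt(2))
  expect_equal(threshold_c_L(s, 100), bs - (1 / sqrt(2)) * log(100) / 100,
               tolerance = 1e-10)
  # approaches beta* from below and is increasing for L >= 3
  cl <- vapply(c(3, 10, 100, 1000, 1e5), function(L) threshold_c_L(s, L),
               numeric(1))
  expect_true(all(diff(cl) > 0))
  expect_lt(abs(cl[5] - bs), 1e-3)

  # finite-L weights route uses beta_hat
  pair <- genotype_pair(rep(1, 6), rep(2, 6))
  sM <- accessibility_setup(graph_complete(2), pair = pair)
  fit <- solve_beta_star(sM, use_finite_L = TRUE)
  expect_equal(fit$beta_star, bs, tolerance = 1e-10) # delta = 1 here too
  expect_false(is.na(fit$beta_hat))
})

test_that("walk-length moments match known critical values and are valid variances", {
  s2 <- setup_hamming(graph_complete(2), delta = 1)
  m2 <- walk_length_moments(s2, solve_beta_star(s2)$beta_star)
  expect_equal(m2$mu_per_locus, log(1 + sqrt(2)) * sqrt(2), tolerance = 1e-10)

  s21 <- setup_hamming(graph_complete(21), delta = 1)
  m21 <- walk_length_moments(s21, solve_beta_star(s21)$beta_star)
  expect_equal(round(m21$mu_per_locus, 2), 3.22)

  for (g in list(graph_complete(3), graph_path(4),
                 graph_complete_no_return(4))) {
    s <- setup_hamming(g, delta = 1)
    sig2 <- vapply(seq(0.05, 2, length.out = 100), function(b) {
      walk_length_moments(s, b)$sigma2_per_locus
    }, numeric(1))
    expect_true(all(sig2 >= 0))
  }
})
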