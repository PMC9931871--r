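test_that("landscape draws are seeded, pinned and uniform", {
  g <- graph_complete(2)
  pr <- genotype_pair(rep(1, 4), rep(2, 4))
  l1 <- draw_landscape(g, pr, beta = 0.7, seed = 12)
  l2 <- draw_landscape(g, pr, beta = 0.7, seed = 12)
  expect_identical(l1$fitness, l2$fitness)
  l3 <- draw_landscape(g, pr, beta = 0.7, seed = 13)
  expect_false(identical(l1$fitness, l3$fitness))

  expect_equal(l1$fitness[l1$a_id], 0)
  expect_equal(l1$fitness[l1$b_id], 0.7)

  lb1 <- draw_landscape(g, pr, beta = 1, seed = 5)
  expect_equal(diff(range(lb1$fitness[c(lb1$a_id, lb1$b_id)])), 1)

  # interior values are standard uniform: mean within 3 standard errors
  big <- draw_landscape(g, genotype_pair(rep(1, 14), rep(2, 14)),
                        beta = 0.5, seed = 31)
  vals <- big$fitness[-c(big$a_id, big$b_id)]
  expect_lt(abs(mean(vals) - 0.5), 3 * sqrt(1 / 12 / length(vals)))

  expect_error(draw_landscape(g, pr, beta = 1.2, seed = 1),
               class = "accperc_domain")
  expect_error(draw_landscape(g, genotype_pair(rep(1, 25), rep(2, 25)),
                              beta = 0.5, seed = 1),
               class = "accperc_resource_cap")
})

test_that("accessibility checking matches hand-worked landscapes", {
  g <- graph_complete(2)
  pr1 <- genotype_pair(1, 2)
  # single locus, direct arrow with higher endpoint fitness: accessible
  l <- hoc_landscape(g, pr1, fitness = c(0, 0.4))
  res <- is_accessible(l)
  expect_true(res$accessible)
  expect_equal(res$path, c(l$a_id, l$b_id))

  # two loci: fitness chosen so exactly one of the two length-2 paths works
  pr2 <- genotype_pair(c(1, 1), c(2, 2))
  # ids (locus 1 least significant): 1 = (1,1)=00, 2 = (2,1)=10,
  # 3 = (1,2)=01, 4 = (2,2)=11
  l2 <- hoc_landscape(g, pr2, fitness = c(0, 0.4, 0.9, 0.8))
  res2 <- is_accessible(l2)
  expect_true(res2$accessible)
  expect_equal(res2$path, c(1, 2, 4)) # 00 -> 10 -> 11; 00 -> 01 -> 11 blocked

  # witness paths are always simple and strictly fitness-increasing
  set.seed(99)
  for (k in 1:20) {
    lr <- draw_landscape(g, genotype_pair(rep(1, 5), rep(2, 5)),
                         beta = runif(1, 0.4, 1), seed = k)
    r <- is_accessible(lr)
    if (r$accessible) {
      expect_false(anyDuplicated(r$path) > 0)
      expect_true(all(diff(lr$fitness[r$path]) > 0))
    }
  }
})

test_that("a mixed two-locus space reproduces the depicted accessibility pattern", {
  # locus 1: alleles u0 -> u1 (irreversible), u1 <-> u2; locus 2: a free
  # triangle w0, w1, w2. Modeled as one allele graph that is the disjoint
  # union of both, with locus 1 restricted to the u component and locus 2 to
  # the w component.
  labs <- c("u0", "u1", "u2", "w0", "w1", "w2")
  adj <- matrix(0L, 6, 6, dimnames = list(labs, labs))
  adj["u0", "u1"] <- 1L
  adj["u1", "u2"] <- 1L
  adj["u2", "u1"] <- 1L
  for (i in 4:6) for (j in 4:6) if (i != j) adj[i, j] <- 1L
  g <- allele_graph(adj)

  gid <- function(l1, l2) getFromNamespace("genotype_id", "accperc")(
    c(match(l1, g$labels), match(l2, g$labels)), g$n)
  fitness <- rep(NA_real_, g$n^2)
  # ordering consistent with the depicted realization: (u1,w0) is the global
  # minimum, (u1,w2) the global maximum, reachable both directly and via
  # (u2,w0) -> (u2,w2); (u0,w1) sits above all of its mutational neighbours,
  # so nothing (in particular not the maximum) is accessible from it
  ord <- c("u1.w0" = 0.05, "u0.w0" = 0.10, "u0.w2" = 0.20, "u1.w1" = 0.30,
           "u2.w0" = 0.40, "u2.w1" = 0.50, "u0.w1" = 0.60, "u2.w2" = 0.70,
           "u1.w2" = 0.95)
  combos <- expand.grid(l1 = c("u0", "u1", "u2"), l2 = c("w0", "w1", "w2"),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    key <- paste(combos$l1[k], combos$l2[k], sep = ".")
    fitness[gid(combos$l1[k], combos$l2[k])] <- unname(ord[key])
  }
  fitness[is.na(fitness)] <- seq(0.0001, 0.001,
                                 length.out = sum(is.na(fitness)))

  up <- hoc_landscape(g, genotype_pair(c("u1", "w0"), c("u1", "w2")), fitness)
  r1 <- is_accessible(up)
  expect_true(r1$accessible)

  blocked <- hoc_landscape(g, genotype_pair(c("u0", "w1"), c("u1", "w2")),
                           fitness)
  expect_false(is_accessible(blocked)$accessible)
})

test_that("linear-extension DP matches brute force on random posets", {
  set.seed(5)
  dp <- getFromNamespace("count_linear_extensions", "accperc")
  bf <- getFromNamespace("count_linear_extensions_bruteforce", "accperc")
  for (rep in 1:25) {
    m <- sample(1:5, 1)
    pred <- integer(m)
    for (j in seq_len(m)) {
      below <- seq_len(j - 1)
      if (length(below) > 0) {
        take <- below[runif(length(below)) < 0.4]
        pred[j] <- sum(2^(take - 1))
      }
    }
    expect_equal(dp(pred, m), bf(pred, m))
  }
  # a chain has exactly one extension; an antichain has m!
  expect_equal(dp(c(0L, 1L, 3L), 3), 1)
  expect_equal(dp(c(0L, 0L, 0L), 3), 6)
})

test_that("exact inclusion-exclusion probability matches hand-derived values", {
  g <- graph_complete(2)
  # single path with k interiors: beta^k / k!
  p4 <- graph_path(4)
  pr <- genotype_pair(1, 4)
  for (b in c(0.3, 0.9)) {
    expect_equal(exact_accessibility_small(p4, pr, b), b^2 / 2,
                 tolerance = 1e-12)
  }
  # two disjoint single-interior chains
  pr2 <- genotype_pair(c(1, 1), c(2, 2))
  for (b in c(0.25, 0.5, 1)) {
    expect_equal(exact_accessibility_small(g, pr2, b), 2 * b - b^2,
                 tolerance = 1e-12)
  }
  expect_error(
    exact_accessibility_small(graph_complete(3),
                              genotype_pair(rep(1, 3), rep(2, 3)), 0.5),
    class = "accperc_resource_cap")
})

test_that("Monte-Carlo estimates agree with the exact oracle within 4 se", {
  set.seed(88)
  cases <- list(
    list(g = graph_complete(2), L = 2, beta = 0.5),
    list(g = graph_complete(2), L = 2, beta = 1),
    list(g = graph_path(3), L = 1, beta = 0.8),
    list(g = graph_complete_no_return(2), L = 2, beta = 0.7),
    list(g = graph_complete(3), L = 1, beta = 0.6)
  )
  for (cs in cases) {
    pr <- genotype_pair(rep(1, cs$L), rep(2, cs$L))
    exact <- exact_accessibility_small(cs$g, pr, cs$beta)
    for (m in c("conditioned", "thinning")) {
      sm <- estimate_accessibility(cs$g, pr, cs$beta, reps = 40000,
                                   seed = 17, method = m)
      se <- max(sqrt(exact * (1 - exact) / sm$reps), 1 / sm$reps)
      expect_lt(abs(sm$p_hat - exact), 4 * se + 1e-12)
    }
  }
  # beta = 1 on the biallelic square is always accessible
  pr <- genotype_pair(c(1, 1), c(2, 2))
  expect_equal(exact_accessibility_small(graph_complete(2), pr, 1), 1)
})

test_that("estimator is deterministic in the seed and monotone in beta by coupling", {
  g <- graph_complete(2)
  pr <- genotype_pair(rep(1, 6), rep(2, 6))
  s1 <- estimate_accessibility(g, pr, 0.6, reps = 2000, seed = 4)
  s2 <- estimate_accessibility(g, pr, 0.6, reps = 2000, seed = 4)
  expect_identical(glance(s1), glance(s2))
  expect_identical(s1$path_lengths, s2$path_lengths)

  ps <- vapply(c(0.2, 0.5, 0.8), function(b) {
    estimate_accessibility(g, pr, b, reps = 3000, seed = 42)$p_hat
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("path-graph homopolymers stay inaccessible in simulation", {
  # beta* ~ 1.25 > 1 for end-to-end traversal of the 3-vertex path graph
  sm <- estimate_accessibility(graph_path(3),
                               genotype_pair(rep(1, 6), rep(3, 6)),
                               beta = 1, reps = 4000, seed = 23)
  expect_lte(sm$p_hat, 0.05)
})

test_that("threshold_scan returns a tidy long table with coupled curves", {
  sc <- threshold_scan(graph_complete(2), L_list = c(3, 4),
                       beta_grid = c(0.4, 0.7, 1), reps = 1500, seed = 2)
  expect_s3_class(sc, "tbl_df")
  expect_equal(nrow(sc), 6)
  expect_true(all(c("L", "beta", "p_hat", "ci_low", "ci_high",
                    "mean_path_length") %in% names(sc)))
  expect_true(all(sc$ci_low <= sc$p_hat & sc$p_hat <= sc$ci_high))
  # coupling: p_hat non-decreasing in beta within each L
  for (L in c(3, 4)) {
    sub <- sc[sc$L == L, ]
    expect_true(all(diff(sub$p_hat[order(sub$beta)]) >= 0))
  }
})
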