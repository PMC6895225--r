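# The FOCS scorer: node p-values, the minimum-order-statistic score, the
# iterative worst-node algorithm, and the batch drivers.

test_that("node_pvalues recomputes through the reference route", {
  set.seed(21)
  g <- random_multigraph(12)
  members <- sample(g$nodes, 5)
  cm <- community(members)
  eps <- stats::setNames(runif(5), members)
  pv <- node_pvalues(g, cm, quantiles = eps)
  expect_setequal(pv$node, members)
  expect_equal(pv$pvalue, 1 - pv$quantile)
  expect_true(all(diff(pv$pvalue) <= 0))
  for (k in seq_len(nrow(pv))) {
    u <- pv$node[k]
    cq <- corrected_quantile(external_view(g, cm, u),
                             community_indegree(g, cm, u),
                             quantile = unname(eps[u]))
    expect_equal(pv$quantile[k], cq$value)
  }
})

test_that("a 2-clique community yields two unit in-degrees", {
  set.seed(22)
  g <- focs_graph(rbind(random_multigraph(6)$edges,
                        data.frame(from = "p", to = "q", mult = 1)))
  pv <- node_pvalues(g, community(c("p", "q")), seed = 1)
  expect_equal(nrow(pv), 2)
  expect_equal(pv$in_degree, c(1, 1))
})

test_that("min_order_cdf endpoints and closed form", {
  expect_equal(min_order_cdf(0.3, 0.3, 17), 0)
  expect_equal(min_order_cdf(1, 0.3, 17), 1)
  expect_equal(min_order_cdf(0.5, 0, 2), 0.75)
  # m = 1, a = 0 is the identity map
  for (x in c(0.1, 0.5, 0.9)) expect_equal(min_order_cdf(x, 0, 1), x)
  expect_equal(min_order_cdf(1, 1, 5), 1)
  expect_error(min_order_cdf(0.2, 0.4, 3), class = "focs_domain_error")
})

test_that("single_f is the composition of its documented parts", {
  set.seed(23)
  g <- random_multigraph(20)
  members <- sample(g$nodes, 6)
  cm <- community(members)
  eps <- stats::setNames(runif(6), members)
  f <- single_f(g, cm, quantiles = eps)
  pv <- node_pvalues(g, cm, quantiles = eps)
  m <- length(g$nodes) - 6 + 1
  expect_equal(f, 1 - ((1 - pv$pvalue[1]) / (1 - pv$pvalue[2]))^m)
  expect_scalar_prob(f)
  # equal top p-values sit at the lower endpoint of F_(1)
  expect_equal(min_order_cdf(pv$pvalue[2], pv$pvalue[2], m), 0)
})

test_that("iteration counts follow the ceiling rule under the budget rule", {
  set.seed(24)
  g <- random_multigraph(16, p = 0.5)
  c3 <- community(sample(g$nodes, 3))
  r3 <- focs_score(g, c3, rho = 0.25, seed = 1, stop_rule = "budget")
  expect_equal(r3$n_tested, 1)   # ceiling(0.75) = 1

  c8 <- community(sample(g$nodes, 8))
  r8 <- focs_score(g, c8, rho = 0.25, seed = 1, stop_rule = "budget")
  expect_equal(r8$n_tested, 2)   # ceiling(2) = 2
  expect_equal(r8$score, min(r8$iteration_f))
  expect_equal(length(r8$removal_order), r8$n_tested)

  # the improving rule never tests more than the budget, and the first
  # iteration is identical under both rules
  ri <- focs_score(g, c8, rho = 0.25, seed = 1)
  expect_lte(ri$n_tested, 2)
  expect_equal(ri$iteration_f[1], r8$iteration_f[1])
  expect_equal(ri$score, min(ri$iteration_f))
})

test_that("the improving rule stops at the first non-decreasing f", {
  set.seed(25)
  for (i in 1:10) {
    g <- random_multigraph(15, p = 0.5)
    cm <- community(sample(g$nodes, 8))
    r <- focs_score(g, cm, rho = 1, seed = i)
    fs <- r$iteration_f
    if (length(fs) >= 2) {
      expect_true(all(diff(fs[-length(fs)]) < 0))
      if (r$n_tested < community_size(cm) - 1) {
        # stopped before the budget/degeneracy limit: the last f rose
        expect_gt(fs[length(fs)], fs[length(fs) - 1])
      }
    }
    expect_equal(r$score, min(fs))
  }
})

test_that("focs_score validates its inputs", {
  g <- cycle_graph(6)
  cm <- community(c("1", "2", "3"))
  expect_error(focs_score(g, cm, rho = 0), class = "focs_parameter_error")
  expect_error(focs_score(g, cm, rho = 1.5), class = "focs_parameter_error")
  expect_error(focs_score(g, community("1"), seed = 1),
               class = "focs_validation_error")
})

test_that("scores are reproducible and within [0, 1]", {
  set.seed(26)
  g <- random_multigraph(18, p = 0.4)
  cm <- community(sample(g$nodes, 7))
  a <- focs_score(g, cm, seed = 99)
  b <- focs_score(g, cm, seed = 99)
  expect_identical(a, b)
  expect_scalar_prob(a$score)
  expect_lte(a$score, a$iteration_f[1])
})

test_that("raising the worst node's observed in-degree lowers its p-value", {
  # the pure continuity-correction mechanism: same null parameters, same
  # uniform deviate, larger observed in-degree => weakly larger quantile
  set.seed(27)
  for (i in 1:20) {
    s <- sample(3:20, 1); f <- sample(3:20, 1)
    k <- sample(2:min(s, s + f), 1)
    p <- null_params(k, s, f)
    supp <- null_support(p)
    if (supp[2] - supp[1] < 1) next
    a <- sample(supp[1]:(supp[2] - 1), 1)
    u <- runif(1)
    q1 <- corrected_quantile(p, a, quantile = u)$value
    q2 <- corrected_quantile(p, a + 1, quantile = u)$value
    expect_gte(q2, q1)
  }
})

test_that("rewiring an external edge of the worst node into C lowers f", {
  # common random numbers end-to-end: move one external edge of the worst
  # node into the community; while that node remains the worst, f must not
  # increase
  set.seed(28)
  tried <- 0
  for (i in 1:30) {
    g <- random_multigraph(14, p = 0.45, max_mult = 1)
    members <- sample(g$nodes, 5)
    cm <- community(members)
    eps <- stats::setNames(runif(5), members)
    pv <- node_pvalues(g, cm, quantiles = eps)
    worst <- pv$node[1]
    ext_nb <- setdiff(g$nodes[as.vector(g$A[worst, ] > 0)], members)
    int_non_nb <- setdiff(members[as.vector(g$A[worst, members] == 0)], worst)
    if (length(ext_nb) == 0 || length(int_non_nb) == 0) next
    tried <- tried + 1
    e <- g$edges
    drop_row <- which((e$from == worst & e$to == ext_nb[1]) |
                        (e$to == worst & e$from == ext_nb[1]))[1]
    e <- e[-drop_row, ]
    e <- rbind(e, data.frame(from = worst, to = int_non_nb[1], mult = 1))
    g2 <- focs_graph(e, nodes = g$nodes)
    pv2 <- node_pvalues(g2, cm, quantiles = eps)
    if (pv2$node[1] != worst) next
    f1 <- single_f(g, cm, quantiles = eps)
    f2 <- single_f(g2, cm, quantiles = eps)
    expect_lte(f2, f1 + 1e-12)
  }
  expect_gte(tried, 5)
})

test_that("bipartite scoring pools both sides and degenerates gracefully", {
  bg <- toy_bipartite()
  bc <- bipartite_community(c("a", "b"), c("x", "y"))
  r <- focs_score(bg, bc, seed = 3)
  expect_scalar_prob(r$score)
  pv <- node_pvalues(bg, bc, seed = 3)
  expect_setequal(pv$node, c("a", "b", "x", "y"))
  # one-sided community is rejected at construction, not a crash
  expect_error(bipartite_community(character(0), c("x")),
               class = "focs_validation_error")
  # removal never empties a side
  r2 <- focs_score(bg, bipartite_community(c("a", "b"), "x"),
                   rho = 1, seed = 4, stop_rule = "budget")
  expect_lte(r2$n_tested, 3)
})

test_that("score_collection reports per-community rows and the proportion", {
  set.seed(29)
  g <- random_multigraph(20, p = 0.35)
  comms <- list(community(sample(g$nodes, 5), id = "c1"),
                community(sample(g$nodes, 8), id = "c2"),
                community(g$nodes, id = "bad"),
                community(sample(g$nodes, 2), id = "tiny"))
  res <- score_collection(g, comms, seed = 10)
  expect_equal(nrow(res), 4)
  expect_equal(res$community_id, c("c1", "c2", "bad", "tiny"))
  expect_true(res$error[3] != "" && is.na(res$score[3]))
  expect_true(res$trivial[4] && !res$trivial[1])
  scored <- res$score[!is.na(res$score)]
  expect_equal(attr(res, "proportion_significant"), mean(scored < 0.05))
  # deterministic under the master seed, and stable per community
  res2 <- score_collection(g, comms, seed = 10)
  expect_identical(res, res2)

  empty <- score_collection(g, list(), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(is.na(attr(empty, "proportion_significant")))
})

test_that("corrected-quantile steps narrow as the null pools grow", {
  # the mechanism behind score stability on dense graphs: with all
  # parameters scaled up, the CDF step containing a mid-support observation
  # shrinks, so the g-hat draw (and hence the score) has less room to move
  max_step <- function(p) {
    supp <- null_support(p)
    max(null_pmf(p, supp[1]:supp[2]))
  }
  small <- null_params(5, 10, 30)
  for (scale in c(10, 100)) {
    big <- null_params(5 * scale, 10 * scale, 30 * scale)
    expect_lt(max_step(big), max_step(small))
  }
})

test_that("stability_cv returns a finite nonnegative coefficient", {
  set.seed(30)
  g <- random_multigraph(15, p = 0.5)
  cm <- community(sample(g$nodes, 6))
  cv <- stability_cv(g, cm, n_runs = 10, seed = 5)
  expect_true(is.finite(cv) && cv >= 0)
  expect_identical(cv, stability_cv(g, cm, n_runs = 10, seed = 5))
  expect_error(stability_cv(g, cm, n_runs = 1))
})
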