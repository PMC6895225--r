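# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

cycle_graph <- function(n) {
  ids <- as.character(seq_len(n))
  focs_graph(data.frame(from = ids, to = ids[c(2:n, 1)]))
}

path_graph <- function(ids) {
  focs_graph(data.frame(from = ids[-length(ids)], to = ids[-1]))
}

# Erdos-Renyi-style multigraph with random multiplicities on a fixed node set
random_multigraph <- function(n, p = 0.4, max_mult = 3) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  focs_graph(data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                        mult = sample(max_mult, sum(keep), replace = TRUE)),
             nodes = ids)
}

# independent brute-force degree bookkeeping straight off the dense adjacency
brute_degree_summary <- function(graph, members) {
  A <- as.matrix(graph$A)
  Cp <- setdiff(graph$nodes, members)
  d <- rowSums(A)
  list(d_C = sum(d[members]),
       cross = sum(A[members, Cp, drop = FALSE]),
       external_internal = sum(A[Cp, Cp, drop = FALSE]),
       d_Cp = sum(d[Cp]))
}

toy_bipartite <- function() {
  focs_graph(data.frame(
    from = c("a", "a", "b", "b", "c", "d"),
    to   = c("x", "y", "x", "z", "y", "z")), bipartite = TRUE)
}

expect_scalar_prob <- function(x) {
  expect_true(is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1)
}
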