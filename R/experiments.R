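# Simulation harness: null calibration on configuration-model networks and a
# power study on planted-partition networks. Community detection is
# pluggable — any callback that maps a focs_graph to a list of node-id
# vectors works; Louvain (via igraph) is the default, with a greedy
# modularity detector as an alternative.

#' Convert to an igraph object
#'
#' Edge multiplicities become edge weights; bipartite side labels become the
#' `type` vertex attribute (TRUE for side V).
#'
#' @param graph a `focs_graph`.
#' @return an igraph graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "focs_graph"))
  verts <- data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  if (graph$bipartite) verts$type <- graph$side[graph$nodes] == "V"
  ed <- graph$edges
  names(ed) <- c("from", "to", "weight")
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

partition_to_list <- function(membership, names) {
  unname(split(names, membership))
}

#' Louvain community detection callback
#'
#' Multi-level modularity optimization (weights = edge multiplicities).
#' Randomized: the vertex processing order depends on the R RNG stream.
#'
#' @param graph a `focs_graph`.
#' @return list of character vectors (one node-id set per community).
#' @export
detect_louvain <- function(graph) {
  ig <- as_igraph(graph)
  cl <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
  partition_to_list(igraph::membership(cl), igraph::V(ig)$name)
}

#' Greedy modularity community detection callback
#'
#' Deterministic agglomerative fallback (no randomized step); multi-edges are
#' collapsed to weights first, as the agglomerative implementation requires a
#' simple graph.
#'
#' @param graph a `focs_graph`.
#' @return list of character vectors.
#' @export
detect_fast_greedy <- function(graph) {
  ig <- igraph::simplify(as_igraph(graph),
                         edge.attr.comb = list(weight = "sum"))
  cl <- igraph::cluster_fast_greedy(ig, weights = igraph::E(ig)$weight)
  partition_to_list(igraph::membership(cl), igraph::V(ig)$name)
}

#' Best-of-n Louvain partition
#'
#' Runs Louvain `n_starts` times with different randomized initializations and
#' keeps the partition with the highest (weighted) modularity.
#'
#' @param graph a `focs_graph`.
#' @param n_starts number of restarts (default 50).
#' @param seed optional integer seed.
#' @return list of character vectors.
#' @export
louvain_best_partition <- function(graph, n_starts = 50L, seed = NULL) {
  ig <- as_igraph(graph)
  w <- igraph::E(ig)$weight
  with_seed_or_stream(seed, {
    best <- NULL; best_q <- -Inf
    for (i in seq_len(n_starts)) {
      cl <- igraph::cluster_louvain(ig, weights = w)
      q <- igraph::modularity(ig, igraph::membership(cl), weights = w)
      if (q > best_q) { best_q <- q; best <- cl }
    }
    partition_to_list(igraph::membership(best), igraph::V(ig)$name)
  })
}

#' Configuration for the null-calibration experiment
#'
#' Defaults follow the no-community benchmark: configuration-model networks
#' of 100 nodes with power-law(-2) degrees truncated to \[10, 50\], one
#' randomly chosen non-trivial detected community scored per network.
#'
#' @param n_networks number of null networks (200 at desk scale).
#' @param n_nodes nodes per network.
#' @param exponent,dmin,dmax degree-sequence parameters.
#' @param alpha_grid nominal levels at which the false-positive rate is read.
#' @param rho fraction tested by the scorer.
#' @param seed master integer seed.
#' @return list of class `null_config`.
#' @export
null_config <- function(n_networks = 200L, n_nodes = 100L, exponent = -2,
                        dmin = 10L, dmax = 50L,
                        alpha_grid = c(0.05, 0.1, 0.25, 0.5),
                        rho = 0.25, seed = 1L) {
  stopifnot(is_count(n_networks), n_networks >= 1,
            is_count(n_nodes), n_nodes > dmax, exponent < 0,
            all(alpha_grid > 0), all(alpha_grid < 1))
  structure(list(n_networks = as.integer(n_networks),
                 n_nodes = as.integer(n_nodes), exponent = exponent,
                 dmin = as.integer(dmin), dmax = as.integer(dmax),
                 alpha_grid = sort(alpha_grid), rho = rho,
                 seed = as.integer(seed)),
            class = "null_config")
}

#' Empirical false-positive rate of the score on null networks
#'
#' For each simulated configuration-model network: run the detector, choose
#' one community with more than two members uniformly at random, and score it.
#' Networks whose detector returns no non-trivial community are skipped and
#' counted. The returned table reports, per nominal level alpha, the fraction
#' of scores at or below alpha with its binomial standard error.
#'
#' @param config a [null_config()].
#' @param detector partition callback (default [detect_louvain()]).
#' @param progress logical; log one line per 50 networks to stderr.
#' @return list with `table` (columns `alpha`, `fpr`, `se`, `n`), `scores`,
#'   and `n_skipped`.
#' @export
null_calibration <- function(config, detector = detect_louvain,
                             progress = FALSE) {
  stopifnot(inherits(config, "null_config"), is.function(detector))
  seeds <- derive_seeds(config$seed, config$n_networks)
  scores <- rep(NA_real_, config$n_networks)
  skipped <- 0L
  for (i in seq_len(config$n_networks)) {
    scores[i] <- withr::with_seed(seeds[i], {
      d <- sample_powerlaw_degrees(config$n_nodes, config$exponent,
                                   config$dmin, config$dmax)
      g <- configuration_model_graph(d)
      parts <- detector(g)
      parts <- parts[vapply(parts, length, 1L) > 2L]
      if (length(parts) == 0L) NA_real_ else {
        pick <- parts[[sample.int(length(parts), 1L)]]
        focs_score(g, community(pick, id = sprintf("net%d", i)),
                   rho = config$rho)$score
      }
    })
    if (is.na(scores[i])) skipped <- skipped + 1L
    if (progress && i %% 50L == 0L) {
      message(sprintf("null_calibration: %d/%d networks", i,
                      config$n_networks))
    }
  }
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  fpr <- vapply(config$alpha_grid, function(al) mean(scores <= al), 1.0)
  tab <- data.frame(alpha = config$alpha_grid, fpr = fpr,
                    se = sqrt(fpr * (1 - fpr) / n), n = n)
  list(table = tab, scores = scores, n_skipped = skipped)
}

#' Largest level up to which the score is conservative
#'
#' Reads a calibration table and returns the largest grid level alpha* such
#' that fpr(alpha) <= alpha + 2 se(alpha) for every grid level alpha <=
#' alpha*; NA if the condition already fails at the smallest level.
#'
#' @param table calibration table from [null_calibration()].
#' @return scalar level, or NA.
#' @export
conservative_alpha <- function(table) {
  ok <- table$fpr <= table$alpha + 2 * table$se
  run <- cumprod(ok) == 1
  if (!any(run)) NA_real_ else max(table$alpha[run])
}

#' Median score versus community mixing
#'
#' For each mixing parameter mu in the config's grid, simulates `reps`
#' planted-partition networks, scores every ground-truth community, and
#' summarizes the scores (median and 5%/95% percentiles). Scores shrink
#' toward 0 as mu drops, so medians are best read on a log scale; exact zeros
#' are floored at the smallest positive double before taking logs downstream.
#'
#' @param config a [power_config()].
#' @param detector optional partition callback; when supplied, detected
#'   communities with more than two members are scored instead of the planted
#'   ground truth.
#' @param progress logical; log one line per mu to stderr.
#' @return data frame with columns `mu`, `median_score`, `q05`, `q95`,
#'   `n_communities`.
#' @export
power_curve <- function(config, detector = NULL, progress = FALSE) {
  stopifnot(inherits(config, "power_config"))
  seeds <- derive_seeds(config$seed, length(config$mu_grid))
  rows <- lapply(seq_along(config$mu_grid), function(k) {
    mu <- config$mu_grid[k]
    scores <- withr::with_seed(seeds[k], {
      unlist(lapply(seq_len(config$reps), function(r) {
        pp <- planted_partition_graph(config, mu)
        comms <- if (is.null(detector)) pp$communities else {
          parts <- detector(pp$graph)
          parts <- parts[vapply(parts, length, 1L) > 2L]
          lapply(seq_along(parts), function(j) {
            community(parts[[j]], id = sprintf("det%d", j))
          })
        }
        vapply(comms, function(cm) {
          focs_score(pp$graph, cm, rho = config$rho)$score
        }, 1.0)
      }))
    })
    if (progress) message(sprintf("power_curve: mu = %g done (%d scores)",
                                  mu, length(scores)))
    data.frame(mu = mu,
               median_score = stats::median(scores),
               q05 = stats::quantile(scores, 0.05, names = FALSE),
               q95 = stats::quantile(scores, 0.95, names = FALSE),
               n_communities = length(scores))
  })
  do.call(rbind, rows)
}

#' Zachary karate club network
#'
#' The standard 34-node, 78-edge social network, exposed as a `focs_graph`
#' (taken from igraph's built-in copy).
#'
#' @return a `focs_graph`.
#' @export
karate_graph <- function() {
  ig <- igraph::make_graph("Zachary")
  el <- igraph::as_edgelist(ig, names = FALSE)
  focs_graph(data.frame(from = sprintf("v%02d", el[, 1L]),
                        to = sprintf("v%02d", el[, 2L]),
                        mult = 1, stringsAsFactors = FALSE))
}
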