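# Synthetic network generators: configuration-model null networks and
# planted-partition community networks. Everything the simulation harness
# needs is generated in code, so no external data is required.

#' Sample a truncated power-law degree sequence
#'
#' n i.i.d. draws from P(d) proportional to d^exponent on the integer range
#' \[dmin, dmax\]. The sum is forced even (a configuration-model requirement)
#' by resampling one entry until parity holds.
#'
#' @param n number of nodes.
#' @param exponent power-law exponent (negative; default -2).
#' @param dmin,dmax inclusive degree range (defaults 10 and 50).
#' @param seed optional integer seed.
#' @return integer vector of length n with even sum.
#' @export
sample_powerlaw_degrees <- function(n, exponent = -2, dmin = 10L, dmax = 50L,
                                    seed = NULL) {
  if (!is_count(n) || n < 1 || !is_count(dmin) || dmin < 1 ||
      !is_count(dmax) || dmax < dmin || !(exponent < 0)) {
    stop_focs("need n >= 1, 1 <= dmin <= dmax, exponent < 0",
              class = "focs_parameter_error")
  }
  support <- dmin:dmax
  prob <- support^exponent
  draw <- function(k) support[sample.int(length(support), k, replace = TRUE,
                                         prob = prob)]
  with_seed_or_stream(seed, {
    d <- draw(n)
    while (sum(d) %% 2 != 0) {
      d[sample.int(n, 1L)] <- draw(1L)
    }
    d
  })
}

match_stubs <- function(stubs) {
  # uniform perfect matching of a stub vector (node indices, one entry per
  # stub); self-loop pairs are dropped, consistent with the loader
  stopifnot(length(stubs) %% 2 == 0)
  if (length(stubs) == 0L) {
    return(list(edges = cbind(integer(), integer()), dropped = 0L))
  }
  perm <- sample(stubs)
  half <- length(perm) / 2
  from <- perm[seq_len(half)]
  to <- perm[half + seq_len(half)]
  loop <- from == to
  list(edges = cbind(from[!loop], to[!loop]), dropped = sum(loop))
}

#' Configuration-model random multigraph
#'
#' Uniform stub matching for a given degree sequence. Stub pairs that form
#' self-loops are dropped (logged in the graph's `dropped_self_loops`), so
#' realized degrees can fall below the request by the dropped stubs;
#' multi-edges are kept.
#'
#' @param degrees integer degree sequence with even sum.
#' @param seed optional integer seed.
#' @return a [focs_graph()] with node ids `"n1" ... "n<length(degrees)>"`.
#' @export
configuration_model_graph <- function(degrees, seed = NULL) {
  if (sum(degrees) %% 2 != 0) {
    stop_focs("degree sequence must have even sum",
              class = "focs_parameter_error")
  }
  n <- length(degrees)
  ids <- sprintf("n%d", seq_len(n))
  with_seed_or_stream(seed, {
    m <- match_stubs(rep(seq_len(n), degrees))
    edges <- data.frame(from = ids[m$edges[, 1L]], to = ids[m$edges[, 2L]],
                        mult = 1, stringsAsFactors = FALSE)
    g <- suppressWarnings(focs_graph(edges, nodes = ids))
    g$dropped_self_loops <- m$dropped
    g
  })
}

#' Configuration for the power (planted-partition) experiment
#'
#' @param n_nodes network size (default 1000).
#' @param size_range inclusive community size range (default c(10, 50)).
#' @param mu_grid mixing parameters in \[0,1\]: the fraction of each node's
#'   stubs pointed outside its community (0 = fully separated, 1 = fully
#'   mixed).
#' @param reps networks per mu value.
#' @param exponent,dmin,dmax degree-sequence parameters, as in
#'   [sample_powerlaw_degrees()].
#' @param rho fraction tested by the scorer.
#' @param seed master integer seed.
#' @return list of class `power_config`.
#' @export
power_config <- function(n_nodes = 1000L, size_range = c(10L, 50L),
                         mu_grid = seq(0.1, 0.9, by = 0.2), reps = 3L,
                         exponent = -2, dmin = 10L, dmax = 50L,
                         rho = 0.25, seed = 1L) {
  stopifnot(all(mu_grid >= 0), all(mu_grid <= 1), is_count(reps), reps >= 1,
            length(size_range) == 2L, size_range[1L] >= 2,
            size_range[2L] >= size_range[1L], size_range[2L] <= n_nodes)
  structure(list(n_nodes = as.integer(n_nodes),
                 size_range = as.integer(size_range),
                 mu_grid = mu_grid, reps = as.integer(reps),
                 exponent = exponent, dmin = as.integer(dmin),
                 dmax = as.integer(dmax), rho = rho,
                 seed = as.integer(seed)),
            class = "power_config")
}

#' Planted-partition community network
#'
#' Partitions the nodes into communities with sizes drawn uniformly from
#' `size_range`, samples a truncated power-law degree sequence, and splits
#' each node's stubs into an internal part (fraction about 1 - mu, matched
#' within the community) and an external part (fraction mu, matched globally
#' across communities). mu = 0 gives externally disconnected communities;
#' mu = 1 removes any within-community preference. Self-loop stub pairs are
#' dropped; multi-edges are kept.
#'
#' @param config a [power_config()] (its `mu_grid`/`reps`/`rho`/`seed` fields
#'   are ignored here).
#' @param mu mixing parameter in \[0,1\].
#' @param seed optional integer seed.
#' @return list with `graph` (a `focs_graph`) and `communities` (ground-truth
#'   list of [community()] objects).
#' @export
planted_partition_graph <- function(config, mu, seed = NULL) {
  stopifnot(inherits(config, "power_config"), mu >= 0, mu <= 1)
  n <- config$n_nodes
  ids <- sprintf("n%d", seq_len(n))
  with_seed_or_stream(seed, {
    # carve node ids into communities; the final block absorbs the remainder
    # (merged into the previous community if it would fall below the minimum)
    sizes <- integer(0)
    left <- n
    while (left > 0L) {
      s <- sample(config$size_range[1L]:config$size_range[2L], 1L)
      if (s >= left) { sizes <- c(sizes, left); left <- 0L }
      else { sizes <- c(sizes, s); left <- left - s }
    }
    if (length(sizes) > 1L && sizes[length(sizes)] < config$size_range[1L]) {
      sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] +
        sizes[length(sizes)]
      sizes <- sizes[-length(sizes)]
    }
    membership <- rep(seq_along(sizes), sizes)

    d <- sample_powerlaw_degrees(n, config$exponent, config$dmin, config$dmax)
    d_int <- round((1 - mu) * d)

    edge_mat <- matrix(integer(), 0L, 2L)
    dropped <- 0L
    for (k in seq_along(sizes)) {
      nodes_k <- which(membership == k)
      dk <- d_int[nodes_k]
      if (sum(dk) %% 2 != 0) {
        # fix parity inside the community by pushing one stub external
        # (at mu = 0 that lone external stub is unmatched and dropped below)
        j <- which.max(dk)
        dk[j] <- dk[j] - 1L
        d_int[nodes_k] <- dk
      }
      m <- match_stubs(rep(nodes_k, dk))
      edge_mat <- rbind(edge_mat, m$edges)
      dropped <- dropped + m$dropped
    }
    d_ext <- d - d_int
    if (mu == 0) d_ext[] <- 0L  # guarantee externally disconnected communities
    if (sum(d_ext) %% 2 != 0) {
      j <- which.max(d_ext)
      d_ext[j] <- d_ext[j] - 1L
    }
    m <- match_stubs(rep(seq_len(n), d_ext))
    edge_mat <- rbind(edge_mat, m$edges)
    dropped <- dropped + m$dropped

    edges <- data.frame(from = ids[edge_mat[, 1L]], to = ids[edge_mat[, 2L]],
                        mult = 1, stringsAsFactors = FALSE)
    g <- suppressWarnings(focs_graph(edges, nodes = ids))
    g$dropped_self_loops <- dropped
    comms <- lapply(seq_along(sizes), function(k) {
      community(ids[membership == k], id = sprintf("pp%d", k))
    })
    list(graph = g, communities = comms)
  })
}
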