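# Graph and community containers.
#
# Networks are undirected multigraphs over a fixed node universe: integer edge
# multiplicities, no self-loops, optionally bipartite with a side label (U/V)
# per node. The adjacency is held as a symmetric sparse matrix so that the
# degree sums the null model needs are plain row/submatrix sums.

#' Construct a network from an edge table
#'
#' @param edges a data frame (or coercible) whose first two columns are node
#'   identifiers and whose optional third column is a positive integer edge
#'   multiplicity (default 1). Duplicate rows accumulate multiplicity;
#'   self-loop rows are dropped with a warning.
#' @param bipartite logical; if `TRUE`, column 1 nodes form side U and column 2
#'   nodes side V unless `sides` is given.
#' @param sides optional named character vector mapping node id to `"U"` or
#'   `"V"`; overrides the column convention and may declare isolated nodes.
#' @param nodes optional character vector of node ids to include even when
#'   isolated (degree 0).
#'
#' @return An object of class `focs_graph`: a list with elements `nodes`
#'   (sorted ids), `A` (symmetric sparse adjacency with multiplicities),
#'   `degree` (named vector), `bipartite`, `side`, and `dropped_self_loops`.
#' @export
focs_graph <- function(edges, bipartite = FALSE, sides = NULL, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_focs("edge table needs at least two columns")
  mult <- if (ncol(edges) >= 3L) edges[[3L]] else rep(1, nrow(edges))
  if (!is.numeric(mult) || any(!is.finite(mult)) ||
      any(mult <= 0) || any(mult != floor(mult))) {
    stop_focs("edge multiplicities must be positive integers")
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])

  self <- from == to
  n_self <- sum(self)
  if (n_self > 0L) {
    warning(sprintf("dropped %d self-loop edge line(s)", n_self),
            call. = FALSE)
    from <- from[!self]; to <- to[!self]; mult <- mult[!self]
  }

  ids <- sort(unique(c(from, to, nodes, names(sides))))
  if (length(ids) == 0L) stop_focs("graph has no nodes")

  side <- NULL
  if (bipartite) {
    if (is.null(sides)) {
      side_u <- unique(from); side_v <- unique(to)
      both <- intersect(side_u, side_v)
      if (length(both) > 0L) {
        stop_focs("bipartite edge list places node(s) on both sides: ",
                  paste(utils::head(both, 5L), collapse = ", "),
                  class = "focs_bipartite_error")
      }
      side <- stats::setNames(rep(NA_character_, length(ids)), ids)
      side[side_u] <- "U"; side[side_v] <- "V"
      # isolated nodes declared via `nodes` default to side U
      side[is.na(side)] <- "U"
    } else {
      if (!all(sides %in% c("U", "V"))) {
        stop_focs("side labels must be \"U\" or \"V\"")
      }
      side <- stats::setNames(rep(NA_character_, length(ids)), ids)
      side[names(sides)] <- unname(sides)
      missing <- ids[is.na(side)]
      if (length(missing) > 0L) {
        stop_focs("side manifest missing node(s): ",
                  paste(utils::head(missing, 5L), collapse = ", "))
      }
      same <- side[from] == side[to]
      if (any(same)) {
        stop_focs("bipartite edge(s) connect nodes on the same side: ",
                  paste(utils::head(paste(from[same], to[same]), 5L),
                        collapse = ", "),
                  class = "focs_bipartite_error")
      }
      # normalize orientation: column 1 = U
      flip <- side[from] == "V"
      tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
    }
  }

  n <- length(ids)
  if (length(from) > 0L) {
    i <- match(from, ids); j <- match(to, ids)
    if (!bipartite) { lo <- pmin(i, j); hi <- pmax(i, j); i <- lo; j <- hi }
    key <- paste(i, j)
    agg <- rowsum(mult, key)
    ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
    A <- Matrix::sparseMatrix(i = c(ij[, 1L], ij[, 2L]),
                              j = c(ij[, 2L], ij[, 1L]),
                              x = c(agg[, 1L], agg[, 1L]),
                              dims = c(n, n), dimnames = list(ids, ids))
    edge_tab <- data.frame(from = ids[ij[, 1L]], to = ids[ij[, 2L]],
                           mult = agg[, 1L], stringsAsFactors = FALSE)
    edge_tab <- edge_tab[order(edge_tab$from, edge_tab$to), , drop = FALSE]
    rownames(edge_tab) <- NULL
  } else {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n), dimnames = list(ids, ids))
    edge_tab <- data.frame(from = character(), to = character(),
                           mult = numeric(), stringsAsFactors = FALSE)
  }

  g <- structure(list(nodes = ids, A = A,
                      degree = stats::setNames(Matrix::rowSums(A), ids),
                      bipartite = bipartite, side = side,
                      edges = edge_tab, dropped_self_loops = n_self),
                 class = "focs_graph")
  stopifnot(abs(sum(g$degree) - 2 * sum(edge_tab$mult)) < 0.5)
  g
}

#' @export
print.focs_graph <- function(x, ...) {
  cat(sprintf("focs_graph: %d nodes, %d edges (multiplicity %d)%s\n",
              length(x$nodes), nrow(x$edges), as.integer(sum(x$edges$mult)),
              if (x$bipartite) {
                sprintf(", bipartite (|U|=%d, |V|=%d)",
                        sum(x$side == "U"), sum(x$side == "V"))
              } else ""))
  invisible(x)
}

#' Read an edge list file
#'
#' Plain text, whitespace/tab-delimited, `#`-prefixed comment lines; columns
#' are node-id, node-id and an optional positive integer multiplicity. For
#' bipartite files column 1 is side U and column 2 side V, unless a node-side
#' manifest is supplied via `sides_file` (two columns: node-id, U/V).
#'
#' @param path edge list file.
#' @param bipartite logical.
#' @param sides_file optional node-side manifest path.
#' @return A [focs_graph()].
#' @export
read_edge_list <- function(path, bipartite = FALSE, sides_file = NULL) {
  if (!file.exists(path)) stop_focs("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop_focs(sprintf("malformed edge line %d: %s", idx[bad[1L]],
                      lines[idx[bad[1L]]]), class = "focs_parse_error")
  }
  mult <- vapply(toks, function(tk) {
    if (length(tk) >= 3L) suppressWarnings(as.numeric(tk[3L])) else 1
  }, 1.0)
  bad <- which(!is.finite(mult) | mult <= 0 | mult != floor(mult))
  if (length(bad) > 0L) {
    stop_focs(sprintf("malformed multiplicity on line %d: %s", idx[bad[1L]],
                      lines[idx[bad[1L]]]), class = "focs_parse_error")
  }
  edges <- data.frame(from = vapply(toks, `[`, "", 1L),
                      to = vapply(toks, `[`, "", 2L),
                      mult = mult, stringsAsFactors = FALSE)
  sides <- NULL
  if (!is.null(sides_file)) {
    man <- utils::read.table(sides_file, header = FALSE,
                             col.names = c("node", "side"),
                             colClasses = "character", comment.char = "#")
    sides <- stats::setNames(man$side, man$node)
  }
  focs_graph(edges, bipartite = bipartite, sides = sides)
}

#' Write a graph back to an edge list file
#'
#' Inverse of [read_edge_list()]: multiplicities are preserved so that a
#' load/write/load round trip is exact. Bipartite graphs are written with side
#' U in column 1.
#'
#' @param graph a `focs_graph`.
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "focs_graph"))
  utils::write.table(graph$edges, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Degree of a node
#'
#' Total edge multiplicity incident to `u` (d_u).
#'
#' @param graph a `focs_graph`.
#' @param u node identifier.
#' @return nonnegative integer-valued scalar.
#' @export
node_degree <- function(graph, u) {
  stopifnot(inherits(graph, "focs_graph"))
  if (!u %in% graph$nodes) stop_focs("unknown node: ", u)
  unname(graph$degree[[u]])
}

#' Construct a community
#'
#' A community is a non-empty strict subset of a graph's nodes. For bipartite
#' graphs supply both side subsets (each non-empty); validation against a
#' particular graph happens in [validate_community()].
#'
#' @param members character vector of node ids (unipartite).
#' @param id community label.
#' @return object of class `focs_community`.
#' @export
community <- function(members, id = "C") {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop_focs("community is empty")
  structure(list(id = as.character(id), bipartite = FALSE,
                 members = sort(members)),
            class = "focs_community")
}

#' @rdname community
#' @param members_u,members_v side-U and side-V member ids.
#' @export
bipartite_community <- function(members_u, members_v, id = "C") {
  members_u <- unique(as.character(members_u))
  members_v <- unique(as.character(members_v))
  if (length(members_u) == 0L || length(members_v) == 0L) {
    stop_focs("bipartite community must have members on both sides",
              class = "focs_validation_error")
  }
  structure(list(id = as.character(id), bipartite = TRUE,
                 members = sort(c(members_u, members_v)),
                 members_u = sort(members_u), members_v = sort(members_v)),
            class = "focs_community")
}

#' @export
print.focs_community <- function(x, ...) {
  if (x$bipartite) {
    cat(sprintf("focs_community \"%s\": |C_U|=%d, |C_V|=%d\n", x$id,
                length(x$members_u), length(x$members_v)))
  } else {
    cat(sprintf("focs_community \"%s\": %d members\n", x$id,
                length(x$members)))
  }
  invisible(x)
}

#' Community size
#' @param community a `focs_community`.
#' @return total member count (both sides for bipartite communities).
#' @export
community_size <- function(community) length(community$members)

#' Validate a community against a graph
#'
#' Checks membership in the node universe, strict-subset status (the external
#' set must be non-empty), and side consistency for bipartite graphs.
#'
#' @param graph a `focs_graph`.
#' @param community a `focs_community`.
#' @return the community, invisibly; errors of class
#'   `focs_validation_error` otherwise.
#' @export
validate_community <- function(graph, community) {
  stopifnot(inherits(graph, "focs_graph"), inherits(community, "focs_community"))
  unknown <- setdiff(community$members, graph$nodes)
  if (length(unknown) > 0L) {
    stop_focs("community \"", community$id, "\" has unknown node(s): ",
              paste(utils::head(unknown, 5L), collapse = ", "),
              class = "focs_validation_error")
  }
  if (length(community$members) >= length(graph$nodes)) {
    stop_focs("community \"", community$id,
              "\" covers the whole node universe",
              class = "focs_validation_error")
  }
  if (graph$bipartite != community$bipartite) {
    stop_focs("community \"", community$id, "\" and graph disagree on ",
              "bipartiteness", class = "focs_validation_error")
  }
  if (community$bipartite) {
    if (!all(graph$side[community$members_u] == "U") ||
        !all(graph$side[community$members_v] == "V")) {
      stop_focs("community \"", community$id,
                "\" assigns node(s) to the wrong side",
                class = "focs_validation_error")
    }
  }
  invisible(community)
}

#' Read a community membership file
#'
#' Text file with columns node-id, community-id (whitespace/tab-delimited,
#' `#` comments). A node may belong to several communities. For bipartite
#' graphs the side split is taken from the graph's side labels.
#'
#' @param path membership file.
#' @param graph the graph the communities live in (needed for the bipartite
#'   side split; also used to validate node ids eagerly when `validate`).
#' @param validate logical; check each community with [validate_community()].
#' @return named list of `focs_community` objects, ordered by first appearance.
#' @export
read_communities <- function(path, graph, validate = TRUE) {
  if (!file.exists(path)) stop_focs("community file not found: ", path)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("node", "community"),
                           colClasses = "character", comment.char = "#")
  ids <- unique(tab$community)
  out <- lapply(ids, function(cid) {
    members <- unique(tab$node[tab$community == cid])
    if (graph$bipartite) {
      unknown <- setdiff(members, graph$nodes)
      if (length(unknown) > 0L) {
        stop_focs("community \"", cid, "\" has unknown node(s): ",
                  paste(utils::head(unknown, 5L), collapse = ", "),
                  class = "focs_validation_error")
      }
      bipartite_community(members[graph$side[members] == "U"],
                          members[graph$side[members] == "V"], id = cid)
    } else {
      community(members, id = cid)
    }
  })
  names(out) <- ids
  if (validate) lapply(out, validate_community, graph = graph)
  out
}

#' Degree bookkeeping for a community
#'
#' The four degree sums the null model is built from, for a unipartite
#' community C with complement C': `d_C` (total degree of C), `cross`
#' (d_C(C'), the boundary edge multiplicity), `external_internal`
#' (d_{C'}(C'), twice the multiplicity internal to C'), and `d_Cp`
#' (d_{C'}, total external degree). Always `d_Cp = cross +
#' external_internal`.
#'
#' @param graph a unipartite `focs_graph`.
#' @param community a `focs_community`.
#' @return list with fields `d_C`, `cross`, `external_internal`, `d_Cp`.
#' @export
degree_summary <- function(graph, community) {
  validate_community(graph, community)
  if (graph$bipartite) {
    stop_focs("degree_summary is defined for unipartite graphs; ",
              "bipartite scoring uses external_view directly")
  }
  C <- community$members
  d_C <- sum(graph$degree[C])
  internal2 <- sum(graph$A[C, C, drop = FALSE])
  cross <- d_C - internal2
  d_Cp <- sum(graph$degree) - d_C
  list(d_C = d_C, cross = cross,
       external_internal = d_Cp - cross, d_Cp = d_Cp)
}

#' In-community degree of a node
#'
#' d_u(C) for unipartite communities; for bipartite communities, the degree of
#' `u` into the community part on the opposite side (d_u(C_V) for u on side U,
#' d_v(C_U) for v on side V). Self-membership contributes nothing because the
#' graph has no self-loops.
#'
#' @param graph a `focs_graph`.
#' @param community a `focs_community`.
#' @param u node id.
#' @return nonnegative integer-valued scalar.
#' @export
community_indegree <- function(graph, community, u) {
  if (!u %in% graph$nodes) stop_focs("unknown node: ", u)
  target <- if (community$bipartite) {
    if (graph$side[[u]] == "U") community$members_v else community$members_u
  } else {
    community$members
  }
  sum(graph$A[u, target, drop = FALSE])
}

#' Null-model parameters for one node against one community
#'
#' Computes the hypergeometric parameters of the community-conditional null
#' for node `u` tested against `community`. The null treats the tested node as
#' external: when `u` is a community member, parameters are computed on the
#' partition (C \ u, C' + u), so that u's edge stubs sit in the external pool.
#'
#' Unipartite: `draws = d_u`, `successes = d_{C*}(C'*)` (boundary edges of the
#' u-external partition), `failures = d_{C'*}(C'*)`, `population = d_{C'*} =
#' successes + failures`. Bipartite (u on side U, tested against C_V):
#' `successes = d_{C_V}(C'_U*)`, `failures = d_{C'_V}(C'_U*)`, `population =
#' d_{C'_U*}`, with C'_U* containing u; symmetric for u on side V.
#'
#' @param graph a `focs_graph`.
#' @param community a `focs_community`.
#' @param u node id (member or external).
#' @return object of class `focs_null_params`: list with `draws`, `successes`,
#'   `failures`, `population`.
#' @export
external_view <- function(graph, community, u) {
  validate_community(graph, community)
  if (!u %in% graph$nodes) stop_focs("unknown node: ", u)
  d_u <- graph$degree[[u]]

  if (!community$bipartite) {
    C <- community$members
    if (u %in% C) {
      if (length(C) == 1L) {
        stop_focs("community \"", community$id, "\" too small to test node ",
                  u, " (C \\ {u} is empty)", class = "focs_validation_error")
      }
      d_Cs <- sum(graph$degree[C]) - d_u
      internal2 <- sum(graph$A[C, C, drop = FALSE]) -
        2 * sum(graph$A[u, C, drop = FALSE])
    } else {
      d_Cs <- sum(graph$degree[C])
      internal2 <- sum(graph$A[C, C, drop = FALSE])
    }
    successes <- d_Cs - internal2            # d_{C*}(C'*)
    population <- sum(graph$degree) - d_Cs   # d_{C'*}
  } else {
    su <- graph$side[[u]]
    own <- if (su == "U") community$members_u else community$members_v
    opp <- if (su == "U") community$members_v else community$members_u
    u_in <- u %in% own
    own_star <- if (u_in) setdiff(own, u) else own
    a_u <- sum(graph$A[u, opp, drop = FALSE])        # d_u(C_opp)
    cross_in <- sum(graph$A[own_star, opp, drop = FALSE])
    d_opp <- sum(graph$degree[opp])
    successes <- d_opp - cross_in            # d_{C_opp}(own-side externals)
    d_own_side <- sum(graph$degree[graph$nodes[graph$side == su]])
    population <- d_own_side - sum(graph$degree[own_star])
  }

  structure(list(draws = as.numeric(d_u),
                 successes = as.numeric(successes),
                 failures = as.numeric(population - successes),
                 population = as.numeric(population)),
            class = "focs_null_params")
}

# Vectorized external-view parameters for every community member at once.
# Same quantities as external_view(graph, community, u) for u in C, computed
# from one submatrix pass; the scorer's hot path. external_view stays as the
# per-node reference implementation and the two are cross-checked in tests.
member_null_params <- function(graph, community) {
  deg <- graph$degree
  if (!community$bipartite) {
    C <- community$members
    if (length(C) < 2L) {
      stop_focs("community \"", community$id,
                "\" has fewer than two members",
                class = "focs_validation_error")
    }
    subA <- graph$A[C, C, drop = FALSE]
    a <- Matrix::rowSums(subA)
    d_C <- sum(deg[C]); internal2 <- sum(subA); total <- sum(deg)
    d_Cs <- d_C - deg[C]
    successes <- d_Cs - (internal2 - 2 * a)
    population <- total - d_Cs
    data.frame(node = C, in_degree = as.numeric(a),
               draws = as.numeric(deg[C]), successes = as.numeric(successes),
               failures = as.numeric(population - successes),
               population = as.numeric(population),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    one_side <- function(own, opp, side_label) {
      if (length(own) == 0L) return(NULL)
      a <- Matrix::rowSums(graph$A[own, opp, drop = FALSE])
      d_opp <- sum(deg[opp])
      cross <- sum(a)                         # d_{C_own}(C_opp)
      successes <- d_opp - (cross - a)
      d_side <- sum(deg[graph$nodes[graph$side == side_label]])
      population <- d_side - (sum(deg[own]) - deg[own])
      data.frame(node = own, in_degree = as.numeric(a),
                 draws = as.numeric(deg[own]),
                 successes = as.numeric(successes),
                 failures = as.numeric(population - successes),
                 population = as.numeric(population),
                 stringsAsFactors = FALSE, row.names = NULL)
    }
    rbind(one_side(community$members_u, community$members_v, "U"),
          one_side(community$members_v, community$members_u, "V"))
  }
}

#' @export
print.focs_null_params <- function(x, ...) {
  cat(sprintf(
    "focs_null_params: draws=%g successes=%g failures=%g population=%g\n",
    x$draws, x$successes, x$failures, x$population))
  invisible(x)
}
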