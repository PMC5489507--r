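#' Scale-free network generators and degree-preserving rewiring
#'
#' Graphs throughout the package are plain undirected [igraph::igraph]
#' objects: simple (no self-loops, no multi-edges), with vertices numbered
#' `1..N`.  Edge-list files on disk use 0-based node identifiers (see
#' [read_edgelist()]).
#'
#' @name netstruct
#' @keywords internal
NULL

#' Validate a graph used as a population structure
#'
#' Checks that `g` is an undirected simple igraph object, optionally that it
#' is connected, and errors otherwise.
#'
#' @param g An igraph object.
#' @param connected If `TRUE`, additionally require connectivity.
#' @return `g`, invisibly.
#' @export
validate_graph <- function(g, connected = FALSE) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("`g` must be undirected", call. = FALSE)
  if (igraph::vcount(g) < 2L) stop("`g` must have at least 2 nodes", call. = FALSE)
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
    stop("`g` must be a simple graph (no self-loops or multi-edges)", call. = FALSE)
  if (connected && !igraph::is_connected(g))
    stop("`g` must be connected", call. = FALSE)
  invisible(g)
}

#' Degree sequence of a graph
#'
#' @param g An igraph object.
#' @return Integer vector of vertex degrees (in vertex order).
#' @export
degree_sequence <- function(g) {
  as.integer(igraph::degree(g))
}

# Shared growth routine for BA / Holme-Kim networks.  Starts from a clique on
# m_attach + 1 nodes; every later node attaches m_attach edges, each either by
# preferential attachment (sampling a repeated-node urn) or, with probability
# p_triad after a PA step, by closing a triangle through a neighbor of the
# last PA target.
grow_scale_free <- function(n, m_attach, p_triad) {
  if (!is.numeric(n) || n < 2) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(m_attach) || m_attach < 1)
    stop("`m_attach` must be an integer >= 1", call. = FALSE)
  if (n <= m_attach)
    stop("`n` must exceed `m_attach`", call. = FALSE)
  if (p_triad < 0 || p_triad > 1)
    stop("`p_triad` must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  m <- as.integer(m_attach)

  seed_n <- m + 1L
  adj <- vector("list", n)
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (a in seq_len(seed_n - 1L)) {
    for (b in seq.int(a + 1L, seed_n)) {
      edges_from <- c(edges_from, a)
      edges_to <- c(edges_to, b)
    }
  }
  for (v in seq_len(seed_n)) adj[[v]] <- setdiff(seq_len(seed_n), v)
  # urn of node ids repeated by degree, drives preferential attachment
  urn <- rep(seq_len(seed_n), each = seed_n - 1L)

  if (n > seed_n) {
    for (v in seq.int(seed_n + 1L, n)) {
      targets <- integer(0)
      last_pa <- NA_integer_
      for (slot in seq_len(m)) {
        picked <- NA_integer_
        if (slot > 1L && !is.na(last_pa) && p_triad > 0 &&
            stats::runif(1) < p_triad) {
          cand <- setdiff(adj[[last_pa]], c(targets, v))
          if (length(cand) > 0L) {
            picked <- cand[[sample.int(length(cand), 1L)]]
          }
        }
        if (is.na(picked)) { # preferential-attachment draw
          repeat {
            t <- urn[[sample.int(length(urn), 1L)]]
            if (!(t %in% targets)) break
          }
          picked <- t
          last_pa <- t
        }
        targets <- c(targets, picked)
      }
      edges_from <- c(edges_from, rep.int(v, m))
      edges_to <- c(edges_to, targets)
      for (t in targets) {
        adj[[t]] <- c(adj[[t]], v)
        adj[[v]] <- c(adj[[v]], t)
      }
      urn <- c(urn, targets, rep.int(v, m))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(edges_from, edges_to))
}

#' Generate a Barabasi-Albert scale-free network
#'
#' Grows a connected simple graph by preferential attachment from a clique
#' seed on `m_attach + 1` nodes; every subsequent node attaches `m_attach`
#' edges to existing nodes with probability proportional to their degree.
#'
#' @param n Number of nodes (`n > m_attach`).
#' @param m_attach Edges added per new node.
#' @return A connected simple igraph object with `n` vertices.
#' @seealso [generate_hk()] for the triad-closing variant.
#' @examples
#' set.seed(1)
#' g <- generate_ba(100, 2)
#' igraph::vcount(g)
#' @export
generate_ba <- function(n, m_attach) {
  grow_scale_free(n, m_attach, p_triad = 0)
}

#' Generate a Holme-Kim scale-free network with tunable clustering
#'
#' As [generate_ba()], but after each preferential-attachment edge the next
#' edge of the same newcomer closes a triangle through a neighbor of the last
#' attachment target with probability `p_triad`.  Larger `p_triad` yields
#' higher clustering at the same degree distribution family; `p_triad = 0`
#' reduces exactly to the BA growth process.
#'
#' @inheritParams generate_ba
#' @param p_triad Triad-formation probability in `[0, 1]`.
#' @return A connected simple igraph object with `n` vertices.
#' @export
generate_hk <- function(n, m_attach, p_triad) {
  grow_scale_free(n, m_attach, p_triad)
}

#' Mean local clustering coefficient
#'
#' Per-node clustering is the number of edges among a node's neighbors
#' divided by `d_i (d_i - 1) / 2`; nodes with degree below 2 contribute 0.
#' The graph-level value is the mean over all nodes.
#'
#' @param g An igraph object.
#' @return A number in `[0, 1]`.
#' @examples
#' clustering_coefficient(igraph::make_full_graph(3)) # 1
#' @export
clustering_coefficient <- function(g) {
  val <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (is.nan(val)) 0 else val
}

#' Degree-preserving double edge swap
#'
#' Picks two edges `(a,b)`, `(c,d)` with four distinct endpoints and replaces
#' them by `(a,c)`, `(b,d)` provided neither replacement already exists.  The
#' degree sequence is unchanged.  Used to seed and mutate the optimizer's
#' population.
#'
#' @param g An igraph object with at least 2 edges.
#' @param max_tries Attempts before giving up (the graph may admit no swap,
#'   e.g. a complete graph).
#' @param edges Optional 2x2 integer matrix of endpoints (rows `(a,b)` and
#'   `(c,d)`) forcing the pair of edges to swap; used for deterministic
#'   checks.
#' @return A new igraph object; attribute `graph_attr(g, "swapped")` is
#'   `TRUE` when a swap was applied and `FALSE` for a no-op.
#' @export
simple_edge_swap <- function(g, max_tries = 100L, edges = NULL) {
  ec <- igraph::ecount(g)
  if (ec < 2L) stop("`g` needs at least 2 edges", call. = FALSE)
  do_swap <- function(a, b, c, d) {
    if (length(unique(c(a, b, c, d))) < 4L) return(NULL)
    if (igraph::are_adjacent(g, a, c) || igraph::are_adjacent(g, b, d)) return(NULL)
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b, c, d)))
    igraph::add_edges(g2, c(a, c, b, d))
  }
  if (!is.null(edges)) {
    out <- do_swap(edges[1, 1], edges[1, 2], edges[2, 1], edges[2, 2])
    if (is.null(out)) {
      return(igraph::set_graph_attr(g, "swapped", FALSE))
    }
    return(igraph::set_graph_attr(out, "swapped", TRUE))
  }
  ends_all <- igraph::as_edgelist(g, names = FALSE)
  for (i in seq_len(max_tries)) {
    eid <- sample.int(ec, 2L)
    a <- ends_all[eid[1L], 1L]; b <- ends_all[eid[1L], 2L]
    c <- ends_all[eid[2L], 1L]; d <- ends_all[eid[2L], 2L]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp } # orientation
    out <- do_swap(a, b, c, d)
    if (!is.null(out)) return(igraph::set_graph_attr(out, "swapped", TRUE))
  }
  igraph::set_graph_attr(g, "swapped", FALSE)
}

#' Select nodes and edges for an edge-switching move
#'
#' Samples a node `u` with degree at least 2, two of its neighbors `i`, `j`
#' (both with degree at least 2), an edge `e_jk` incident to `j` and an edge
#' `e_im` incident to `i`, such that the five nodes `u, i, j, k, m` are
#' pairwise distinct, edge `j-i` is absent and edge `k-m` is absent.  Removing
#' `e_jk`, `e_im` and adding `e_ji`, `e_km` then preserves every node degree
#' (see [edge_switch()]).
#'
#' Failure to find a valid tuple within `max_attempts` is a normal outcome
#' (e.g. on a star graph no neighbor pair qualifies) and is reported through
#' the `found` flag rather than an error.
#'
#' @param g An igraph object.
#' @param max_attempts Sampling attempts before reporting failure.
#' @return An object of class `rewire_proposal`: a list with `found` (flag)
#'   and, when found, node ids `u`, `i`, `j`, `k`, `m`.
#' @export
node_select <- function(g, max_attempts = 1000L) {
  e <- graph_edges0(g)
  res <- cpp_node_select(e$n, e$ei, e$ej, as.integer(max_attempts))
  if (res[[1L]] == 0L) {
    return(structure(list(found = FALSE), class = "rewire_proposal"))
  }
  structure(
    list(found = TRUE, u = res[[2L]], i = res[[3L]], j = res[[4L]],
         k = res[[5L]], m = res[[6L]]),
    class = "rewire_proposal"
  )
}

#' @export
print.rewire_proposal <- function(x, ...) {
  if (!x$found) {
    cat("<rewire_proposal> no valid tuple found\n")
  } else {
    cat(sprintf(
      "<rewire_proposal> u=%d i=%d j=%d k=%d m=%d  (drop j-k, i-m; add j-i, k-m)\n",
      x$u, x$i, x$j, x$k, x$m
    ))
  }
  invisible(x)
}

#' Apply an edge-switching move
#'
#' Removes edges `j-k` and `i-m` and adds `j-i` and `k-m` as specified by a
#' [node_select()] proposal.  Node degrees are preserved: `i` loses `m` and
#' gains `j`, `j` loses `k` and gains `i`, `k` loses `j` and gains `m`, `m`
#' loses `i` and gains `k`.
#'
#' @param g The igraph object the proposal was drawn from.
#' @param proposal A found `rewire_proposal`.
#' @return A new igraph object with the move applied.
#' @export
edge_switch <- function(g, proposal) {
  if (!inherits(proposal, "rewire_proposal") || !isTRUE(proposal$found))
    stop("`proposal` must be a found rewire_proposal", call. = FALSE)
  with(proposal, {
    ids <- c(u, i, j, k, m)
    if (length(unique(ids)) != 5L)
      stop("proposal nodes must be pairwise distinct", call. = FALSE)
    if (!igraph::are_adjacent(g, j, k) || !igraph::are_adjacent(g, i, m))
      stop("proposal removes edges absent from `g`", call. = FALSE)
    if (igraph::are_adjacent(g, j, i) || igraph::are_adjacent(g, k, m))
      stop("proposal adds edges already present in `g`", call. = FALSE)
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(j, k, i, m)))
    igraph::add_edges(g2, c(j, i, k, m))
  })
}

#' Is the graph connected?
#'
#' @param g An igraph object.
#' @return `TRUE` iff one component spans all nodes.
#' @export
graph_is_connected <- function(g) {
  igraph::is_connected(g)
}

#' Read a graph from an edge-list file
#'
#' One whitespace-separated pair of 0-based integer node ids per line;
#' `#` starts a comment.
#'
#' @param path File path.
#' @param n Optional node count (defaults to `max(id) + 1`; supply when
#'   trailing nodes are isolated).
#' @param validate If `TRUE`, require a simple connected graph.
#' @return An igraph object (vertices `1..N` map to file ids `0..N-1`).
#' @export
read_edgelist <- function(path, n = NULL, validate = TRUE) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("from", "to"),
                           colClasses = "integer")
  if (nrow(raw) == 0L) stop("empty edge list: ", path, call. = FALSE)
  if (any(raw < 0L)) stop("node ids must be >= 0", call. = FALSE)
  nn <- if (is.null(n)) max(raw) + 1L else as.integer(n)
  g <- igraph::make_empty_graph(nn, directed = FALSE)
  g <- igraph::add_edges(g, rbind(raw$from + 1L, raw$to + 1L))
  if (validate) validate_graph(g, connected = TRUE)
  g
}

#' Write a graph to an edge-list file
#'
#' Emits 0-based, `min max`-ordered, lexicographically sorted pairs so the
#' output is byte-stable for a given graph.
#'
#' @param g An igraph object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}
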