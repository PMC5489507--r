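# Independent oracles and small fixture builders used across the suite.

# Brute-force mean local clustering: per node, enumerate neighbor pairs and
# count realized edges.  Deliberately independent of the package's
# implementation.
oracle_clustering <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  has_edge <- function(a, b) b %in% adj[[a]]
  vals <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    d <- length(nb)
    if (d < 2) return(0)
    cnt <- 0L
    for (p in seq_len(d - 1)) {
      for (q in seq.int(p + 1, d)) {
        if (has_edge(nb[p], nb[q])) cnt <- cnt + 1L
      }
    }
    cnt / (d * (d - 1) / 2)
  }, numeric(1))
  mean(vals)
}

# Breadth-first-search connectivity oracle.
oracle_connected <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

# Random connected-ish simple graph for oracle comparisons.
random_small_graph <- function(n_max = 30L, p = 0.2) {
  n <- sample(4:n_max, 1)
  igraph::sample_gnp(n, p)
}

sorted_edge_keys <- function(g) sort(netcoop:::edge_keys(g))

graph_identical <- function(g1, g2) {
  igraph::vcount(g1) == igraph::vcount(g2) &&
    identical(sorted_edge_keys(g1), sorted_edge_keys(g2))
}

# stable logistic used as the Fermi-rule reference
fermi_ref <- function(delta, k) 1 / (1 + exp(delta / k))
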