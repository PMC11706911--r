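# Toy graphs and independent brute-force oracles used across the suite.

graph_from_edges <- function(edges, n = NULL, weights = NULL) {
  g <- igraph::graph_from_edgelist(cbind(as.character(edges[, 1]),
                                         as.character(edges[, 2])),
                                   directed = FALSE)
  if (!is.null(n)) {
    extra <- setdiff(as.character(seq_len(n)), igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  as_gene_network(g)
}

make_star <- function(n) {
  graph_from_edges(cbind(rep(1, n - 1), 2:n))
}

make_path <- function(n) {
  graph_from_edges(cbind(seq_len(n - 1), 2:n))
}

make_complete <- function(n) {
  graph_from_edges(t(combn(n, 2)))
}

two_triangles <- function(joined = FALSE) {
  e <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  if (joined) e <- rbind(e, c(3, 4))
  graph_from_edges(e)
}

random_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  graph_from_edges(pairs[keep, , drop = FALSE], n = n)
}

# Floyd-Warshall all-pairs shortest hop counts, independent of igraph
floyd_warshall <- function(network) {
  g <- network$graph
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  diag(d) <- 0
  if (igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g)
    for (r in seq_len(nrow(ends))) {
      d[ends[r, 1], ends[r, 2]] <- 1
      d[ends[r, 2], ends[r, 1]] <- 1
    }
  }
  for (k in seq_len(n))
    for (i in seq_len(n)) {
      thr <- d[i, k] + d[k, ]
      upd <- thr < d[i, ]
      d[i, upd] <- thr[upd]
    }
  d
}

efficiency_brute <- function(network) {
  d <- floyd_warshall(network)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# hand evaluation of Q = sum_s (e_s/L - (d_s/2L)^2), independent of igraph
modularity_of_partition <- function(network, membership) {
  g <- network$graph
  L <- igraph::ecount(g)
  if (L == 0) return(0)
  nodes <- igraph::V(g)$name
  if (is.null(names(membership))) names(membership) <- nodes
  ends <- igraph::as_edgelist(g)
  within <- membership[ends[, 1]] == membership[ends[, 2]]
  deg <- igraph::degree(g)
  q <- 0
  for (s in unique(membership)) {
    e_s <- sum(within & membership[ends[, 1]] == s)
    d_s <- sum(deg[nodes[membership[nodes] == s]])
    q <- q + e_s / L - (d_s / (2 * L))^2
  }
  q
}

# enumerate all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxb) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (b in seq_len(maxb + 1L))
      recurse(c(prefix, b), max(maxb, b))
  }
  recurse(integer(0), 0L)
  out
}

max_modularity_brute <- function(network) {
  n <- igraph::vcount(network$graph)
  parts <- all_partitions(n)
  max(vapply(parts, function(p) modularity_of_partition(network, p),
             numeric(1)))
}

adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# minimal hand-built correlation_estimate for threshold tests
fake_corr_estimate <- function(rho, q) {
  p <- q
  structure(list(gene_ids = rownames(rho), rho = rho, t_matrix = NULL,
                 omega = NULL, p_values = p, q_values = q,
                 n_permutations = 0L, seed = NA_integer_),
            class = "correlation_estimate")
}

sym_mat <- function(genes, fill = 0) {
  m <- matrix(fill, length(genes), length(genes),
              dimnames = list(genes, genes))
  diag(m) <- 1
  m
}
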