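# Thresholded signed co-occurrence networks and their structural metrics.
# Edge weights keep the signed SparCC correlation; paths, modularity and
# node roles operate on the unweighted, sign-stripped graph, as is standard
# for co-occurrence topology.

#' Build a signed gene co-occurrence network
#'
#' Keeps the gene pairs with \eqn{|\rho| >} \code{threshold} (strict) and
#' BH q-value \eqn{<} \code{alpha} (strict); genes with no surviving edge
#' are dropped, so network size counts connected genes only.
#'
#' @param corr a \code{\link{sparcc_correlation}} result.
#' @param annotation optional data.frame (\code{gene_id}, \code{family},
#'   \code{enzyme_class}) used to tag nodes.
#' @param threshold correlation-magnitude cutoff.
#' @param alpha FDR cutoff on q-values.
#' @param group optional group label carried on the network.
#' @return An object of class \code{gene_network}: list with \code{graph}
#'   (an \pkg{igraph} undirected graph whose edges carry \code{weight} =
#'   signed \eqn{\rho} and \code{q_value}), \code{group}, \code{threshold},
#'   \code{alpha}.
#' @export
build_network <- function(corr, annotation = NULL, threshold = 0.6,
                          alpha = 0.05, group = NA_character_) {
  stopifnot(inherits(corr, "correlation_estimate"))
  rho <- corr$rho
  q <- corr$q_values
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  keep <- abs(rho[ut]) > threshold & q[ut] < alpha
  ut <- ut[keep, , drop = FALSE]
  genes <- corr$gene_ids
  if (nrow(ut) == 0) {
    warning("no gene pair passed |rho| > ", threshold, " and q < ", alpha,
            "; returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    el <- data.frame(gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
                     weight = rho[ut], q_value = q[ut],
                     stringsAsFactors = FALSE)
    swap <- el$gene_a > el$gene_b
    tmp <- el$gene_a[swap]; el$gene_a[swap] <- el$gene_b[swap]
    el$gene_b[swap] <- tmp
    el <- el[order(el$gene_a, el$gene_b), , drop = FALSE]
    nodes <- sort(unique(c(el$gene_a, el$gene_b)))
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = data.frame(name = nodes))
  }
  if (!is.null(annotation) && igraph::vcount(g) > 0) {
    cls <- setNames(annotation$enzyme_class, annotation$gene_id)
    igraph::V(g)$enzyme_class <- unname(cls[igraph::V(g)$name])
  }
  structure(list(graph = g, group = group, threshold = threshold,
                 alpha = alpha),
            class = "gene_network")
}

#' Wrap a plain igraph graph as a gene network
#'
#' Utility for tests and for graphs not built from a correlation estimate;
#' missing edge weights default to +1 and q-values to 0.
#'
#' @param graph an undirected \pkg{igraph} graph with named vertices.
#' @param group optional group label.
#' @return A \code{gene_network}.
#' @export
as_gene_network <- function(graph, group = NA_character_) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  if (is.null(igraph::E(graph)$weight) && igraph::ecount(graph) > 0)
    igraph::E(graph)$weight <- 1
  if (is.null(igraph::E(graph)$q_value) && igraph::ecount(graph) > 0)
    igraph::E(graph)$q_value <- 0
  structure(list(graph = graph, group = group, threshold = NA_real_,
                 alpha = NA_real_),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  L <- igraph::ecount(x$graph)
  neg <- if (L > 0) sum(igraph::E(x$graph)$weight < 0) else 0
  cat("<gene_network", if (!is.na(x$group)) paste0(" '", x$group, "'"), "> ",
      igraph::vcount(x$graph), " nodes, ", L, " links (",
      neg, " negative)\n", sep = "")
  invisible(x)
}

#' Fast-greedy module detection
#'
#' Clauset-Newman-Moore greedy modularity agglomeration on the unweighted,
#' sign-stripped graph. An edgeless graph yields one module per node with
#' \eqn{Q = 0}. Module labels are renumbered \code{"M1"}, \code{"M2"}, ...
#' by each module's smallest gene ID so labels are deterministic.
#'
#' @param network a \code{gene_network}.
#' @return List with \code{membership} (named character, gene -> module
#'   label) and \code{modularity} (the partition's \eqn{Q}).
#' @export
detect_modules_fast_greedy <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0)
    return(list(membership = setNames(character(0), character(0)),
                modularity = 0))
  if (igraph::ecount(g) == 0) {
    mem <- setNames(paste0("M", seq_len(igraph::vcount(g))),
                    igraph::V(g)$name)
    return(list(membership = mem, modularity = 0))
  }
  fg <- igraph::cluster_fast_greedy(g, weights = NA)
  # pick the best cut of the agglomeration dendrogram ourselves: the
  # membership igraph reports can sit one merge short of its own
  # maximum-modularity state on small graphs
  ones <- rep(1, igraph::ecount(g))
  n_comp <- igraph::count_components(g)
  cuts <- seq(igraph::vcount(g), n_comp)
  qs <- vapply(cuts, function(k)
    igraph::modularity(g, igraph::cut_at(fg, no = k), weights = ones),
    numeric(1))
  best <- cuts[which.max(qs)]  # ties resolve to the least-merged state
  mem_int <- igraph::cut_at(fg, no = best)
  names(mem_int) <- igraph::V(g)$name
  q <- max(qs)
  # deterministic relabeling by smallest member gene ID
  first_gene <- vapply(split(names(mem_int), as.integer(mem_int)),
                       function(v) sort(v)[1], character(1))
  new_order <- names(sort(first_gene))
  relabel <- setNames(paste0("M", seq_along(new_order)), new_order)
  mem <- setNames(unname(relabel[as.character(as.integer(mem_int))]),
                  names(mem_int))
  list(membership = mem, modularity = q)
}

#' Zi-Pi node-role classification
#'
#' Computes, on the unweighted graph, each node's within-module degree
#' z-score \eqn{z_i} (relative to the mean and SD of within-module degree in
#' its own module; SD 0 gives \eqn{z_i = 0}) and participation coefficient
#' \eqn{P_i = 1 - \sum_s (k_{is}/k_i)^2}, then assigns the standard four
#' roles: peripheral (\eqn{z < z_t, P < P_t}), connector
#' (\eqn{z < z_t, P \ge P_t}), module hub (\eqn{z \ge z_t, P < P_t}),
#' network hub (\eqn{z \ge z_t, P \ge P_t}).
#'
#' @param network a \code{gene_network}.
#' @param modules result of \code{\link{detect_modules_fast_greedy}} (or a
#'   named membership vector).
#' @param z_threshold,p_threshold role boundaries (2.5 and 0.62 by
#'   convention).
#' @return data.frame with \code{gene}, \code{module}, \code{degree},
#'   \code{within_module_degree}, \code{z}, \code{p}, \code{role}.
#' @export
classify_node_roles <- function(network, modules, z_threshold = 2.5,
                                p_threshold = 0.62) {
  stopifnot(inherits(network, "gene_network"))
  mem <- if (is.list(modules)) modules$membership else modules
  g <- network$graph
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(mem)))
    stop("modules missing for node(s): ",
         paste(setdiff(nodes, names(mem)), collapse = ", "))
  mem <- mem[nodes]
  k <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  within <- vapply(seq_along(nodes), function(i) {
    nb <- names(adj[[i]])
    sum(mem[nb] == mem[nodes[i]])
  }, numeric(1))
  names(within) <- nodes
  z <- numeric(length(nodes))
  for (m in unique(mem)) {
    idx <- which(mem == m)
    s <- sd(within[idx])
    z[idx] <- if (length(idx) < 2 || is.na(s) || s == 0) 0 else
      (within[idx] - mean(within[idx])) / s
  }
  p_i <- vapply(seq_along(nodes), function(i) {
    if (k[i] == 0) return(0)
    nb <- names(adj[[i]])
    kis <- table(mem[nb])
    1 - sum((as.numeric(kis) / k[i])^2)
  }, numeric(1))
  role <- ifelse(z >= z_threshold,
                 ifelse(p_i >= p_threshold, "network_hub", "module_hub"),
                 ifelse(p_i >= p_threshold, "connector", "peripheral"))
  data.frame(gene = nodes, module = unname(mem), degree = unname(k),
             within_module_degree = unname(within), z = z, p = p_i,
             role = role, stringsAsFactors = FALSE, row.names = NULL)
}

#' Power-law fit to the degree distribution
#'
#' Ordinary least squares of \eqn{\log_{10}} degree frequency on
#' \eqn{\log_{10}} degree over the observed (nonzero) degrees. Needs at
#' least 3 distinct degrees; otherwise the fit is flagged unsupported.
#'
#' @param network a \code{gene_network}.
#' @return List with \code{exponent} (so \eqn{P(k) \propto k^{-exponent}}),
#'   \code{r2}, \code{p} (slope p-value) and \code{supported}.
#' @export
fit_power_law <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  k <- igraph::degree(network$graph)
  k <- k[k > 0]
  tab <- table(k)
  if (length(tab) < 3)
    return(list(exponent = NA_real_, r2 = NA_real_, p = NA_real_,
                supported = FALSE))
  df <- data.frame(logk = log10(as.numeric(names(tab))),
                   logf = log10(as.numeric(tab)))
  fit <- lm(logf ~ logk, data = df)
  sm <- summary(fit)
  list(exponent = -unname(coef(fit)[2]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       supported = TRUE)
}

#' Topology summary (Table-style metric set)
#'
#' Computes the full structural metric panel of a co-occurrence network:
#' size, connectivity (link count), average connectivity \eqn{2L/N}, the
#' percentage of negative links, average shortest path length and diameter
#' (unweighted hops, connected pairs only), mean local clustering
#' coefficient (degree-<2 nodes contribute 0), density
#' \eqn{2L/(N(N-1))}, degree centralisation
#' \eqn{\sum_i (k_{max} - k_i) / ((N-1)(N-2))}, fast-greedy modularity
#' \eqn{Q}, the power-law fit, and the Zi-Pi role percentages.
#'
#' @param network a \code{gene_network}.
#' @param modules optional precomputed \code{\link{detect_modules_fast_greedy}}
#'   result (computed if missing).
#' @return List of class \code{topology_summary}.
#' @export
topology_summary <- function(network, modules = NULL) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  N <- igraph::vcount(g)
  L <- igraph::ecount(g)
  if (N == 0) stop("network is empty")
  if (is.null(modules)) modules <- detect_modules_fast_greedy(network)
  w <- igraph::E(g)$weight
  pct_neg <- if (L > 0) 100 * sum(w < 0) / L else NA_real_
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE,
                               weights = NA)
  diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE,
                           weights = NA)
  clust <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  dens <- if (N > 1) 2 * L / (N * (N - 1)) else NA_real_
  k <- igraph::degree(g)
  centralisation <- if (N >= 3)
    sum(max(k) - k) / ((N - 1) * (N - 2)) else NA_real_
  pl <- fit_power_law(network)
  roles <- classify_node_roles(network, modules)
  role_pct <- vapply(c("peripheral", "connector", "module_hub", "network_hub"),
                     function(r) 100 * sum(roles$role == r) / N, numeric(1))
  structure(
    list(network_size = N,
         connectivity = L,
         average_connectivity = if (N > 0) 2 * L / N else NA_real_,
         pct_negative_links = pct_neg,
         average_path_length = apl,
         diameter = diam,
         clustering_coefficient = clust,
         density = dens,
         centralisation = centralisation,
         modularity = modules$modularity,
         powerlaw_r2 = pl$r2,
         powerlaw_p = pl$p,
         pct_peripherals = role_pct[["peripheral"]],
         pct_connectors = role_pct[["connector"]],
         pct_module_hubs = role_pct[["module_hub"]],
         pct_network_hubs = role_pct[["network_hub"]]),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  v <- unlist(x)
  cat("<topology_summary>\n")
  for (n in names(v)) cat(sprintf("  %-24s %s\n", n, format(signif(v[[n]], 4))))
  invisible(x)
}

#' Shared-node partition across networks
#'
#' For every nonempty subset of the supplied networks, counts the node IDs
#' present in exactly that subset (Venn-diagram cells) and reports each
#' cell's percentage of the union of all nodes.
#'
#' @param networks named list of >= 2 \code{gene_network} objects.
#' @return data.frame with \code{groups} (ampersand-joined subset),
#'   \code{n_groups}, \code{count}, \code{pct}.
#' @export
shared_node_partition <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 2,
            !is.null(names(networks)))
  node_sets <- lapply(networks, function(nw) igraph::V(nw$graph)$name)
  all_nodes <- sort(unique(unlist(node_sets)))
  grp <- names(networks)
  membership <- vapply(node_sets, function(s) all_nodes %in% s,
                       logical(length(all_nodes)))
  if (length(all_nodes) == 1) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(r) paste(grp[r], collapse = " & "))
  cells <- unlist(lapply(seq_along(grp), function(sz)
    combn(grp, sz, paste, collapse = " & ")))
  counts <- table(factor(key, levels = cells))
  data.frame(groups = names(counts),
             n_groups = lengths(strsplit(names(counts), " & ", fixed = TRUE)),
             count = as.integer(counts),
             pct = 100 * as.integer(counts) / length(all_nodes),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enzyme-class node and link proportions
#'
#' Per CAZy enzyme class: the percentage of nodes in that class and the
#' percentage of links incident to at least one node of that class (a GH-GT
#' link counts for both classes, so link percentages can exceed 100 summed).
#'
#' @param network a \code{gene_network}.
#' @param annotation data.frame (\code{gene_id}, \code{enzyme_class});
#'   may be omitted if nodes already carry \code{enzyme_class}.
#' @return data.frame with \code{enzyme_class}, \code{node_count},
#'   \code{node_pct}, \code{link_count}, \code{link_pct}.
#' @export
class_link_proportions <- function(network, annotation = NULL) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  nodes <- igraph::V(g)$name
  if (!is.null(annotation)) {
    cls <- setNames(annotation$enzyme_class, annotation$gene_id)[nodes]
  } else {
    cls <- igraph::V(g)$enzyme_class
  }
  if (is.null(cls) || anyNA(cls))
    stop("unannotated node(s): ",
         paste(nodes[if (is.null(cls)) TRUE else is.na(cls)], collapse = ", "))
  names(cls) <- nodes
  N <- length(nodes)
  L <- igraph::ecount(g)
  ends <- if (L > 0) igraph::as_edgelist(g) else
    matrix(character(0), ncol = 2)
  classes <- sort(unique(cls))
  out <- lapply(classes, function(cc) {
    nc <- sum(cls == cc)
    lc <- if (L > 0) sum(cls[ends[, 1]] == cc | cls[ends[, 2]] == cc) else 0
    data.frame(enzyme_class = cc, node_count = nc, node_pct = 100 * nc / N,
               link_count = lc,
               link_pct = if (L > 0) 100 * lc / L else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
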