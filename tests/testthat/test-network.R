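test_that("edges need |rho| strictly above the threshold and q strictly below alpha", {
  genes <- paste0("G", 1:4)
  rho <- sym_mat(genes)
  q <- sym_mat(genes, fill = 0.001)
  diag(q) <- NA
  rho[1, 2] <- rho[2, 1] <- 0.60        # boundary: excluded
  rho[1, 3] <- rho[3, 1] <- 0.61        # in
  rho[2, 4] <- rho[4, 2] <- 0.90        # strong but not significant
  q[2, 4] <- q[4, 2] <- 0.2
  nw <- build_network(fake_corr_estimate(rho, q))
  el <- igraph::as_edgelist(nw$graph)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("G1", "G3"))
  # G2 and G4 have no surviving edge and are dropped from the node list
  expect_setequal(igraph::V(nw$graph)$name, c("G1", "G3"))
})

test_that("no surviving edges warns and returns an empty network", {
  genes <- paste0("G", 1:4)
  rho <- sym_mat(genes, fill = 0.1)
  q <- sym_mat(genes, fill = 0.9)
  expect_warning(nw <- build_network(fake_corr_estimate(rho, q)), "empty")
  expect_equal(igraph::vcount(nw$graph), 0)
})

test_that("closed-form topology: complete graph and path graph", {
  k5 <- topology_summary(make_complete(5))
  expect_equal(k5$density, 1)
  expect_equal(k5$clustering_coefficient, 1)
  expect_equal(k5$diameter, 1)
  expect_equal(k5$average_path_length, 1)
  expect_equal(k5$centralisation, 0)
  expect_equal(k5$average_connectivity, 2 * 10 / 5)

  p4 <- topology_summary(make_path(4))
  expect_equal(p4$diameter, 3)
  expect_equal(p4$average_path_length, 10 / 6)
})

test_that("average connectivity and density identities hold on generated networks", {
  for (seed in 1:5) {
    nw <- random_network(n = 12, p = 0.25, seed = seed)
    s <- topology_summary(nw)
    N <- s$network_size; L <- s$connectivity
    expect_equal(s$average_connectivity, 2 * L / N)
    expect_equal(s$density, 2 * L / (N * (N - 1)))
    expect_gte(s$diameter, s$average_path_length)
  }
})

test_that("unweighted shortest paths agree with Floyd-Warshall on random graphs", {
  for (seed in 1:6) {
    nw <- random_network(n = sample(5:12, 1), p = 0.3, seed = 100 + seed)
    d_oracle <- floyd_warshall(nw)
    d_pkg <- igraph::distances(nw$graph, weights = NA)
    d_pkg <- d_pkg[rownames(d_oracle), colnames(d_oracle)]
    expect_equal(d_pkg, d_oracle)
  }
})

test_that("fast-greedy finds the planted two-triangle structure", {
  sep <- two_triangles(joined = FALSE)
  mods <- detect_modules_fast_greedy(sep)
  expect_equal(length(unique(mods$membership)), 2)
  expect_equal(mods$modularity, 0.5)

  joined <- two_triangles(joined = TRUE)
  mods_j <- detect_modules_fast_greedy(joined)
  expect_equal(length(unique(mods_j$membership)), 2)
  expect_equal(mods_j$modularity, 6 / 7 - 1 / 2, tolerance = 1e-12)
})

test_that("edgeless graphs give singleton modules with Q = 0", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  mods <- detect_modules_fast_greedy(as_gene_network(g))
  expect_equal(length(unique(mods$membership)), 3)
  expect_equal(mods$modularity, 0)
})

test_that("modularity is invariant under relabeling and bounded by the brute-force optimum", {
  nw <- two_triangles(joined = TRUE)
  mods <- detect_modules_fast_greedy(nw)
  mem_int <- as.integer(factor(mods$membership))[order(names(mods$membership))]
  q1 <- modularity_of_partition(nw, setNames(
    mem_int, sort(names(mods$membership)))[igraph::V(nw$graph)$name])
  q2 <- modularity_of_partition(nw, setNames(
    3 - mem_int, sort(names(mods$membership)))[igraph::V(nw$graph)$name])
  expect_equal(q1, q2)
  expect_lte(mods$modularity, max_modularity_brute(nw) + 1e-12)
})

test_that("node roles follow the Zi-Pi thresholds on hand-solved graphs", {
  joined <- two_triangles(joined = TRUE)
  mods <- list(membership = setNames(c("A", "A", "A", "B", "B", "B"),
                                     as.character(1:6)))
  roles <- classify_node_roles(joined, mods)
  bridge <- roles[roles$gene == "3", ]
  expect_equal(bridge$p, 1 - (4 / 9 + 1 / 9))
  expect_identical(bridge$role, "peripheral")
  inner <- roles[roles$gene == "1", ]
  expect_equal(inner$p, 0)  # all links inside its own module
  # within-module degrees are equal in each triangle, so all z = 0
  expect_true(all(roles$z == 0))
})

test_that("a high-participation node is a connector", {
  # hub 1 linked once into each of three 3-node modules
  e <- rbind(c(2, 3), c(3, 4), c(2, 4), c(5, 6), c(6, 7), c(5, 7),
             c(8, 9), c(9, 10), c(8, 10), c(1, 2), c(1, 5), c(1, 8))
  nw <- graph_from_edges(e)
  mem <- setNames(c("H", rep("A", 3), rep("B", 3), rep("C", 3)),
                  as.character(1:10))
  roles <- classify_node_roles(nw, mem)
  hub <- roles[roles$gene == "1", ]
  expect_equal(hub$p, 1 - 3 * (1 / 3)^2)
  expect_identical(hub$role, "connector")
})

test_that("power-law fitting recovers a generative exponent and flags degenerate input", {
  set.seed(41)
  k_support <- 1:12
  prob <- k_support^(-2.5)
  deg <- sample(k_support, 500, replace = TRUE, prob = prob / sum(prob))
  # wrap the degree sequence as a fake network via a degree-preserving stub
  fake <- structure(list(graph = igraph::sample_degseq(
    deg + (sum(deg) %% 2) * c(1, rep(0, 499)), method = "configuration")),
    class = "gene_network")
  igraph::V(fake$graph)$name <- as.character(seq_along(deg))
  fit <- fit_power_law(fake)
  expect_true(fit$supported)
  expect_lt(abs(fit$exponent - 2.5), 0.4)
  expect_gte(fit$r2, 0)
  expect_lte(fit$r2, 1)

  ring <- graph_from_edges(cbind(1:6, c(2:6, 1)))  # regular: one distinct degree
  expect_false(fit_power_law(ring)$supported)
})

test_that("shared-node partition enumerates Venn cells correctly", {
  mk <- function(nodes) {
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    as_gene_network(g)
  }
  nets <- list(x = mk(c("a", "b", "c")), y = mk(c("a", "b", "c")))
  part <- shared_node_partition(nets)
  expect_equal(part$pct[part$groups == "x & y"], 100)

  nets2 <- list(x = mk(c("a", "b")), y = mk(c("c", "d")))
  part2 <- shared_node_partition(nets2)
  expect_equal(part2$count[part2$groups == "x"], 2)
  expect_equal(part2$count[part2$groups == "y"], 2)
  expect_equal(part2$count[part2$groups == "x & y"], 0)

  nets3 <- list(x = mk(c("a", "b", "c")), y = mk(c("b", "c", "d")),
                z = mk(c("c", "d", "e")))
  part3 <- shared_node_partition(nets3)
  got <- setNames(part3$count, part3$groups)
  expect_equal(got[["x"]], 1)            # a
  expect_equal(got[["x & y"]], 1)        # b
  expect_equal(got[["x & y & z"]], 1)    # c
  expect_equal(got[["y & z"]], 1)        # d
  expect_equal(got[["z"]], 1)            # e
  expect_equal(sum(part3$count), 5)
  expect_equal(sum(part3$pct), 100)
})

test_that("enzyme-class link proportions count incident edges per class", {
  nw <- graph_from_edges(rbind(c("GH1", "GH2"), c("GH2", "GT1"),
                               c("GT1", "GT2"), c("GT2", "CE1"),
                               c("GH1", "CE1")))
  ann <- data.frame(gene_id = c("GH1", "GH2", "GT1", "GT2", "CE1"),
                    enzyme_class = c("GH", "GH", "GT", "GT", "CE"))
  props <- class_link_proportions(nw, ann)
  got <- setNames(props$link_pct, props$enzyme_class)
  # hand count over the 5 edges
  expect_equal(got[["GH"]], 100 * 3 / 5)
  expect_equal(got[["GT"]], 100 * 3 / 5)
  expect_equal(got[["CE"]], 100 * 2 / 5)
  expect_equal(setNames(props$node_pct, props$enzyme_class)[["GH"]], 40)

  all_gh <- graph_from_edges(rbind(c("GH1", "GH2"), c("GH2", "GH3")))
  ann_gh <- data.frame(gene_id = paste0("GH", 1:3), enzyme_class = "GH")
  expect_equal(class_link_proportions(all_gh, ann_gh)$link_pct, 100)

  one_edge <- graph_from_edges(cbind("GH1", "GT1"))
  ann2 <- data.frame(gene_id = c("GH1", "GT1"), enzyme_class = c("GH", "GT"))
  p2 <- class_link_proportions(one_edge, ann2)
  expect_true(all(p2$link_pct == 100))  # shared edge counts for both classes

  expect_error(class_link_proportions(one_edge,
                                      data.frame(gene_id = "GH1",
                                                 enzyme_class = "GH")),
               "GT1")
})
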