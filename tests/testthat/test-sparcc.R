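test_that("log-ratio variances match a direct per-pair computation", {
  m <- matrix(c(10, 4, 7, 3,
                 2, 8, 5, 9,
                 6, 6, 1, 12,
                 3, 5, 9, 2), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), paste0("G", 1:4)))
  tab <- abundance_table(m)
  t_mat <- log_ratio_variance_matrix(tab, pseudocount = 1)
  # oracle: variance of the log ratio computed pair by pair
  fr <- (m + 1) / rowSums(m + 1)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(t_mat[i, j], var(log(fr[, i] / fr[, j])),
                 tolerance = 1e-12)
  }
  expect_identical(t_mat, t(t_mat))
  expect_equal(unname(diag(t_mat)), rep(0, 4))
})

test_that("proportional genes have zero log-ratio variance and rho = 1", {
  set.seed(2)
  base <- matrix(rpois(10 * 4, 50) + 1, 10, 4,
                 dimnames = list(paste0("S", 1:10), paste0("G", 1:4)))
  base[, 2] <- 3 * base[, 1] + 2  # (x2 + 1) = 3 (x1 + 1) after pseudocount
  tab <- abundance_table(base)
  t_mat <- log_ratio_variance_matrix(tab)
  expect_equal(t_mat["G1", "G2"], 0, tolerance = 1e-12)
  est <- estimate_basis_correlations(t_mat)
  expect_equal(est$rho["G1", "G2"], 1)
})

test_that("fewer than 4 genes or samples is rejected", {
  m <- matrix(1:9, 3, 3, dimnames = list(paste0("S", 1:3), paste0("G", 1:3)))
  expect_error(log_ratio_variance_matrix(abundance_table(m)), ">= 4 genes")
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("S", 1:3), paste0("G", 1:4)))
  expect_error(log_ratio_variance_matrix(abundance_table(m)), ">= 4 samples")
})

test_that("a single strong planted correlation is recovered within 0.15", {
  cfg <- synthetic_config(n_samples_per_group = 200, groups = "a",
                          n_genes = 50, module_sizes = c(2L),
                          within_module_rho = 0.8, negative_fraction = 0,
                          hub_count = 0, seed = 31)
  d <- generate_dataset(cfg)
  pair <- names(d$truth$module_assignment)[!is.na(d$truth$module_assignment)]
  est <- estimate_basis_correlations(log_ratio_variance_matrix(d$abundance))
  expect_lt(abs(est$rho[pair[1], pair[2]] - 0.8), 0.15)
})

test_that("independent genes yield small estimated correlations", {
  cfg <- synthetic_config(n_samples_per_group = 100, groups = "a",
                          n_genes = 50, module_sizes = c(2L),
                          within_module_rho = 0.5, hub_count = 0, seed = 32)
  d <- generate_dataset(cfg)
  est <- estimate_basis_correlations(log_ratio_variance_matrix(d$abundance))
  bg <- names(d$truth$module_assignment)[is.na(d$truth$module_assignment)]
  off <- est$rho[bg, bg][upper.tri(est$rho[bg, bg])]
  expect_lte(mean(abs(off)), 0.15)
})

test_that("rho stays clipped and symmetric through estimation", {
  d <- generate_dataset(synthetic_config(n_samples_per_group = 12,
                                         groups = "a", n_genes = 25,
                                         module_sizes = c(8L),
                                         within_module_rho = 0.9, seed = 33))
  est <- estimate_basis_correlations(log_ratio_variance_matrix(d$abundance))
  expect_true(all(est$rho >= -1 & est$rho <= 1))
  expect_identical(est$rho, t(est$rho))
  expect_equal(unname(diag(est$rho)), rep(1, 25))
})

test_that("doubling one gene's scale barely moves other pairs (compositional robustness)", {
  cfg <- synthetic_config(n_samples_per_group = 150, groups = "a",
                          n_genes = 30, module_sizes = c(6L),
                          within_module_rho = 0.8, hub_count = 0, seed = 34)
  d <- generate_dataset(cfg)
  est1 <- estimate_basis_correlations(log_ratio_variance_matrix(d$abundance))
  bumped <- d$abundance$counts
  bumped[, 1] <- bumped[, 1] * 8  # large scale change of one component
  est2 <- estimate_basis_correlations(
    log_ratio_variance_matrix(abundance_table(bumped, d$abundance$group)))
  others <- setdiff(colnames(bumped), colnames(bumped)[1])
  delta <- abs(est1$rho[others, others] - est2$rho[others, others])
  expect_lt(max(delta), 0.1)
})

test_that("permutation p-values follow the add-one rule and are reproducible", {
  d <- generate_dataset(synthetic_config(n_samples_per_group = 30,
                                         groups = "a", n_genes = 10,
                                         module_sizes = c(4L),
                                         within_module_rho = 0.95, seed = 35))
  t_mat <- log_ratio_variance_matrix(d$abundance)
  est <- estimate_basis_correlations(t_mat)
  n_perm <- 60
  p1 <- permutation_significance(d$abundance, est$rho, n_perm = n_perm,
                                 seed = 17)
  p2 <- permutation_significance(d$abundance, est$rho, n_perm = n_perm,
                                 seed = 17)
  expect_identical(p1, p2)
  expect_true(all(is.na(diag(p1))))
  ut <- p1[upper.tri(p1)]
  expect_true(all(ut >= 1 / (n_perm + 1) & ut <= 1))
  # the strongest planted pair should beat every permutation: p = 1/(B+1)
  mod_genes <- names(d$truth$module_assignment)[
    !is.na(d$truth$module_assignment)]
  expect_equal(min(p1[mod_genes, mod_genes], na.rm = TRUE), 1 / (n_perm + 1))
})

test_that("BH adjustment reproduces the hand step-up and its guarantees", {
  genes <- paste0("G", 1:4)
  # upper triangle p = (0.01, 0.02, 0.03, 0.04, 0.9, 1.0), m = 6
  p <- sym_mat(genes)
  p[1, 2] <- 0.01; p[1, 3] <- 0.02; p[1, 4] <- 0.03
  p[2, 3] <- 0.04; p[2, 4] <- 0.9; p[3, 4] <- 1.0
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  q <- bh_fdr(p)
  # step-up by hand: q_k = min_{j >= k} p_(j) m / j
  expect_equal(q[1, 2], 0.06)
  expect_equal(q[2, 3], 0.06)
  expect_equal(q[2, 4], 1.0)
  expect_equal(q[3, 4], 1.0)
  # equal p's are unchanged; q >= p always
  p_eq <- sym_mat(genes, fill = 0.2)
  q_eq <- bh_fdr(p_eq)
  expect_equal(q_eq[upper.tri(q_eq)], p_eq[upper.tri(p_eq)])
  expect_true(all(q[upper.tri(q)] >= p[upper.tri(p)]))
  p[2, 3] <- NA; p[3, 2] <- NA
  expect_error(bh_fdr(p), "NA")
})

test_that("the full estimate object satisfies its structural invariants", {
  d <- generate_dataset(synthetic_config(n_samples_per_group = 20,
                                         groups = "a", n_genes = 12,
                                         module_sizes = c(5L),
                                         within_module_rho = 0.9, seed = 36))
  est <- sparcc_correlation(d$abundance, n_perm = 40, seed = 3)
  expect_s3_class(est, "correlation_estimate")
  expect_identical(est$p_values, t(est$p_values))
  expect_identical(est$q_values, t(est$q_values))
  ut <- upper.tri(est$rho)
  expect_true(all(est$q_values[ut] >= est$p_values[ut] - 1e-12))
  expect_true(all(est$t_matrix >= 0))
})
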