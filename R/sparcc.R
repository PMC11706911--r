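# SparCC basis-correlation inference for compositional count data.
#
# The observed counts only carry relative information: closure to fractions
# induces spurious negative correlation among proportions. SparCC works on
# log-ratio variances t_ij = var log(x_i/x_j), which are invariant to the
# closure, and solves for latent per-gene ("basis") variances omega_i under
# the sparsity approximation that most true correlations are zero:
#
#   t_ij = omega_i + omega_j - 2 rho_ij sqrt(omega_i omega_j)
#
# Summing over j with rho ~= 0 gives a linear system in omega; pairs whose
# estimated |rho| exceeds an exclusion threshold are iteratively removed
# from the system and it is re-solved, so a few strong correlations do not
# bias the variance estimates.

#' Log-ratio variance matrix
#'
#' Computes \eqn{t_{ij} = \mathrm{var}\, \log(x_i / x_j)} over samples on
#' per-sample fractions, after adding a pseudocount. Uses the identity
#' \eqn{t_{ij} = C_{ii} + C_{jj} - 2C_{ij}} with \eqn{C} the covariance of
#' the log fractions, so the computation is a single covariance pass.
#'
#' @param table an \code{\link{abundance_table}} (>= 4 samples, >= 4 genes).
#' @param pseudocount added to every count before closure to fractions.
#' @return Symmetric genes x genes matrix with zero diagonal.
#' @export
log_ratio_variance_matrix <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$counts + pseudocount
  if (ncol(x) < 4)
    stop("SparCC needs >= 4 genes; the basis-variance system is ",
         "underdetermined with ", ncol(x))
  if (nrow(x) < 4)
    stop("SparCC needs >= 4 samples; got ", nrow(x))
  y <- log(x / rowSums(x))
  C <- cov(y)
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  t_mat[t_mat < 0] <- 0  # numerical guard; exact zeros for proportional genes
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(colnames(x), colnames(x))
  t_mat
}

#' Estimate SparCC basis variances and correlations
#'
#' Solves the sparsity-approximated linear system for basis variances
#' \eqn{\omega}, forms \eqn{\rho_{ij} = (\omega_i + \omega_j - t_{ij}) /
#' (2\sqrt{\omega_i \omega_j})} clipped to \eqn{[-1, 1]}, and iteratively
#' excludes the strongest pair with \eqn{|\rho|} above
#' \code{exclusion_threshold} from the variance system (one pair per round,
#' up to \code{max_exclusion_rounds}), re-solving each time.
#'
#' @param t_matrix symmetric log-ratio variance matrix from
#'   \code{\link{log_ratio_variance_matrix}}.
#' @param exclusion_threshold \eqn{|\rho|} above which a pair is excluded
#'   from the basis-variance system.
#' @param max_exclusion_rounds maximum number of excluded pairs.
#' @return List with \code{rho} (clipped correlation matrix, unit diagonal),
#'   \code{omega} (basis variances, floored at a small positive epsilon if
#'   the solver returns a negative value), and \code{excluded} (two-column
#'   matrix of excluded pair indices).
#' @export
estimate_basis_correlations <- function(t_matrix, exclusion_threshold = 0.8,
                                        max_exclusion_rounds = 10) {
  G <- nrow(t_matrix)
  stopifnot(G == ncol(t_matrix), G >= 4)
  M <- matrix(1, G, G)
  diag(M) <- G - 1
  t_work <- t_matrix
  excluded <- matrix(integer(0), ncol = 2)
  floored <- FALSE

  solve_round <- function() {
    omega <- tryCatch(solve(M, rowSums(t_work)),
                      error = function(e)
                        stop("basis-variance system is singular after ",
                             nrow(excluded), " exclusions; lower ",
                             "max_exclusion_rounds or raise ",
                             "exclusion_threshold", call. = FALSE))
    if (any(omega <= 0)) {
      floored <<- TRUE
      omega[omega <= 0] <- 1e-10
    }
    rho <- (outer(omega, omega, "+") - t_matrix) / (2 * sqrt(outer(omega, omega)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    list(omega = omega, rho = rho)
  }

  fit <- solve_round()
  for (round in seq_len(max_exclusion_rounds)) {
    a <- abs(fit$rho)
    diag(a) <- 0
    if (nrow(excluded) > 0) a[excluded] <- 0
    top <- arrayInd(which.max(a), dim(a))
    if (a[top] <= exclusion_threshold) break
    i <- top[1]; j <- top[2]
    excluded <- rbind(excluded, c(i, j), c(j, i))
    t_work[i, j] <- t_work[j, i] <- 0
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    fit <- solve_round()
  }
  if (floored)
    warning("negative basis variance(s) floored at 1e-10; estimates for ",
            "the affected genes are unreliable")
  dimnames(fit$rho) <- dimnames(t_matrix)
  names(fit$omega) <- rownames(t_matrix)
  list(rho = fit$rho, omega = fit$omega, excluded = excluded)
}

.sparcc_rho <- function(counts, pseudocount, exclusion_threshold,
                        max_exclusion_rounds) {
  x <- counts + pseudocount
  y <- log(x / rowSums(x))
  C <- cov(y)
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0
  suppressWarnings(
    estimate_basis_correlations(t_mat, exclusion_threshold,
                                max_exclusion_rounds)$rho)
}

#' Permutation significance for SparCC correlations
#'
#' Each permutation shuffles every gene's values across samples
#' independently (destroying all between-gene association while keeping
#' marginal distributions), recomputes the full SparCC estimate, and
#' compares \eqn{|\rho|} pairwise. Two-sided add-one p-values:
#' \eqn{p_{ij} = (1 + \#\{|\rho^{perm}_{ij}| \ge |\rho^{obs}_{ij}|\}) /
#' (1 + n_{perm})}.
#'
#' @param table the \code{\link{abundance_table}} the correlations came from.
#' @param rho observed SparCC correlation matrix.
#' @param n_perm number of permutations.
#' @param seed integer seed; fixed seed gives an identical p-value matrix.
#' @param pseudocount,exclusion_threshold,max_exclusion_rounds passed through
#'   to the SparCC recomputation.
#' @return Symmetric matrix of p-values with \code{NA} diagonal.
#' @export
permutation_significance <- function(table, rho, n_perm = 1000, seed = 1L,
                                     pseudocount = 1,
                                     exclusion_threshold = 0.8,
                                     max_exclusion_rounds = 10) {
  stopifnot(inherits(table, "abundance_table"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  counts <- table$counts
  stopifnot(ncol(counts) == nrow(rho))
  set.seed(seed)
  n <- nrow(counts)
  abs_obs <- abs(rho)
  exceed <- matrix(0, nrow(rho), ncol(rho))
  for (b in seq_len(n_perm)) {
    perm <- apply(counts, 2, sample, size = n)
    rho_p <- .sparcc_rho(perm, pseudocount, exclusion_threshold,
                         max_exclusion_rounds)
    exceed <- exceed + (abs(rho_p) >= abs_obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p <- (p + t(p)) / 2  # symmetric by construction; guard against fp asymmetry
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho)
  p
}

#' Benjamini-Hochberg adjustment over unique gene pairs
#'
#' Applies the BH step-up to the \eqn{G(G-1)/2} upper-triangle p-values and
#' mirrors the result to the lower triangle.
#'
#' @param p_values symmetric p-value matrix (diagonal ignored).
#' @return Symmetric q-value matrix with \code{NA} diagonal.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.matrix(p_values), nrow(p_values) == ncol(p_values))
  ut <- upper.tri(p_values)
  p <- p_values[ut]
  if (anyNA(p)) stop("NA p-values in the upper triangle")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  q <- p.adjust(p, method = "BH")
  out <- p_values
  out[ut] <- q
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- NA_real_
  out
}

#' Full SparCC correlation estimate with significance
#'
#' Convenience wrapper running \code{\link{log_ratio_variance_matrix}},
#' \code{\link{estimate_basis_correlations}},
#' \code{\link{permutation_significance}} and \code{\link{bh_fdr}}.
#'
#' @inheritParams log_ratio_variance_matrix
#' @inheritParams permutation_significance
#' @param exclusion_threshold,max_exclusion_rounds exclusion-loop controls.
#' @return An object of class \code{correlation_estimate}: list with
#'   \code{gene_ids}, \code{rho}, \code{t_matrix}, \code{omega},
#'   \code{p_values}, \code{q_values}, \code{n_permutations}, \code{seed}.
#' @examples
#' d <- generate_dataset(synthetic_config(
#'   n_samples_per_group = 10, groups = "g", n_genes = 12,
#'   module_sizes = c(4L, 4L), seed = 7))
#' est <- sparcc_correlation(d$abundance, n_perm = 20, seed = 7)
#' range(est$rho)
#' @export
sparcc_correlation <- function(table, n_perm = 1000, seed = 1L,
                               pseudocount = 1, exclusion_threshold = 0.8,
                               max_exclusion_rounds = 10) {
  t_mat <- log_ratio_variance_matrix(table, pseudocount)
  est <- estimate_basis_correlations(t_mat, exclusion_threshold,
                                     max_exclusion_rounds)
  p <- permutation_significance(table, est$rho, n_perm = n_perm, seed = seed,
                                pseudocount = pseudocount,
                                exclusion_threshold = exclusion_threshold,
                                max_exclusion_rounds = max_exclusion_rounds)
  q <- bh_fdr_allow_na(p)
  structure(
    list(gene_ids = colnames(table$counts),
         rho = est$rho,
         t_matrix = t_mat,
         omega = est$omega,
         p_values = p,
         q_values = q,
         n_permutations = n_perm,
         seed = seed),
    class = "correlation_estimate")
}

# permutation matrices carry an NA diagonal; adjust off-diagonal pairs only
bh_fdr_allow_na <- function(p_values) {
  tmp <- p_values
  diag(tmp) <- 0
  out <- bh_fdr(tmp)
  diag(out) <- NA_real_
  out
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat("<correlation_estimate> ", length(x$gene_ids), " genes, ",
      x$n_permutations, " permutations (seed ", x$seed, ")\n", sep = "")
  off <- abs(x$rho[upper.tri(x$rho)])
  cat("mean |rho| = ", round(mean(off), 3),
      "; max |rho| = ", round(max(off), 3), "\n", sep = "")
  invisible(x)
}
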