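# Network stability: global efficiency, robustness under node removal,
# per-node vulnerability, and per-sample cohesion.

#' Global network efficiency
#'
#' \eqn{Eff = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}} over ordered node
#' pairs, with unweighted hop distances and \eqn{1/d = 0} for disconnected
#' pairs. \eqn{N} is the current node count, so efficiency is comparable
#' across deletion steps of the same attack but can rise when a peripheral
#' node is removed.
#'
#' @param network a \code{gene_network} or an \pkg{igraph} graph.
#' @return Efficiency in \eqn{[0, 1]}; 0 (with a warning) for fewer than 2
#'   nodes.
#' @export
network_efficiency <- function(network) {
  g <- if (inherits(network, "gene_network")) network$graph else network
  N <- igraph::vcount(g)
  if (N < 2) {
    warning("efficiency undefined for fewer than 2 nodes; returning 0")
    return(0)
  }
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Robustness under random or targeted node removal
#'
#' Removes \code{round(f * N)} nodes at each removal fraction
#' \eqn{f \in \{0, 0.1, ..., 0.5\}} and records the efficiency of the
#' remainder. Targeted attack removes nodes by descending intact-network
#' degree (ties broken by descending absolute-weighted degree, then by gene
#' ID), computed once on the intact network. Random attack averages over
#' \code{n_iterations} uniform removal orders. The decline statistics are
#' the \eqn{R^2} and p-value of the OLS regression of the (mean) efficiency
#' on the removal fraction.
#'
#' @param network a \code{gene_network}.
#' @param mode \code{"random"} or \code{"targeted"}.
#' @param n_iterations iterations for random attack.
#' @param seed integer seed for random attack.
#' @return Object of class \code{robustness_curve}: list with \code{mode},
#'   \code{curve} (data.frame \code{fraction}, \code{n_removed},
#'   \code{eff}, \code{eff_sd}), \code{n_iterations}, \code{decline_r2},
#'   \code{decline_p}, \code{seed}.
#' @export
robustness_under_attack <- function(network, mode = c("random", "targeted"),
                                    n_iterations = 100, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  mode <- match.arg(mode)
  g <- network$graph
  N <- igraph::vcount(g)
  if (N < 2) stop("robustness needs >= 2 nodes")
  fractions <- seq(0, 0.5, by = 0.1)
  n_remove <- round(fractions * N)
  nodes <- igraph::V(g)$name

  eff_after <- function(drop) {
    network_efficiency(igraph::delete_vertices(g, drop))
  }

  if (mode == "targeted") {
    k <- igraph::degree(g)
    wk <- igraph::strength(g, weights = abs(igraph::E(g)$weight))
    ord <- nodes[order(-k, -wk, nodes)]
    eff <- vapply(n_remove, function(m) eff_after(ord[seq_len(m)]), numeric(1))
    curve <- data.frame(fraction = fractions, n_removed = n_remove,
                        eff = eff, eff_sd = NA_real_)
  } else {
    set.seed(seed)
    effs <- matrix(NA_real_, n_iterations, length(fractions))
    for (it in seq_len(n_iterations)) {
      ord <- sample(nodes)
      effs[it, ] <- vapply(n_remove, function(m) eff_after(ord[seq_len(m)]),
                           numeric(1))
    }
    curve <- data.frame(fraction = fractions, n_removed = n_remove,
                        eff = colMeans(effs),
                        eff_sd = apply(effs, 2, sd))
  }
  fit <- lm(eff ~ fraction, data = curve)
  sm <- summary(fit)
  decline_p <- if (nrow(curve) > 2 && sm$fstatistic[1] > 0)
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)) else NA_real_
  structure(
    list(mode = mode, curve = curve,
         n_iterations = if (mode == "random") n_iterations else 1L,
         decline_r2 = sm$r.squared, decline_p = decline_p,
         seed = if (mode == "random") seed else NA_integer_),
    class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("<robustness_curve> ", x$mode, " attack; decline R2 = ",
      round(x$decline_r2, 3), "\n", sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Per-node vulnerability
#'
#' \eqn{V_i = (Eff - Eff_{-i}) / Eff}, where \eqn{Eff_{-i}} is the global
#' efficiency after deleting node \eqn{i} and its links (normalised by the
#' remaining \eqn{N - 1} nodes). \eqn{V_i} can be negative: removing a
#' peripheral node can raise the mean inverse distance of the remainder.
#'
#' @param network a \code{gene_network} with >= 3 nodes.
#' @return List of class \code{vulnerability_table}: \code{table}
#'   (data.frame \code{gene}, \code{vulnerability}), \code{mean},
#'   \code{max}, \code{efficiency} (of the intact network).
#' @export
node_vulnerability <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  N <- igraph::vcount(g)
  if (N < 3) stop("vulnerability needs >= 3 nodes")
  eff0 <- network_efficiency(g)
  nodes <- igraph::V(g)$name
  if (eff0 == 0) {
    warning("intact network has zero efficiency; vulnerability undefined")
    v <- rep(NA_real_, N)
  } else {
    v <- vapply(nodes, function(nd) {
      eff_i <- network_efficiency(igraph::delete_vertices(g, nd))
      (eff0 - eff_i) / eff0
    }, numeric(1))
  }
  structure(
    list(table = data.frame(gene = nodes, vulnerability = unname(v),
                            stringsAsFactors = FALSE),
         mean = mean(v), max = if (anyNA(v)) NA_real_ else max(v),
         efficiency = eff0),
    class = "vulnerability_table")
}

#' Per-sample community cohesion
#'
#' For each gene \eqn{j} in the network, its positive connectedness is the
#' mean of the positive edge weights incident to it (0 if none) and its
#' negative connectedness the mean of the negative weights. For each sample
#' with relative abundances \eqn{r_{sj}} over the network genes, positive
#' cohesion is \eqn{\sum_j r_{sj}\,\bar{w}^+_j}, negative cohesion is the
#' absolute value of the corresponding negative sum, and the ratio is
#' negative/positive (flagged \code{NA} when positive cohesion is 0).
#' Cohesion is invariant to rescaling a sample's total abundance.
#'
#' @param table an \code{\link{abundance_table}} containing the network's
#'   genes.
#' @param network a \code{gene_network}.
#' @param connectedness_from \code{"network"} (default: mean over retained,
#'   thresholded edges) or \code{"correlation"} (mean over all off-diagonal
#'   correlations, requiring \code{corr}).
#' @param corr a \code{correlation_estimate}; needed only for
#'   \code{connectedness_from = "correlation"}.
#' @return data.frame of class \code{cohesion_table} with \code{sample},
#'   \code{group}, \code{positive}, \code{negative}, \code{ratio}.
#' @export
sample_cohesion <- function(table, network,
                            connectedness_from = c("network", "correlation"),
                            corr = NULL) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(network, "gene_network"))
  connectedness_from <- match.arg(connectedness_from)
  g <- network$graph
  genes <- igraph::V(g)$name
  missing_genes <- setdiff(genes, table$gene_ids)
  if (length(missing_genes) > 0)
    stop("network gene(s) absent from the abundance table: ",
         paste(missing_genes, collapse = ", "))
  if (connectedness_from == "network") {
    conn_pos <- conn_neg <- setNames(numeric(length(genes)), genes)
    if (igraph::ecount(g) > 0) {
      ends <- igraph::as_edgelist(g)
      w <- igraph::E(g)$weight
      for (j in genes) {
        inc <- w[ends[, 1] == j | ends[, 2] == j]
        pos <- inc[inc > 0]
        neg <- inc[inc < 0]
        conn_pos[j] <- if (length(pos) > 0) mean(pos) else 0
        conn_neg[j] <- if (length(neg) > 0) mean(neg) else 0
      }
    }
  } else {
    if (is.null(corr)) stop("connectedness_from = 'correlation' needs `corr`")
    rho <- corr$rho[genes, genes, drop = FALSE]
    diag(rho) <- NA
    conn_pos <- apply(rho, 1, function(r) {
      pos <- r[!is.na(r) & r > 0]
      if (length(pos) > 0) mean(pos) else 0
    })
    conn_neg <- apply(rho, 1, function(r) {
      neg <- r[!is.na(r) & r < 0]
      if (length(neg) > 0) mean(neg) else 0
    })
  }
  counts <- table$counts[, genes, drop = FALSE]
  totals <- rowSums(counts)
  if (any(totals == 0))
    warning("sample(s) with zero total abundance over network genes: ",
            paste(rownames(counts)[totals == 0], collapse = ", "))
  rel <- counts / ifelse(totals == 0, NA, totals)
  pos <- as.numeric(rel %*% conn_pos)
  neg <- abs(as.numeric(rel %*% conn_neg))
  ratio <- ifelse(pos == 0, NA_real_, neg / pos)
  out <- data.frame(sample = rownames(counts),
                    group = unname(table$group[rownames(counts)]),
                    positive = pos, negative = neg, ratio = ratio,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohesion_table", "data.frame")
  out
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Compares a per-observation stability metric (node vulnerability, sample
#' cohesion, ...) between groups: one-way ANOVA followed by Tukey's HSD at
#' the 5% level with a compact letter display — groups sharing no letter
#' differ significantly.
#'
#' @param values numeric vector of observations.
#' @param group group label per observation (>= 2 groups, >= 2 observations
#'   each).
#' @return List of class \code{group_comparison}: \code{F},
#'   \code{df_between}, \code{df_within}, \code{p}, \code{tukey}
#'   (data.frame of pairwise contrasts), \code{letters} (named character).
#' @export
compare_groups <- function(values, group) {
  stopifnot(length(values) == length(group))
  ok <- complete.cases(values, group)
  values <- values[ok]
  group <- factor(as.character(group[ok]))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  sizes <- table(group)
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  df <- data.frame(y = values, g = group)
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$g
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = 0.05)$mcletters$Letters
  structure(
    list(F = an["g", "F value"],
         df_between = an["g", "Df"],
         df_within = an["Residuals", "Df"],
         p = an["g", "Pr(>F)"],
         tukey = data.frame(contrast = rownames(tuk), tuk, row.names = NULL),
         letters = letters[levels(group)]),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$F, 4), ", p = ", signif(x$p, 3), "\n", sep = "")
  print(data.frame(group = names(x$letters), letter = unname(x$letters)),
        row.names = FALSE)
  invisible(x)
}
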