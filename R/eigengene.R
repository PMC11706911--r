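# Module eigengenes: per-module first principal component of standardised
# gene profiles, used to correlate each module's higher-order abundance
# pattern with environmental covariates.

#' Module eigengenes
#'
#' For each module with at least 2 genes present in the table,
#' \code{log1p}-transforms (by default) and standardises the member genes to
#' zero mean and unit variance across samples, extracts the first principal
#' component, scales the score vector to unit variance, and fixes its sign
#' so that it correlates positively with the module's mean standardised
#' profile.
#'
#' @param table an \code{\link{abundance_table}} (>= 3 samples).
#' @param modules a \code{\link{detect_modules_fast_greedy}} result or named
#'   membership vector (gene -> module label).
#' @param transform \code{"log1p"} (default; sequencing counts are
#'   approximately log-normal, so the component is extracted on the log
#'   scale) or \code{"none"} for already-transformed abundances.
#' @return Object of class \code{eigengene_matrix}: list with
#'   \code{eigengenes} (samples x modules matrix, unit-variance columns),
#'   \code{explained_variance} (named fraction in (0, 1]), \code{skipped}
#'   (modules with < 2 usable genes).
#' @export
module_eigengenes <- function(table, modules,
                              transform = c("log1p", "none")) {
  stopifnot(inherits(table, "abundance_table"))
  transform <- match.arg(transform)
  mem <- if (is.list(modules)) modules$membership else modules
  if (nrow(table$counts) < 3) stop("eigengenes need >= 3 samples")
  mem <- mem[names(mem) %in% table$gene_ids]
  labs <- unique(unname(mem))
  eig <- list()
  expl <- c()
  skipped <- character(0)
  for (m in sort(labs)) {
    genes <- names(mem)[mem == m]
    X <- table$counts[, genes, drop = FALSE]
    if (transform == "log1p") X <- log1p(X)
    sds <- apply(X, 2, sd)
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) {
      warning("module ", m, " has fewer than 2 usable genes; skipped")
      skipped <- c(skipped, m)
      next
    }
    Xs <- scale(X)
    pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
    e <- pc$x[, 1]
    if (sd(e) == 0) {
      warning("module ", m, " has a degenerate first component; skipped")
      skipped <- c(skipped, m)
      next
    }
    e <- e / sd(e)
    if (cor(e, rowMeans(Xs)) < 0) e <- -e
    eig[[m]] <- e
    expl[m] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  if (length(eig) == 0) stop("no module had >= 2 usable genes")
  structure(
    list(eigengenes = do.call(cbind, eig),
         explained_variance = expl,
         skipped = skipped),
    class = "eigengene_matrix")
}

#' @export
print.eigengene_matrix <- function(x, ...) {
  cat("<eigengene_matrix> ", ncol(x$eigengenes), " modules x ",
      nrow(x$eigengenes), " samples; explained variance: ",
      paste(names(x$explained_variance),
            round(x$explained_variance, 2), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Correlate module eigengenes with soil chemistry
#'
#' Pearson correlation with two-sided p-value for every (module, property)
#' pair over the shared samples, Benjamini-Hochberg adjusted across the full
#' grid, with significance stars on the q-values (\code{*} q < 0.05,
#' \code{**} q < 0.01, \code{***} q < 0.001). Zero-variance properties are
#' reported with missing correlations and excluded from the adjustment.
#'
#' @param eigengenes a \code{\link{module_eigengenes}} result.
#' @param chemistry samples x properties numeric matrix (>= 4 shared
#'   samples).
#' @return data.frame of class \code{env_correlation_table} with
#'   \code{module}, \code{property}, \code{r}, \code{p}, \code{q},
#'   \code{stars}, \code{n}.
#' @export
correlate_eigengenes_with_chemistry <- function(eigengenes, chemistry) {
  stopifnot(inherits(eigengenes, "eigengene_matrix"), is.matrix(chemistry))
  E <- eigengenes$eigengenes
  shared <- intersect(rownames(E), rownames(chemistry))
  if (length(shared) < 4)
    stop("need >= 4 shared samples; got ", length(shared))
  E <- E[shared, , drop = FALSE]
  Chem <- chemistry[shared, , drop = FALSE]
  grid <- expand.grid(module = colnames(E), property = colnames(Chem),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    e <- E[, grid$module[i]]
    v <- Chem[, grid$property[i]]
    if (sd(v) == 0 || sd(e) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(e, v, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(grid, r = res[, "r"], p = res[, "p"],
                    q = NA_real_, stars = "", n = length(shared),
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out$stars <- ifelse(is.na(out$q), "",
               ifelse(out$q < 0.001, "***",
               ifelse(out$q < 0.01, "**",
               ifelse(out$q < 0.05, "*", ""))))
  out <- out[order(out$module, out$property), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("env_correlation_table", "data.frame")
  out
}
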