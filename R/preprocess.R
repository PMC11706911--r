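#' Remove low-abundance genes
#'
#' Retains exactly the genes with at least \code{min_count} counts in at
#' least \code{ceiling(min_prevalence * n_samples)} samples — the standard
#' prevalence filter applied to each land-use table before correlation
#' inference. The sample set is unchanged; the filter is idempotent and
#' never adds genes.
#'
#' @param table an \code{\link{abundance_table}}.
#' @param min_count minimum count for a sample to count towards prevalence.
#' @param min_prevalence minimum fraction of samples reaching
#'   \code{min_count}.
#' @param verbose log the retained-gene summary via \code{message()}.
#' @return The filtered \code{abundance_table}.
#' @export
filter_low_abundance <- function(table, min_count = 3, min_prevalence = 0.10,
                                 verbose = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  n <- nrow(table$counts)
  if (n == 0 || ncol(table$counts) == 0) stop("abundance table is empty")
  need <- ceiling(min_prevalence * n)
  prevalence <- colSums(table$counts >= min_count)
  keep <- prevalence >= need
  if (!any(keep)) {
    stop("all ", length(keep), " genes removed by the low-abundance filter ",
         "(required >= ", min_count, " counts in >= ", need, "/", n,
         " samples; max prevalence observed: ", max(prevalence), ")")
  }
  if (verbose)
    message("low-abundance filter: retained ", sum(keep), "/", length(keep),
            " genes (>= ", min_count, " counts in >= ", need, "/", n,
            " samples)")
  abundance_table(table$counts[, keep, drop = FALSE], group = table$group)
}

#' Split an abundance table by group
#'
#' Partitions the samples by their group label, preserving group order of
#' first appearance. Filtering is intended to be applied per group, after
#' splitting, so each group's network is built from its own prevalent genes.
#'
#' @param table an \code{\link{abundance_table}}.
#' @return Named list of \code{abundance_table}, one per group.
#' @export
split_by_group <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (anyNA(table$group) || any(!nzchar(table$group)))
    stop("every sample must carry a nonempty group label")
  groups <- unique(table$group)
  out <- lapply(groups, function(g) {
    ids <- table$sample_ids[table$group == g]
    if (length(ids) < 3)
      warning("group '", g, "' has only ", length(ids),
              " samples; correlations will be unstable")
    abundance_table(table$counts[ids, , drop = FALSE],
                    group = table$group[ids])
  })
  names(out) <- groups
  out
}
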