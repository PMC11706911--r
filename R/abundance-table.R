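#' Construct an abundance table
#'
#' The canonical container for a gene-family abundance matrix: samples in
#' rows, gene families (e.g. CAZy families such as \code{"GH13"}) in columns,
#' with one land-use (or other) group label per sample. Counts are
#' nonnegative; the table is assumed already standardised by read depth
#' upstream.
#'
#' @param counts numeric matrix, samples x genes, with row and column names.
#' @param group character vector of group labels, one per sample; either
#'   named by sample ID or in row order. Defaults to a single group.
#' @return An object of class \code{abundance_table}: a list with elements
#'   \code{counts} (samples x genes matrix), \code{sample_ids},
#'   \code{gene_ids} and \code{group} (named character vector).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("GH", 1:4)))
#' abundance_table(m, group = c("forest", "forest", "pasture"))
#' @export
abundance_table <- function(counts, group = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample row names and gene column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative abundance at sample '", rownames(counts)[neg[1, 1]],
         "', gene '", colnames(counts)[neg[1, 2]], "'")
  if (anyNA(counts))
    stop("`counts` contains missing values")
  if (is.null(group)) group <- rep("all", nrow(counts))
  if (!is.null(names(group))) {
    missing_grp <- setdiff(rownames(counts), names(group))
    if (length(missing_grp) > 0)
      stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
    group <- group[rownames(counts)]
  } else {
    if (length(group) != nrow(counts))
      stop("`group` must have one label per sample")
    names(group) <- rownames(counts)
  }
  group <- as.character(group)
  names(group) <- rownames(counts)
  if (anyNA(group) || any(!nzchar(group)))
    stop("empty or missing group label for sample(s): ",
         paste(rownames(counts)[is.na(group) | !nzchar(group)], collapse = ", "))
  structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         gene_ids = colnames(counts),
         group = group),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", length(x$sample_ids), " samples x ",
      length(x$gene_ids), " genes\n", sep = "")
  tab <- table(x$group)
  cat("groups: ", paste(names(tab), " (", tab, ")", sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Subset an abundance table
#'
#' @param x an \code{abundance_table}.
#' @param samples,genes character vectors of IDs to retain (default: all).
#' @return An \code{abundance_table} restricted to the requested samples/genes.
#' @export
subset_abundance <- function(x, samples = x$sample_ids, genes = x$gene_ids) {
  stopifnot(inherits(x, "abundance_table"))
  bad_s <- setdiff(samples, x$sample_ids)
  if (length(bad_s) > 0) stop("unknown sample(s): ", paste(bad_s, collapse = ", "))
  bad_g <- setdiff(genes, x$gene_ids)
  if (length(bad_g) > 0) stop("unknown gene(s): ", paste(bad_g, collapse = ", "))
  abundance_table(x$counts[samples, genes, drop = FALSE], group = x$group[samples])
}
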