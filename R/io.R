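# Fixed on-disk dialects: TSV, UTF-8, "." decimal, header row, first column
# = row IDs; canonical in-memory orientation is samples x genes.

.read_tsv_matrix <- function(path, what = "table") {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop(what, " file must have row IDs plus >= 1 data column: ", path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate column IDs in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric value in ", path, " at row '", ids[bad[1, 1]],
           "', column '", colnames(m)[bad[1, 2]], "'")
    m <- matrix(as.numeric(m), nrow(m), dimnames = list(NULL, colnames(m)))
  }
  rownames(m) <- ids
  m
}

#' Read a gene-abundance table from TSV
#'
#' @param path TSV file: header row, first column row IDs, numeric cells.
#' @param orientation \code{"samples_by_genes"} (default) or
#'   \code{"genes_by_samples"}; the latter is transposed on read so the
#'   in-memory table is always samples x genes.
#' @param metadata_path optional sample-metadata TSV (columns
#'   \code{sample_id}, \code{group}) used to attach group labels.
#' @param group optional named character vector of group labels, used when
#'   \code{metadata_path} is not given.
#' @return An \code{\link{abundance_table}}.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_by_genes",
                                                 "genes_by_samples"),
                                 metadata_path = NULL, group = NULL) {
  orientation <- match.arg(orientation)
  m <- .read_tsv_matrix(path, "abundance")
  if (orientation == "genes_by_samples") m <- t(m)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative abundance in ", path, " at sample '",
         rownames(m)[neg[1, 1]], "', gene '", colnames(m)[neg[1, 2]], "'")
  if (!is.null(metadata_path)) group <- read_sample_metadata(metadata_path)
  abundance_table(m, group = group)
}

#' @rdname read_abundance_table
#' @param table an \code{abundance_table} to write (samples x genes).
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  .write_tsv_matrix(table$counts, path, id_col = "sample_id")
}

.write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write sample-to-group metadata
#'
#' @param path TSV with columns \code{sample_id} and \code{group}.
#' @return \code{read_sample_metadata}: named character vector of group
#'   labels.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df)))
    stop("metadata file must have columns sample_id and group: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  setNames(as.character(df$group), df$sample_id)
}

#' @rdname read_sample_metadata
#' @param group named character vector (sample -> group).
#' @export
write_sample_metadata <- function(group, path) {
  write.table(data.frame(sample_id = names(group), group = unname(group)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a soil-chemistry table
#'
#' Samples x properties numeric TSV (pH, Olsen P, total C, total N, C/N,
#' AMN/TN, moisture, CEC, exchangeable cations, ...).
#'
#' @param path TSV file path.
#' @return \code{read_chemistry_table}: numeric matrix, samples x properties.
#' @export
read_chemistry_table <- function(path) {
  .read_tsv_matrix(path, "chemistry")
}

#' @rdname read_chemistry_table
#' @param chemistry samples x properties numeric matrix.
#' @export
write_chemistry_table <- function(chemistry, path) {
  .write_tsv_matrix(chemistry, path, id_col = "sample_id")
}

#' Read or write a gene-annotation table
#'
#' @param path TSV with columns \code{gene_id}, \code{family},
#'   \code{enzyme_class}; enzyme classes must be among the six CAZy classes
#'   GT, GH, PL, CE, AA, CBM.
#' @return \code{read_annotation_table}: data.frame with those columns.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "family", "enzyme_class")
  if (!all(need %in% colnames(df)))
    stop("annotation file must have columns gene_id, family, enzyme_class: ", path)
  bad <- setdiff(unique(df$enzyme_class), .CAZY_CLASSES)
  if (length(bad) > 0)
    stop("enzyme_class outside the six CAZy classes: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene IDs in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df[, need]
}

#' @rdname read_annotation_table
#' @param annotation data.frame with \code{gene_id}, \code{family},
#'   \code{enzyme_class}.
#' @export
write_annotation_table <- function(annotation, path) {
  stopifnot(all(c("gene_id", "family", "enzyme_class") %in% colnames(annotation)))
  write.table(annotation[, c("gene_id", "family", "enzyme_class")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a gene network
#'
#' \code{edge_list} writes a 5-column TSV (\code{gene_a}, \code{gene_b},
#' \code{correlation}, \code{sign}, \code{q_value}) ordered by gene IDs;
#' \code{graphml} writes GraphML carrying node \code{enzyme_class} (and
#' \code{role}, if roles were attached via \code{\link{classify_node_roles}})
#' plus edge weight and q-value attributes.
#'
#' @param network a \code{\link{build_network}} result.
#' @param path output file.
#' @param format \code{"edge_list"} or \code{"graphml"}.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(network, path, format = c("edge_list", "graphml")) {
  stopifnot(inherits(network, "gene_network"))
  format <- match.arg(format)
  g <- network$graph
  if (format == "edge_list") {
    if (igraph::ecount(g) == 0) {
      el <- data.frame(gene_a = character(0), gene_b = character(0),
                       correlation = numeric(0), sign = character(0),
                       q_value = numeric(0))
    } else {
      ends <- igraph::as_edgelist(g)
      swap <- ends[, 1] > ends[, 2]
      el <- data.frame(gene_a = ifelse(swap, ends[, 2], ends[, 1]),
                       gene_b = ifelse(swap, ends[, 1], ends[, 2]),
                       correlation = igraph::E(g)$weight,
                       sign = ifelse(igraph::E(g)$weight >= 0,
                                     "positive", "negative"),
                       q_value = igraph::E(g)$q_value,
                       stringsAsFactors = FALSE)
      el <- el[order(el$gene_a, el$gene_b), , drop = FALSE]
    }
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
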