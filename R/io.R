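# Readers and writers for the pipeline's on-disk formats: TSV tables,
# GraphML networks (Cytoscape-compatible), FASTA proteomes and gene-set
# files. All tabular artifacts are tab-separated text.

#' Write / read a tab-separated table
#'
#' @param x data.frame.
#' @param file path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` the path,
#'   invisibly.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = TRUE, row.names = FALSE,
                     na = "NA", qmethod = "double")
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a network as GraphML
#'
#' Exports the directed network with all edge attributes (importance, rank,
#' correlations, sign) and optional node attributes (subnetwork, profile,
#' NERD-like flag) in GraphML, openable in Cytoscape.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param file output path.
#' @param partition optional [detect_communities()] result (adds a
#'   `subnetwork` node attribute).
#' @param node_attrs optional data.frame with a `gene` column plus
#'   attribute columns.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(network, file, partition = NULL,
                                  node_attrs = NULL) {
  edges <- if (inherits(network, "grn_network")) network$edges else network
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!is.null(partition)) {
    idx <- match(igraph::V(g)$name, partition$gene)
    g <- igraph::set_vertex_attr(g, "subnetwork",
                                 value = partition$subnetwork[idx])
  }
  if (!is.null(node_attrs)) {
    idx <- match(igraph::V(g)$name, node_attrs$gene)
    for (col in setdiff(names(node_attrs), "gene"))
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Read a GraphML network back into an edge table
#'
#' @param file GraphML path.
#' @return data.frame with regulator, target and all stored edge
#'   attributes; node attributes (if any) are attached as the `nodes`
#'   attribute.
#' @export
read_network_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  df <- igraph::as_data_frame(g, what = "edges")
  names(df)[1:2] <- c("regulator", "target")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  if (ncol(nodes) > 1) {
    names(nodes)[names(nodes) == "name"] <- "gene"
    attr(df, "nodes") <- nodes
  }
  df
}

#' Write / read a protein FASTA
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Read a gene-set file (one id per line)
#'
#' @param file path; an empty file yields an empty set.
#' @return character vector of ids.
#' @export
read_gene_set <- function(file) {
  x <- readLines(file)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @param ids character vector to write.
#' @export
write_gene_set <- function(ids, file) {
  writeLines(ids, file)
  invisible(file)
}
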