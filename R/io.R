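#' Read and write geo-referenced alignments
#'
#' FASTA I/O goes through ape (DNAbin); the sample table is a plain CSV
#' with columns id, locality, lat, lon and an optional lineage column.
#'
#' @param fasta path to an aligned FASTA file.
#' @param csv path to the sample CSV.
#' @return a [geo_alignment()].
#' @export
read_geo_alignment <- function(fasta, csv) {
  dna <- ape::read.FASTA(fasta)
  m <- toupper(as.character(as.matrix(dna)))
  samples <- utils::read.csv(csv, stringsAsFactors = FALSE)
  geo_alignment(m, samples)
}

#' @rdname read_geo_alignment
#' @param geoaln a [geo_alignment()] to write.
#' @export
write_geo_alignment <- function(geoaln, fasta, csv) {
  dna <- ape::as.DNAbin(tolower(geoaln$seq))
  ape::write.FASTA(dna, fasta)
  utils::write.csv(geoaln$samples, csv, row.names = FALSE)
  invisible(list(fasta = fasta, csv = csv))
}

#' Write a distance matrix as square CSV or PHYLIP-style text
#'
#' @param D symmetric labelled matrix.
#' @param path output path.
#' @param format "csv" (default) or "phylip".
#' @export
write_distance_matrix <- function(D, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(D, path)
  } else {
    lines <- c(sprintf("%d", nrow(D)),
               vapply(seq_len(nrow(D)), function(i)
                 paste(formatC(rownames(D)[i], width = -10),
                       paste(sprintf("%.6f", D[i, ]), collapse = " ")),
                 character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a parsimony network set as an edge list and GraphML
#'
#' @param net a `parsimony_networks` object.
#' @param edge_csv path for the edge-list CSV.
#' @param graphml optional path for GraphML-compatible XML.
#' @export
write_network <- function(net, edge_csv, graphml = NULL) {
  utils::write.csv(net$edges, edge_csv, row.names = FALSE)
  if (!is.null(graphml)) {
    nodes <- sprintf('    <node id="h%d"/>', net$nodes$haplotype)
    edges <- if (nrow(net$edges)) sprintf(
      '    <edge source="h%d" target="h%d"><data key="steps">%d</data></edge>',
      net$edges$h1, net$edges$h2, net$edges$steps) else character(0)
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="steps" for="edge" attr.name="steps" attr.type="int"/>',
      '  <graph edgedefault="undirected">',
      nodes, edges,
      "  </graph>", "</graphml>"), graphml)
  }
  invisible(edge_csv)
}
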