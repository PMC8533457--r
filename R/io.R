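#' Read an expression matrix from TSV
#'
#' The canonical on-disk matrix format is tab-separated text with a header row
#' of sample ids and a first column of feature ids — the layout of a GEO-style
#' series matrix, without any binary dependency. Row and column order are
#' preserved exactly as found in the file.
#'
#' @param path Path to the expression TSV (header = sample ids, first column =
#'   feature ids).
#' @param phenotype_path Optional path to a phenotype TSV with columns
#'   `sample_id` and `group` (values `case`/`control`).
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, phenotype_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a feature-id column plus at least one sample: ", path)
  fid <- df[[1L]]
  sid <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value at feature '%s', sample '%s' in %s",
                 fid[bad[1L, 1L]], sid[bad[1L, 2L]], path))
  }
  dimnames(vals) <- list(fid, sid)
  phenotype <- NULL
  if (!is.null(phenotype_path)) {
    phenotype <- read_phenotype(phenotype_path)
  }
  expression_matrix(vals, phenotype = phenotype)
}

#' Write an expression matrix to TSV
#'
#' Values are serialized at 8 significant digits so that write/read round
#' trips reproduce the matrix to well below 1e-6 on the log2-intensity scale.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param phenotype_path Optional path for a companion phenotype TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, phenotype_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  lines <- c(
    paste(c("feature_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], formatC(v[i, ], digits = 8, format = "g")),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  if (!is.null(phenotype_path)) {
    if (is.null(x$phenotype)) stop("matrix has no phenotype to write")
    write_phenotype(x$phenotype, phenotype_path)
  }
  invisible(path)
}

#' Read phenotype labels from TSV
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Named character vector, sample id -> group.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df))) {
    stop("phenotype TSV must have columns sample_id and group: ", path)
  }
  stats::setNames(df$group, df$sample_id)
}

#' Write phenotype labels to TSV
#' @param phenotype Named character vector, sample id -> group.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  writeLines(c("sample_id\tgroup",
               paste(names(phenotype), phenotype, sep = "\t")), path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene...`.
#' Duplicate genes within a line are dropped keeping the first occurrence;
#' empty lines are skipped. Gene symbols are treated case-sensitively
#' throughout the package to avoid silent collisions.
#'
#' @param path Path to a GMT file.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  descriptions <- character()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields", i, path))
    nm <- f[1L]
    if (nm %in% names(sets)) stop(sprintf("duplicate gene-set name '%s' at line %d", nm, i))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("empty gene set '%s' at line %d", nm, i))
    sets[[nm]] <- genes
    descriptions[nm] <- f[2L]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' Read a transcription-factor list
#'
#' One gene symbol per line; blank lines ignored; duplicates removed keeping
#' first occurrence.
#'
#' @param path Path to text file.
#' @return Character vector of TF symbols.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a probe-to-gene map from TSV
#'
#' @param path TSV with columns `probe_id` and `gene_symbol`.
#' @return Named character vector, probe id -> gene symbol.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% colnames(df))) {
    stop("probe map TSV must have columns probe_id and gene_symbol: ", path)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("probe map assigns a probe to more than one gene: ",
         df$probe_id[duplicated(df$probe_id)][1L])
  }
  stats::setNames(df$gene_symbol, df$probe_id)
}

#' Write a probe-to-gene map to TSV
#' @param map Named character vector, probe id -> gene symbol.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(map, path) {
  writeLines(c("probe_id\tgene_symbol",
               paste(names(map), map, sep = "\t")), path)
  invisible(path)
}

#' Write a regulatory network as an edge-list TSV
#'
#' Columns: `tf`, `target`, `mode` (+1/-1), `mi`, `pvalue`, `adjusted_p`.
#' Mutual information and p-values are written with 8 decimal places so round
#' trips are exact at that precision. All edges are written: regulons at or
#' above the minimum size, smaller regulons, and TF-TF edges (the latter with
#' their recorded mode).
#'
#' @param network A `RegulatoryNetwork` (see [build_regulons()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  ed <- network_edges(network)
  lines <- c("tf\ttarget\tmode\tmi\tpvalue\tadjusted_p",
             sprintf("%s\t%s\t%+d\t%.8f\t%.8f\t%.8f",
                     ed$tf, ed$target, ed$mode, ed$mi, ed$p, ed$adj_p))
  writeLines(lines, path)
  invisible(path)
}

# Flatten a RegulatoryNetwork into one edge data.frame (all regulons + TF-TF).
network_edges <- function(network) {
  parts <- lapply(names(network$all_regulons), function(tf) {
    r <- network$all_regulons[[tf]]
    if (!nrow(r)) return(NULL)
    data.frame(tf = tf, target = r$target, mode = r$mode, mi = r$mi,
               p = r$p, adj_p = r$adj_p, stringsAsFactors = FALSE)
  })
  tt <- network$tf_tf_edges
  if (!is.null(tt) && nrow(tt)) parts <- c(parts, list(tt))
  out <- do.call(rbind, parts)
  if (is.null(out)) stop("network has no edges")
  rownames(out) <- NULL
  out
}

#' Read a regulatory network from an edge-list TSV
#'
#' Inverse of [write_network()]. TF-TF edges (rows whose target is itself a
#' TF in the file) are stored separately from regulon targets, mirroring the
#' in-memory layout. Stage parameters are not serialized in the edge list.
#'
#' @param path Edge-list TSV path.
#' @param min_regulon_size Minimum number of (non-TF) targets for a regulon
#'   to enter the main regulon map; smaller regulons are kept in
#'   `all_regulons`.
#' @return A `RegulatoryNetwork`.
#' @export
read_network <- function(path, min_regulon_size = 15L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("tf", "target", "mode", "mi", "pvalue", "adjusted_p")
  if (!all(need %in% colnames(df))) {
    stop("network TSV must have columns ", paste(need, collapse = ", "))
  }
  if (!all(df$mode %in% c(-1L, 1L))) {
    stop("unknown mode value in network file (must be +1 or -1): ",
         df$mode[!df$mode %in% c(-1L, 1L)][1L])
  }
  edges <- data.frame(tf = as.character(df$tf), target = as.character(df$target),
                      mode = as.integer(df$mode), mi = df$mi,
                      p = df$pvalue, adj_p = df$adjusted_p,
                      stringsAsFactors = FALSE)
  assemble_network(edges, universe = union(edges$tf, edges$target),
                   min_regulon_size = min_regulon_size, params = list())
}

#' Export the regulon-overlap graph as GraphML
#'
#' Nodes are regulons (labeled by TF); an edge connects two regulons that
#' share at least `min_shared` target genes, weighted by the shared-target
#' count and annotated with the Jaccard index — the association-map view of
#' the network, where edge width reflects mutual regulation of genes by two
#' TFs.
#'
#' @param network A `RegulatoryNetwork`.
#' @param path Output GraphML path.
#' @param min_shared Minimum shared-target count for an edge (default 1).
#' @return `path`, invisibly.
#' @export
write_overlap_graphml <- function(network, path, min_shared = 1L) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  sim <- regulon_similarity(network)
  sim <- sim[sim$shared >= min_shared, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = sim$tf1, to = sim$tf2,
                   weight = sim$shared, jaccard = sim$jaccard),
    directed = FALSE,
    vertices = data.frame(
      name = names(network$regulons),
      regulon_size = vapply(network$regulons, nrow, integer(1))
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
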