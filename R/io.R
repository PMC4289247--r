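#' Read a co-association edge list
#'
#' Tab-separated columns `gene_a  gene_b  sign`; the sign column is optional
#' and defaults to +1. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Data frame `from`, `to`, `sign`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least two columns: ", path)
  out <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                    sign = if (ncol(df) >= 3L) as.integer(df[[3]]) else 1L,
                    stringsAsFactors = FALSE)
  out
}

#' Write a layer's edge list as TSV
#' @param net A `species_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(
    data.frame(gene_a = net$edges$from, gene_b = net$edges$to,
               sign = net$edges$sign),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog pair table
#'
#' Tab-separated columns `species_a  gene_a  species_b  gene_b`.
#'
#' @param path File path.
#' @return Data frame with those four columns.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("ortholog table needs four columns: ", path)
  stats::setNames(df[1:4], c("species_a", "gene_a", "species_b", "gene_b"))
}

#' Dump a multi-layer network to a directory
#'
#' Writes a JSON manifest (species, node/edge counts, weight scheme), one
#' edge TSV per layer, the ortholog pair table with weights, and the global
#' node index.
#'
#' @param mln A `multilayer_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_multilayer <- function(mln, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    species = lapply(mln$layers, function(l)
      list(id = l$species_id, n_genes = length(l$nodes), n_edges = nrow(l$edges))),
    weight_scheme = mln$scheme, M = mln$M,
    n_triplets = nrow(mln$triplets))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (l in mln$layers)
    write_edge_list(l, file.path(dir, paste0("edges_", l$species_id, ".tsv")))
  orth <- do.call(rbind, lapply(names(mln$orthologies), function(nm) {
    om <- mln$orthologies[[nm]]
    data.frame(species_a = om$species_a, gene_a = om$pairs$gene_a,
               species_b = om$species_b, gene_b = om$pairs$gene_b,
               weight = om$pairs$weight)
  }))
  if (!is.null(orth))
    utils::write.table(orth, file.path(dir, "orthologs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(mln$node_index, file.path(dir, "node_index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a multi-layer network dump written by [write_multilayer()]
#' @param dir Directory containing the dump.
#' @return A `multilayer_network`.
#' @export
read_multilayer <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  idx <- utils::read.delim(file.path(dir, "node_index.tsv"),
                           stringsAsFactors = FALSE)
  layers <- lapply(manifest$species, function(sp) {
    e <- read_edge_list(file.path(dir, paste0("edges_", sp$id, ".tsv")))
    species_network(sp$id, idx$gene[idx$species == sp$id], e)
  })
  opath <- file.path(dir, "orthologs.tsv")
  ot <- NULL
  if (file.exists(opath)) {
    o <- utils::read.delim(opath, stringsAsFactors = FALSE)
    ot <- o[c("species_a", "gene_a", "species_b", "gene_b")]
  }
  build_multilayer(layers, ot, detect_triplets = TRUE,
                   scheme = manifest$weight_scheme)
}

#' Read an expression matrix (genes x conditions TSV)
#'
#' First column = gene id, remaining columns numeric expression values.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  m
}

#' Read gene sets in GMT format
#'
#' One set per line: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  do.call(c, out)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "crossclust") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-to-GO-term annotations from a GAF 2.x file
#'
#' Comment lines start with `!`. The gene identifier is taken from column 2
#' (`DB Object ID`) or column 3 (`DB Object Symbol`); the term from column 5.
#' No propagation to ancestor terms is performed.
#'
#' @param path File path.
#' @param id_column 2 or 3, which column holds the gene identifier.
#' @return Binary gene x term incidence matrix.
#' @export
read_gaf <- function(path, id_column = 2) {
  stopifnot(id_column %in% c(2, 3))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("no annotation rows in ", path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(f, `[`, "", id_column)
  terms <- vapply(f, `[`, "", 5L)
  go_annotation_matrix(data.frame(gene = genes, term = terms,
                                  stringsAsFactors = FALSE))
}

#' Build a binary gene-by-term annotation matrix
#' @param ann Data frame with columns `gene`, `term`.
#' @return 0/1 matrix, genes in rows, terms in columns.
#' @export
go_annotation_matrix <- function(ann) {
  ann <- unique(ann[c("gene", "term")])
  g <- factor(ann$gene); t <- factor(ann$term)
  B <- matrix(0L, nlevels(g), nlevels(t),
              dimnames = list(levels(g), levels(t)))
  B[cbind(as.integer(g), as.integer(t))] <- 1L
  B
}

#' Write a co-appearance matrix as sparse Matrix Market plus node index
#'
#' The upper triangle (including the unit diagonal) is written as a
#' coordinate MTX file; the node index TSV maps matrix rows to genes.
#'
#' @param coap A `coappearance_matrix`.
#' @param mtx_path Output `.mtx` path.
#' @param index_path Output node index TSV path.
#' @export
write_coappearance <- function(coap, mtx_path, index_path) {
  v <- coap$values
  v[lower.tri(v)] <- 0
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(v, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  mtx_path)
  utils::write.table(coap$node_index, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mtx_path)
}

#' Write a module set as TSV (`gene  species  module_id  tag`)
#' @param modules A `module_set` (tags optional, see [classify_modules()]).
#' @param mln The `multilayer_network` the modules refer to.
#' @param path Output path.
#' @param tags Optional named character vector of per-module tags.
#' @export
write_modules <- function(modules, mln, path, tags = NULL) {
  rows <- do.call(rbind, lapply(names(modules$modules), function(id) {
    idx <- modules$modules[[id]]
    data.frame(gene = mln$node_index$gene[idx],
               species = mln$node_index$species[idx],
               module_id = id,
               tag = if (is.null(tags)) NA_character_ else unname(tags[id]))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
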