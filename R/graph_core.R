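#' Construct a species co-association network layer
#'
#' A layer holds one species' undirected co-association graph. Edges carry a
#' sign (+1 for positive association, -1 for negative); unsigned inputs
#' default to +1. Self-loops are rejected and duplicate edges collapsed.
#'
#' @param species_id Single string naming the species.
#' @param nodes Character vector of gene identifiers (order defines the
#'   within-layer node order used for the global index).
#' @param edges Data frame with columns `from`, `to` and optionally `sign`
#'   (+1/-1, default +1). May have zero rows.
#' @return An object of class `species_network` with elements `species_id`,
#'   `nodes`, and `edges` (canonicalized so `from` < `to` in node order).
#' @examples
#' net <- species_network("wrm", c("a", "b", "c"),
#'                        data.frame(from = c("a", "b"), to = c("b", "c")))
#' network_stats(net)$m_pos
#' @export
species_network <- function(species_id, nodes, edges = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("layer '", species_id, "' has no nodes")
  if (anyDuplicated(nodes)) stop("duplicate gene ids in layer '", species_id, "'")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), sign = integer())
  } else {
    edges <- as.data.frame(edges)
    if (is.null(edges$sign)) edges$sign <- 1L
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
    ia <- match(as.character(edges$from), nodes)
    ib <- match(as.character(edges$to), nodes)
    if (anyNA(ia) || anyNA(ib)) {
      bad <- unique(c(edges$from[is.na(ia)], edges$to[is.na(ib)]))
      stop("edge endpoints not declared in layer '", species_id, "': ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (any(ia == ib)) stop("self-loops are not allowed (layer '", species_id, "')")
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    edges <- data.frame(from = nodes[lo], to = nodes[hi], sign = edges$sign,
                        stringsAsFactors = FALSE)
    key <- paste(lo, hi, edges$sign)
    dup <- duplicated(key)
    if (any(dup)) edges <- edges[!dup, , drop = FALSE]
    # same pair with both signs is contradictory input
    pk <- paste(match(edges$from, nodes), match(edges$to, nodes))
    if (anyDuplicated(pk)) stop("edge listed with both signs in layer '", species_id, "'")
    rownames(edges) <- NULL
  }
  structure(list(species_id = species_id, nodes = nodes, edges = edges),
            class = "species_network")
}

#' Degree and edge-count summaries of a layer
#'
#' Computes per-node degrees and total edge counts per sign class. The
#' identity `m = sum(k) / 2` holds within each class.
#'
#' @param net A `species_network`.
#' @return List with named numeric vectors `k_pos`, `k_neg` (degree per node)
#'   and counts `m_pos`, `m_neg`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "species_network"))
  k <- function(sgn) {
    e <- net$edges[net$edges$sign == sgn, , drop = FALSE]
    tab <- table(factor(c(e$from, e$to), levels = net$nodes))
    stats::setNames(as.numeric(tab), net$nodes)
  }
  kp <- k(1L); kn <- k(-1L)
  list(k_pos = kp, k_neg = kn, m_pos = sum(kp) / 2, m_neg = sum(kn) / 2)
}

#' Derive orthology-link weights from raw cross-species gene pairs
#'
#' Many-to-many orthology forms bipartite cliques that would otherwise
#' dominate the coupling term, so each pair is down-weighted by the ortholog
#' counts of its endpoints. With `a` = number of orthologs of gene i in the
#' partner species and `b` = number of orthologs of gene j in i's species,
#' the default weight is the symmetric mean of reciprocals
#' `w = (1/a + 1/b) / 2`; one-to-one pairs get weight exactly 1. Alternative
#' schemes `"recip_product"` (`1/(a*b)`) and `"recip_geom"` (`1/sqrt(a*b)`)
#' are available, as is `"uniform"` (all weights 1) to reproduce the
#' unweighted behaviour in which large cliques collapse into one module.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` (one row per
#'   orthologous pair). Duplicates are dropped with a warning.
#' @param species_pair Character vector of length 2 naming the two species.
#' @param scheme Weighting scheme; see Details.
#' @return An `orthology_map`: list with `species_a`, `species_b`, `pairs`
#'   (data frame `gene_a`, `gene_b`, `weight`).
#' @examples
#' p <- data.frame(gene_a = c("x", "x"), gene_b = c("u", "v"))
#' compute_ortholog_weights(p, c("s1", "s2"))$pairs$weight  # 0.75 0.75
#' @export
compute_ortholog_weights <- function(pairs, species_pair = c("A", "B"),
                                     scheme = c("mean_recip", "recip_product",
                                                "recip_geom", "uniform")) {
  scheme <- match.arg(scheme)
  pairs <- as.data.frame(pairs)
  stopifnot(nrow(pairs) > 0L, all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  dup <- duplicated(paste(pairs$gene_a, pairs$gene_b, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate ortholog pair(s) removed")
    pairs <- pairs[!dup, , drop = FALSE]
  }
  a <- as.numeric(table(pairs$gene_a)[pairs$gene_a])  # orthologs of gene_a
  b <- as.numeric(table(pairs$gene_b)[pairs$gene_b])  # orthologs of gene_b
  w <- switch(scheme,
              mean_recip    = (1 / a + 1 / b) / 2,
              recip_product = 1 / (a * b),
              recip_geom    = 1 / sqrt(a * b),
              uniform       = rep(1, length(a)))
  structure(list(species_a = species_pair[1], species_b = species_pair[2],
                 pairs = data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                                    weight = w, stringsAsFactors = FALSE)),
            class = "orthology_map")
}

#' Assemble a multi-layer network from layers and ortholog tables
#'
#' Layers are concatenated in the declared order (nodes in input order) to
#' form the global node index. Ortholog pairs referencing genes absent from
#' their layer are dropped with a warning reporting the count. When
#' `detect_triplets = TRUE` and at least three layers are given, 1-1-1
#' ortholog triplets (three genes, one per species, pairwise one-to-one with
#' no other partner) are enumerated for every species triple.
#'
#' @param layers List of `species_network` objects with unique species ids.
#' @param ortholog_table Data frame with columns `species_a`, `gene_a`,
#'   `species_b`, `gene_b`, or `NULL` for no coupling.
#' @param detect_triplets Enumerate 1-1-1 triplets across species triples.
#' @param scheme Ortholog weighting scheme passed to
#'   [compute_ortholog_weights()].
#' @return A `multilayer_network`: `layers`, `orthologies` (list of
#'   `orthology_map` keyed `"spA|spB"`, with resolved global indices
#'   `idx_a`, `idx_b`), `triplets` (data frame of global indices, possibly
#'   empty), `node_index` (data frame `node`, `species`, `gene`), and `M`.
#' @export
build_multilayer <- function(layers, ortholog_table = NULL,
                             detect_triplets = FALSE,
                             scheme = "mean_recip") {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "species_network")))
  ids <- vapply(layers, `[[`, "", "species_id")
  if (anyDuplicated(ids)) stop("duplicate species_id: ", ids[duplicated(ids)][1])
  names(layers) <- ids
  node_index <- do.call(rbind, lapply(layers, function(l)
    data.frame(species = l$species_id, gene = l$nodes, stringsAsFactors = FALSE)))
  node_index <- data.frame(node = seq_len(nrow(node_index)), node_index,
                           row.names = NULL)
  key <- paste(node_index$species, node_index$gene, sep = "\r")

  orthologies <- list()
  if (!is.null(ortholog_table) && nrow(ortholog_table) > 0L) {
    ot <- as.data.frame(ortholog_table)
    stopifnot(all(c("species_a", "gene_a", "species_b", "gene_b") %in% names(ot)))
    unknown_sp <- setdiff(unique(c(ot$species_a, ot$species_b)), ids)
    if (length(unknown_sp))
      stop("ortholog table references undeclared species: ",
           paste(unknown_sp, collapse = ", "))
    # canonical orientation: species in layer order
    ord <- match(ot$species_a, ids) > match(ot$species_b, ids)
    ot[ord, c("species_a", "gene_a", "species_b", "gene_b")] <-
      ot[ord, c("species_b", "gene_b", "species_a", "gene_a")]
    ia <- match(paste(ot$species_a, ot$gene_a, sep = "\r"), key)
    ib <- match(paste(ot$species_b, ot$gene_b, sep = "\r"), key)
    bad <- is.na(ia) | is.na(ib)
    if (any(bad)) {
      warning(sum(bad), " ortholog pair(s) reference unknown genes; dropped")
      ot <- ot[!bad, , drop = FALSE]; ia <- ia[!bad]; ib <- ib[!bad]
    }
    for (pk in unique(paste(ot$species_a, ot$species_b, sep = "|"))) {
      sel <- paste(ot$species_a, ot$species_b, sep = "|") == pk
      sp <- strsplit(pk, "|", fixed = TRUE)[[1]]
      om <- compute_ortholog_weights(
        data.frame(gene_a = ot$gene_a[sel], gene_b = ot$gene_b[sel]),
        species_pair = sp, scheme = scheme)
      om$pairs$idx_a <- match(paste(sp[1], om$pairs$gene_a, sep = "\r"), key)
      om$pairs$idx_b <- match(paste(sp[2], om$pairs$gene_b, sep = "\r"), key)
      orthologies[[pk]] <- om
    }
  }

  triplets <- data.frame(i = integer(), j = integer(), k = integer())
  if (detect_triplets && length(layers) >= 3L && length(orthologies) >= 3L)
    triplets <- find_triplets(orthologies, ids)

  structure(list(layers = layers, orthologies = orthologies,
                 triplets = triplets, node_index = node_index,
                 M = nrow(node_index), scheme = scheme),
            class = "multilayer_network")
}

# One-to-one pairs of an orthology map: both endpoints appear exactly once.
one_to_one_pairs <- function(om) {
  p <- om$pairs
  p[p$gene_a %in% names(which(table(p$gene_a) == 1L)) &
      p$gene_b %in% names(which(table(p$gene_b) == 1L)), , drop = FALSE]
}

# Enumerate 1-1-1 triplets (global node indices) across all species triples.
find_triplets <- function(orthologies, species_ids) {
  out <- list()
  combs <- utils::combn(species_ids, 3, simplify = FALSE)
  for (tri in combs) {
    k12 <- paste(tri[1], tri[2], sep = "|")
    k13 <- paste(tri[1], tri[3], sep = "|")
    k23 <- paste(tri[2], tri[3], sep = "|")
    if (!all(c(k12, k13, k23) %in% names(orthologies))) next
    p12 <- one_to_one_pairs(orthologies[[k12]])
    p13 <- one_to_one_pairs(orthologies[[k13]])
    p23 <- one_to_one_pairs(orthologies[[k23]])
    if (!nrow(p12) || !nrow(p13) || !nrow(p23)) next
    a12 <- data.frame(g1 = p12$gene_a, g2 = p12$gene_b,
                      i1 = p12$idx_a, i2 = p12$idx_b)
    a13 <- data.frame(g1 = p13$gene_a, g3 = p13$gene_b, i3 = p13$idx_b)
    a23 <- data.frame(g2 = p23$gene_a, g3 = p23$gene_b)
    m <- merge(a12, a13, by = "g1")
    if (!nrow(m)) next
    hit <- merge(m, a23, by = c("g2", "g3"))
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.frame(i = hit$i1, j = hit$i2, k = hit$i3)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), k = integer()))
  res <- do.call(rbind, out)
  res[order(res$i, res$j, res$k), , drop = FALSE]
}

#' Create a node labeling
#'
#' A labeling assigns every node of a multi-layer network a label in `1..q`
#' (a Potts spin configuration).
#'
#' @param sigma Integer vector over the global node index.
#' @param q Number of allowed labels.
#' @return Integer vector of class `labeling` with attribute `q`.
#' @export
labeling <- function(sigma, q) {
  sigma <- as.integer(sigma)
  q <- as.integer(q)
  stopifnot(q >= 1L, !anyNA(sigma), all(sigma >= 1L), all(sigma <= q))
  structure(sigma, q = q, class = "labeling")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("multilayer_network:", length(x$layers), "layers,", x$M, "nodes\n")
  for (l in x$layers)
    cat("  layer", l$species_id, ":", length(l$nodes), "genes,",
        nrow(l$edges), "edges\n")
  for (nm in names(x$orthologies))
    cat("  orthology", nm, ":", nrow(x$orthologies[[nm]]$pairs), "pairs\n")
  if (nrow(x$triplets)) cat("  1-1-1 triplets:", nrow(x$triplets), "\n")
  invisible(x)
}

#' @export
print.species_network <- function(x, ...) {
  s <- network_stats(x)
  cat("species_network", x$species_id, ":", length(x$nodes), "genes,",
      s$m_pos, "positive /", s$m_neg, "negative edges\n")
  invisible(x)
}
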