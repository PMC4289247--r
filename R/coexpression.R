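#' Pearson correlation matrix of an expression matrix
#'
#' Rows are genes, columns conditions. Values may be log2(x + offset)
#' transformed and per-gene standardized first (Pearson correlation is
#' invariant to standardization; the option is kept so the stored matrix
#' matches the transformed profiles). Genes with any missing value are
#' dropped; zero-variance genes yield `NA` correlations and are excluded by
#' downstream steps.
#'
#' @param expr Numeric gene x condition matrix with rownames.
#' @param log_transform Apply log2(x + offset) first.
#' @param offset Offset for the log transform (default 1).
#' @param standardize Per-gene z-score across conditions.
#' @return Symmetric correlation matrix (diagonal 1; `NA` rows/columns for
#'   zero-variance genes).
#' @export
correlation_matrix <- function(expr, log_transform = FALSE, offset = 1,
                               standardize = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3L) stop("need at least 3 conditions for correlation")
  keep <- !apply(expr, 1L, anyNA)
  if (!all(keep)) {
    message(sum(!keep), " gene(s) with missing values dropped")
    expr <- expr[keep, , drop = FALSE]
  }
  if (log_transform) {
    if (any(expr <= -offset)) stop("values <= -offset; cannot log-transform")
    expr <- log2(expr + offset)
  }
  sds <- apply(expr, 1L, stats::sd)
  if (all(sds == 0)) stop("all genes have constant expression")
  if (standardize) {
    nz <- sds > 0
    expr[nz, ] <- (expr[nz, , drop = FALSE] -
                     rowMeans(expr[nz, , drop = FALSE])) / sds[nz]
  }
  r <- suppressWarnings(stats::cor(t(expr)))
  diag(r) <- 1
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  r
}

#' Rank-based co-expression network
#'
#' Each gene nominates its top `d` partners by absolute correlation; an edge
#' exists if either endpoint nominates the other (symmetric union), signed
#' by the sign of the correlation. Ties at the d-th rank are broken by
#' descending |r| then ascending gene name, so the network is reproducible.
#' Genes with undefined (NA) correlations are excluded.
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param d Number of neighbors each gene nominates (1 <= d < n genes).
#' @param species_id Species id for the resulting layer.
#' @return A `species_network` over the genes of `corr`.
#' @export
rank_network <- function(corr, d, species_id = "S") {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  ok <- rowSums(!is.na(corr)) > 1L  # drop zero-variance (all-NA) genes
  corr <- corr[ok, ok, drop = FALSE]
  genes <- rownames(corr)
  n <- length(genes)
  if (d < 1L || d >= n) stop("d must satisfy 1 <= d < number of genes (", n, ")")
  pick <- lapply(seq_len(n), function(i) {
    r <- corr[i, ]; r[i] <- NA
    ord <- order(-abs(r), genes, na.last = TRUE)
    ord[seq_len(d)]
  })
  from <- rep(seq_len(n), each = d)
  to <- unlist(pick)
  keep <- !is.na(corr[cbind(from, to)])
  from <- from[keep]; to <- to[keep]
  lo <- pmin(from, to); hi <- pmax(from, to)
  dup <- duplicated(cbind(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  sg <- ifelse(corr[cbind(lo, hi)] >= 0, 1L, -1L)
  species_network(species_id, genes,
                  data.frame(from = genes[lo], to = genes[hi], sign = sg))
}

#' Choose the neighbor count d for the rank network
#'
#' Returns the smallest `d <= d_max` at which the rank network forms a
#' single connected component spanning all genes with defined correlations
#' (optionally a component covering at least `coverage` of them). If no d
#' connects the graph, `d_max` is returned with a warning.
#'
#' @param corr Symmetric correlation matrix.
#' @param d_max Largest d to try.
#' @param coverage Fraction of genes the giant component must cover
#'   (default 1: fully connected).
#' @return Integer d.
#' @export
choose_d <- function(corr, d_max, coverage = 1) {
  stopifnot(d_max >= 1L, coverage > 0, coverage <= 1)
  for (d in seq_len(d_max)) {
    net <- rank_network(corr, d)
    g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE,
                                       vertices = net$nodes)
    comp <- igraph::components(g)
    if (max(comp$csize) >= coverage * length(net$nodes)) return(d)
  }
  warning("network not connected at any d <= ", d_max, "; returning d_max")
  d_max
}
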