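#' GO similarity network from a binary annotation matrix
#'
#' Each term column of the gene-by-term incidence matrix B is scaled by its
#' inverse document frequency idf_j = log(n / n_j), where n is the number of
#' genes and n_j the number carrying term j (a term annotating every gene
#' gets weight 0). The similarity of two genes is the cosine of their
#' idf-weighted annotation vectors, giving a weighted gene-by-gene network
#' with values in [0, 1]. Genes with no terms are excluded with a message;
#' genes whose weighted vector is all zero get similarity 0.
#'
#' @param B Binary gene x term matrix (rownames = genes).
#' @return `go_similarity_network`: `W` (symmetric, zero diagonal), `genes`.
#' @export
go_similarity <- function(B) {
  stopifnot(is.matrix(B), all(B %in% c(0, 1)))
  keep <- rowSums(B) > 0
  if (!all(keep)) {
    message(sum(!keep), " gene(s) without GO terms excluded from similarity")
    B <- B[keep, , drop = FALSE]
  }
  n <- nrow(B)
  idf <- log(n / colSums(B))
  idf[!is.finite(idf)] <- 0
  G <- sweep(B, 2L, idf, `*`)
  nrm <- sqrt(rowSums(G^2))
  zero <- nrm == 0
  if (any(zero)) message(sum(zero), " gene(s) with all-zero weighted vectors")
  nrm[zero] <- 1
  Gn <- G / nrm
  W <- tcrossprod(Gn)
  W[zero, ] <- 0; W[, zero] <- 0
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  structure(list(W = W, genes = rownames(B)), class = "go_similarity_network")
}

#' Weighted-network modularity of a module assignment
#'
#' Q_w = (1/2m) * sum_{i,j} [W_ij - k_i k_j/(2m)] delta(module_i, module_j)
#' with k_i = sum_j W_ij and m = sum_i k_i / 2; the same degree-product null
#' as the layer modularity, applied to an arbitrary weighted network (here
#' typically the GO similarity benchmark). Genes not assigned to any module
#' contribute no co-labeled pairs.
#'
#' @param gsn A `go_similarity_network` (or list with `W`, `genes`).
#' @param labels Named vector of module labels over (a subset of) the genes;
#'   genes absent or NA count as unassigned. A `module_set` is accepted and
#'   resolved via its node index gene names.
#' @return Numeric Q_w.
#' @export
weighted_modularity <- function(gsn, labels) {
  W <- gsn$W
  genes <- gsn$genes
  if (inherits(labels, "module_set")) {
    ms <- labels
    labels <- stats::setNames(rep(NA_character_, length(genes)), genes)
    for (id in names(ms$modules)) {
      g <- ms$node_index$gene[ms$modules[[id]]]
      labels[intersect(g, genes)] <- id
    }
  }
  lab <- labels[genes]
  k <- rowSums(W)
  m <- sum(k) / 2
  if (m == 0) stop("similarity network has no weight (m = 0)")
  assigned <- !is.na(lab)
  Q <- 0
  for (lv in unique(lab[assigned])) {
    sel <- which(assigned & lab == lv)
    Q <- Q + sum(W[sel, sel]) - (sum(k[sel]) / (2 * m))^2 * 2 * m
  }
  Q / (2 * m)
}

#' Fraction of metagenes recovered intact by a module set
#'
#' A metagene (cross-species group of genes expected to co-cluster) counts
#' as recovered when all of its members that resolve against the network lie
#' in a single module. Unresolvable members are dropped with a message
#' (strict mode fails the metagene instead); metagenes with fewer than two
#' resolvable members are skipped.
#'
#' @param modules A `module_set`.
#' @param metagenes Named list of gene identifier vectors (e.g. from
#'   [read_gmt()]).
#' @param strict Fail a metagene containing unresolvable members.
#' @return Fraction in [0, 1].
#' @export
metagene_recovery <- function(modules, metagenes, strict = FALSE) {
  if (!length(metagenes)) stop("empty metagene set")
  gene_of <- modules$node_index$gene
  module_of <- rep(NA_character_, length(gene_of))
  for (id in names(modules$modules))
    module_of[modules$modules[[id]]] <- id
  n_drop <- 0L
  verdict <- vapply(metagenes, function(members) {
    hit <- match(members, gene_of)
    missing <- is.na(hit)
    if (any(missing)) {
      n_drop <<- n_drop + sum(missing)
      if (strict) return(FALSE)
      hit <- hit[!missing]
    }
    if (length(hit) < 2L) return(NA)
    mods <- module_of[hit]
    !anyNA(mods) && length(unique(mods)) == 1L
  }, NA)
  if (n_drop) message(n_drop, " metagene member(s) not in the network")
  verdict <- verdict[!is.na(verdict)]
  if (!length(verdict)) stop("no metagene with >= 2 resolvable members")
  mean(verdict)
}

#' Ortholog enrichment between a pair of single-species modules
#'
#' Compares the observed number of orthologous pairs spanning the two
#' modules with the expectation O_wf * (n_w/N_w) * (n_f/N_f) under random
#' gene membership, and computes an upper-tail hypergeometric p-value
#' drawing n_w * n_f candidate cross pairs from the N_w * N_f total pairs of
#' which O_wf are orthologous.
#'
#' @param module_a,module_b Global node-index vectors (one per species).
#' @param orthology An `orthology_map` with resolved indices.
#' @param totals List/vector with `N_a`, `N_b` (genome sizes) and `O`
#'   (total ortholog pairs between the species).
#' @return List `observed`, `expected`, `fold` (NA when expected is 0),
#'   `p_value`.
#' @export
ortholog_enrichment <- function(module_a, module_b, orthology, totals) {
  p <- orthology$pairs
  obs <- sum(p$idx_a %in% module_a & p$idx_b %in% module_b)
  n_a <- length(module_a); n_b <- length(module_b)
  N_a <- totals[["N_a"]]; N_b <- totals[["N_b"]]; O <- totals[["O"]]
  expected <- O * (n_a / N_a) * (n_b / N_b)
  if (expected == 0)
    return(list(observed = obs, expected = 0, fold = NA_real_, p_value = NA_real_))
  pval <- stats::phyper(obs - 1, O, N_a * N_b - O, n_a * n_b,
                        lower.tail = FALSE)
  list(observed = obs, expected = expected, fold = obs / expected,
       p_value = pval)
}

# Numeric keys of all within-module node pairs of a clustering.
coassigned_pairs <- function(groups, base) {
  out <- lapply(groups, function(g) {
    g <- sort(as.numeric(g))
    if (length(g) < 2L) return(numeric(0))
    cmb <- utils::combn(g, 2L)
    cmb[1, ] * base + cmb[2, ]
  })
  unique(unlist(out))
}

#' Pairwise overlap between two clusterings
#'
#' Over all node pairs co-assigned by at least one clustering: I = pairs
#' co-assigned by both, II = by A only, III = by B only; the overlap is
#' I / (I + II + III). Pairs separated by both sides (the overwhelming
#' majority) are excluded by construction. Two all-singleton clusterings
#' have overlap 1.
#'
#' @param A,B `module_set` objects or lists of node-id vectors.
#' @return Numeric in [0, 1].
#' @export
clustering_overlap <- function(A, B) {
  ga <- if (inherits(A, "module_set")) A$modules else A
  gb <- if (inherits(B, "module_set")) B$modules else B
  universe <- unique(c(unlist(ga), unlist(gb)))
  ga <- lapply(ga, match, table = universe)
  gb <- lapply(gb, match, table = universe)
  base <- length(universe) + 1
  pa <- coassigned_pairs(ga, base)
  pb <- coassigned_pairs(gb, base)
  if (!length(pa) && !length(pb)) return(1)
  I <- length(intersect(pa, pb))
  I / (I + (length(pa) - I) + (length(pb) - I))
}

#' Scan the coupling constant and report the accuracy trade-off
#'
#' For each kappa the full pipeline is run (ensemble annealing, consensus,
#' module extraction); the report holds each layer's modularity at the
#' consensus partition, the metagene recovery fraction, and the weighted
#' modularity of the GO benchmark network when those benchmarks are
#' supplied. The recommended kappa maximizes the GO-network modularity when
#' available; otherwise the knee of the recovery-versus-layer-modularity
#' trade-off (the kappa maximizing recovery + mean layer modularity) is
#' used.
#'
#' @param mln A `multilayer_network`.
#' @param kappa_grid Numeric vector of coupling constants.
#' @param q,schedule,R Passed to [run_ensemble()].
#' @param params_base Base [cost_params()]; kappa is overridden per grid
#'   point.
#' @param metagenes Optional metagene list for [metagene_recovery()].
#' @param go_network Optional `go_similarity_network` benchmark.
#' @param threshold,min_size Consensus extraction settings.
#' @return List: `report` (data frame, one row per kappa), `recommended`,
#'   `modules` (module sets per kappa).
#' @export
kappa_scan <- function(mln, kappa_grid, q = 50L, schedule = anneal_schedule(),
                       R = 16L, params_base = cost_params(),
                       metagenes = NULL, go_network = NULL,
                       threshold = 0.95, min_size = 5L) {
  stopifnot(length(kappa_grid) >= 1L)
  layer_ids <- vapply(mln$layers, `[[`, "", "species_id")
  rows <- list(); mods <- list()
  for (kap in kappa_grid) {
    params <- params_base
    params$kappa <- kap
    params$kappa_triplet <- kap
    ens <- run_ensemble(mln, params, q, schedule, R)
    coap <- coappearance(ens, mln)
    ms <- extract_modules(coap, threshold, min_size)
    sigma <- modules_to_labeling(ms, mln$M)
    layer_q <- vapply(mln$layers, function(l)
      modularity_term(l, layer_sigma(mln, l$species_id, sigma),
                      params$lambda), 0)
    row <- data.frame(kappa = kap, n_modules = length(ms$modules),
                      t(stats::setNames(layer_q, paste0("Q_", layer_ids))))
    row$metagene_recovery <- if (is.null(metagenes)) NA_real_
      else metagene_recovery(ms, metagenes)
    row$go_modularity <- if (is.null(go_network)) NA_real_
      else weighted_modularity(go_network, ms)
    rows[[length(rows) + 1L]] <- row
    mods[[as.character(kap)]] <- ms
  }
  report <- do.call(rbind, rows)
  recommended <- if (!is.null(go_network)) {
    report$kappa[which.max(report$go_modularity)]
  } else {
    score <- rowMeans(report[, paste0("Q_", layer_ids), drop = FALSE])
    if (!is.null(metagenes)) score <- score + report$metagene_recovery
    report$kappa[which.max(score)]
  }
  list(report = report, recommended = recommended, modules = mods)
}

#' Shared-regulator coherence of a module set
#'
#' Tests whether within-module gene pairs share more regulators than
#' between-module pairs. The statistic is the ratio of the mean
#' shared-regulator count over within-module pairs to the mean over
#' between-module pairs; the null distribution comes from shuffles of the
#' module labels preserving module sizes, and the p-value is the fraction of
#' null statistics at least as large as the observed one (with the +1
#' correction).
#'
#' @param reg_edges Data frame `regulator`, `target` (gene ids).
#' @param modules A `module_set`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List `fold`, `p_value`, `n_within`, `n_between`.
#' @export
regulatory_coherence <- function(reg_edges, modules, n_perm = 1000L,
                                 seed = 1L) {
  genes <- modules$node_index$gene
  lab <- rep(NA_integer_, length(genes))
  for (i in seq_along(modules$modules)) lab[modules$modules[[i]]] <- i
  sel <- which(!is.na(lab))
  if (length(sel) < 2L) stop("fewer than two genes assigned to modules")
  genes <- genes[sel]; lab <- lab[sel]
  regs <- factor(reg_edges$regulator)
  tgt <- match(as.character(reg_edges$target), genes)
  inc <- matrix(0, length(genes), nlevels(regs))
  ok <- !is.na(tgt)
  inc[cbind(tgt[ok], as.integer(regs)[ok])] <- 1
  S <- tcrossprod(inc)           # shared-regulator counts per gene pair
  ut <- upper.tri(S)
  stat <- function(l) {
    same <- outer(l, l, "==")[ut]
    nw <- sum(same); nb <- sum(!same)
    if (nw == 0L || nb == 0L) return(NA_real_)
    mean(S[ut][same]) / mean(S[ut][!same])
  }
  obs <- stat(lab)
  if (is.na(obs)) stop("need both within- and between-module pairs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(lab)), 0)
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= obs)) / (1 + length(null))
  ut_same <- outer(lab, lab, "==")[ut]
  list(fold = obs, p_value = p,
       n_within = sum(ut_same), n_between = sum(!ut_same))
}

# Save/restore the global RNG state so evaluation helpers with their own
# seeds do not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Map ncRNAs to modules by expression correlation
#'
#' For each ncRNA, Pearson correlations to all protein-coding genes are
#' computed; a null distribution is built by shuffling the ncRNA's condition
#' values `n_shuffles` times, correlating each shuffled profile with all
#' coding genes, and pooling the values. The neighbor threshold is the
#' smallest correlation at which the estimated false discovery rate (ratio
#' of null to observed tail fractions) drops below `fdr`; the resulting
#' neighbor set is tested for enrichment in every module with an upper-tail
#' hypergeometric test and the ncRNA is mapped to modules with p < `p_map`
#' (possibly several, possibly none).
#'
#' @param ncrna_expr ncRNA x condition matrix.
#' @param coding_expr Coding-gene x condition matrix over the same
#'   conditions.
#' @param modules A `module_set` whose node-index gene names match
#'   `rownames(coding_expr)`.
#' @param n_shuffles Number of condition shuffles for the null (>= 1).
#' @param fdr Neighbor false discovery rate (default 5%).
#' @param p_map Module mapping p-value cutoff (default 0.01).
#' @param p_adjust `"none"` (default; the mapping threshold is a raw
#'   p-value) or `"BH"` to Benjamini-Hochberg-adjust the per-module
#'   p-values of each ncRNA before thresholding.
#' @param seed Integer seed for the shuffles.
#' @return Data frame `ncrna`, `module_id`, `p_value`, `n_neighbors`,
#'   `threshold`; zero rows when nothing maps.
#' @export
map_ncrna <- function(ncrna_expr, coding_expr, modules, n_shuffles = 10L,
                      fdr = 0.05, p_map = 0.01,
                      p_adjust = c("none", "BH"), seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (ncol(ncrna_expr) != ncol(coding_expr))
    stop("ncRNA and coding matrices must share condition columns")
  genes <- rownames(coding_expr)
  module_genes <- lapply(modules$modules, function(idx)
    intersect(modules$node_index$gene[idx], genes))
  G <- length(genes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tc <- t(coding_expr)
  out <- list()
  for (r in rownames(ncrna_expr)) {
    x <- ncrna_expr[r, ]
    if (stats::sd(x) == 0) next
    robs <- as.numeric(stats::cor(tc, x))
    rnull <- unlist(lapply(seq_len(n_shuffles), function(i)
      as.numeric(stats::cor(tc, sample(x)))))
    # smallest (most inclusive) threshold whose estimated FDR — the ratio of
    # the null tail fraction to the observed tail fraction — is below `fdr`
    cand <- sort(unique(robs))
    thr <- NA_real_
    for (cc in cand) {
      nobs <- sum(robs >= cc)
      fn <- mean(rnull >= cc)
      if (nobs > 0 && fn / (nobs / G) < fdr) { thr <- cc; break }
    }
    if (is.na(thr)) next  # no threshold achieves the FDR: unmapped
    neigh <- genes[robs >= thr]
    pvals <- vapply(module_genes, function(mg) {
      x_in <- length(intersect(neigh, mg))
      stats::phyper(x_in - 1, length(mg), G - length(mg),
                    length(neigh), lower.tail = FALSE)
    }, 0)
    shown <- if (p_adjust == "BH") stats::p.adjust(pvals, "BH") else pvals
    for (id in names(module_genes)[shown < p_map])
      out[[length(out) + 1L]] <- data.frame(
        ncrna = r, module_id = id, p_value = pvals[[id]],
        n_neighbors = length(neigh), threshold = thr)
  }
  if (!length(out))
    return(data.frame(ncrna = character(), module_id = character(),
                      p_value = numeric(), n_neighbors = integer(),
                      threshold = numeric()))
  do.call(rbind, out)
}

#' Class enrichment of mapped ncRNAs per module
#'
#' For each module and ncRNA class, tests whether the module's mapped
#' ncRNAs contain more members of the class than expected when drawing the
#' module's mapped total from the global pool of mapped ncRNAs (upper-tail
#' hypergeometric). Classes absent from the pool are skipped with a message.
#'
#' @param assignments Output of [map_ncrna()].
#' @param classes Named character vector mapping ncRNA id to class.
#' @return Data frame `module_id`, `class`, `count`, `mapped_in_module`,
#'   `p_value`.
#' @export
ncrna_class_enrichment <- function(assignments, classes) {
  if (!nrow(assignments))
    return(data.frame(module_id = character(), class = character(),
                      count = integer(), mapped_in_module = integer(),
                      p_value = numeric()))
  cls <- classes[assignments$ncrna]
  known <- !is.na(cls)
  if (!all(known)) message(sum(!known), " mapped ncRNA(s) without a class")
  assignments <- assignments[known, , drop = FALSE]
  cls <- cls[known]
  pool_n <- nrow(assignments)
  out <- list()
  for (id in unique(assignments$module_id)) {
    in_mod <- assignments$module_id == id
    k <- sum(in_mod)
    for (cl in unique(cls)) {
      K <- sum(cls == cl)
      x <- sum(cls[in_mod] == cl)
      p <- stats::phyper(x - 1, K, pool_n - K, k, lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        module_id = id, class = cl, count = x, mapped_in_module = k,
        p_value = p)
    }
  }
  do.call(rbind, out)
}

#' Permutation test for cross-layer co-appearance enrichment
#'
#' Given a division of each layer into blocks (for instance planted
#' modules) and a claimed correspondence between some blocks of the two
#' layers, computes the mean co-appearance within every (block_a, block_b)
#' cell and tests whether the matched cells exceed what an equally sized
#' random selection of cells achieves. Cross-layer label coincidences are
#' lumpy (a whole block pair co-appears or not, run by run), so the cell
#' grid — not random gene sets — is the exchangeable unit under the null.
#' Used to check that with kappa = 0 the cross-species linkage of planted
#' conserved modules is at chance level, and that it is enriched for
#' kappa > 0.
#'
#' @param coap A `coappearance_matrix`.
#' @param blocks_a,blocks_b Lists of node-index vectors (blocks of layer A
#'   and of layer B).
#' @param matched Two-column matrix/data frame of block indices (a, b)
#'   claimed to correspond.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List `statistic` (mean co-appearance over matched cells),
#'   `cell_means` (|blocks_a| x |blocks_b| matrix), `p_value`.
#' @export
cross_coappearance_test <- function(coap, blocks_a, blocks_b, matched,
                                    n_perm = 1000L, seed = 1L) {
  v <- coap$values
  matched <- as.matrix(matched)
  stopifnot(ncol(matched) == 2L, nrow(matched) >= 1L)
  cells <- matrix(0, length(blocks_a), length(blocks_b))
  for (i in seq_along(blocks_a)) for (j in seq_along(blocks_b))
    cells[i, j] <- mean(v[blocks_a[[i]], blocks_b[[j]]])
  obs <- mean(cells[matched])
  k <- nrow(matched)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    mean(sample(cells, k)), 0)
  list(statistic = obs, cell_means = cells,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm))
}
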