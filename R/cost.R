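#' Cost-function parameters
#'
#' @param kappa Coupling constant weighting the orthology term (>= 0). At 0
#'   the layers are clustered independently; large values force orthologs
#'   into common modules.
#' @param lambda Resolution parameter multiplying the degree-product null in
#'   the modularity kernel; 1 is the conventional choice, larger values give
#'   smaller modules.
#' @param signed Treat positive and negative edges as separate classes and
#'   score Q+ - Q-.
#' @param kappa_triplet Weight of the third-order 1-1-1 triplet term
#'   (defaults to `kappa`).
#' @param normalize_layers Normalize each layer's modularity by its own 2m
#'   (and, via `normalize_orthology`, each coupling term by its total
#'   weight) so every term of H is O(1). Off by default: the raw form keeps
#'   each intra-layer link and each orthology link on a common O(1) scale,
#'   which is the scale on which kappa of order 1-3 balances co-association
#'   against orthology and on which the heat-bath dynamics anneal both
#'   terms in one pass. Mixed scaling (normalized layers, raw coupling)
#'   puts the two terms ~1e4 apart and freezes ortholog pairs long before
#'   the layer structure can order.
#' @param normalize_orthology Normalize each orthology map's coupling term
#'   by its total pair weight and the triplet term by the triplet count.
#'   Defaults to `normalize_layers`.
#' @return List of class `cost_params`.
#' @export
cost_params <- function(kappa = 1, lambda = 1, signed = FALSE,
                        kappa_triplet = kappa, normalize_layers = FALSE,
                        normalize_orthology = normalize_layers) {
  stopifnot(kappa >= 0, lambda > 0, kappa_triplet >= 0)
  structure(list(kappa = kappa, lambda = lambda, signed = isTRUE(signed),
                 kappa_triplet = kappa_triplet,
                 normalize_layers = isTRUE(normalize_layers),
                 normalize_orthology = isTRUE(normalize_orthology)),
            class = "cost_params")
}

# Subnetwork of one sign class (edges of the given sign only).
sign_class <- function(net, sgn) {
  species_network(net$species_id, net$nodes,
                  net$edges[net$edges$sign == sgn, , drop = FALSE])
}

#' Modularity term of one layer
#'
#' Computes Q = c * sum_{i,j} [A_ij - lambda k_i k_j / (2m)] delta(s_i, s_j)
#' with the sum over ordered pairs including i = j, where c = 1/(2m) when
#' `normalize = TRUE` and 1 otherwise. All edges are treated as unweighted
#' (A = 1) regardless of sign; use [signed_modularity_term()] for the signed
#' score. With lambda = 1 the all-one-module labeling scores exactly 0.
#'
#' @param net A `species_network`.
#' @param sigma Integer labels over `net$nodes` (in node order).
#' @param lambda Resolution parameter.
#' @param normalize Divide by 2m.
#' @return Numeric scalar Q (<= 1 when normalized).
#' @export
modularity_term <- function(net, sigma, lambda = 1, normalize = TRUE) {
  stopifnot(length(sigma) == length(net$nodes))
  e <- net$edges
  m <- nrow(e)
  if (m == 0L) stop("layer '", net$species_id, "' has no edges (m = 0)")
  ia <- match(e$from, net$nodes); ib <- match(e$to, net$nodes)
  same <- sigma[ia] == sigma[ib]
  k <- tabulate(c(ia, ib), nbins = length(net$nodes))
  K2 <- sum(tapply(k, sigma, sum)^2)
  raw <- 2 * sum(same) - lambda * K2 / (2 * m)
  if (normalize) raw / (2 * m) else raw
}

#' Signed modularity term Q+ - Q-
#'
#' Each sign class is scored with its own degrees and edge count; negative
#' links act oppositely, so co-labeling the endpoints of a negative edge is
#' penalized. A class with no edges contributes 0.
#'
#' @inheritParams modularity_term
#' @export
signed_modularity_term <- function(net, sigma, lambda = 1, normalize = TRUE) {
  pos <- sign_class(net, 1L); neg <- sign_class(net, -1L)
  if (nrow(pos$edges) == 0L && nrow(neg$edges) == 0L)
    stop("layer '", net$species_id, "' has no edges (m = 0)")
  qp <- if (nrow(pos$edges)) modularity_term(pos, sigma, lambda, normalize) else 0
  qn <- if (nrow(neg$edges)) modularity_term(neg, sigma, lambda, normalize) else 0
  qp - qn
}

#' Orthology coupling term
#'
#' Sum of pair weights over orthologous pairs whose endpoints share a label:
#' `sum w_ij delta(sigma_i, sigma_j)`. The map must carry resolved global
#' indices, i.e. come from [build_multilayer()].
#'
#' @param om An `orthology_map` with `idx_a`, `idx_b` columns.
#' @param sigma Global labeling (integer vector over all nodes).
#' @return Non-negative scalar, at most `sum(w)`.
#' @export
orthology_term <- function(om, sigma) {
  p <- om$pairs
  if (is.null(p$idx_a)) stop("orthology map lacks resolved node indices")
  sum(p$weight[sigma[p$idx_a] == sigma[p$idx_b]])
}

# Labels of a layer's nodes from a global labeling.
layer_sigma <- function(mln, layer_id, sigma) {
  sigma[mln$node_index$node[mln$node_index$species == layer_id]]
}

#' Total Potts cost of a labeling
#'
#' H = -( sum_layers Q_layer + kappa * sum_pairs orthology_term
#'        + kappa_triplet * #co-labeled 1-1-1 triplets ).
#' Lower is better; co-labeling orthologs strictly lowers H when kappa > 0.
#' With `normalize_orthology` on, each map's term is divided by its total
#' pair weight and the triplet term by the number of triplets.
#'
#' @param mln A `multilayer_network`.
#' @param sigma A [labeling()] (or integer vector) over all M nodes.
#' @param params A [cost_params()].
#' @return Numeric scalar H.
#' @export
total_cost <- function(mln, sigma, params = cost_params()) {
  stopifnot(inherits(params, "cost_params"), length(sigma) == mln$M)
  sigma <- as.integer(sigma)
  qsum <- sum(vapply(mln$layers, function(l) {
    ls <- layer_sigma(mln, l$species_id, sigma)
    if (params$signed)
      signed_modularity_term(l, ls, params$lambda, params$normalize_layers)
    else
      modularity_term(l, ls, params$lambda, params$normalize_layers)
  }, 0))
  osum <- sum(vapply(mln$orthologies, function(om) {
    tot <- if (params$normalize_orthology) sum(om$pairs$weight) else 1
    orthology_term(om, sigma) / tot
  }, 0))
  tsum <- 0
  if (nrow(mln$triplets)) {
    tnorm <- if (params$normalize_orthology) nrow(mln$triplets) else 1
    tsum <- sum(sigma[mln$triplets$i] == sigma[mln$triplets$j] &
                  sigma[mln$triplets$j] == sigma[mln$triplets$k]) / tnorm
  }
  -(qsum + params$kappa * osum + params$kappa_triplet * tsum)
}

# Collapsed M x M pair-gain matrix: H(sigma) = -(sum_ij C_ij delta_ij + triplet
# term). Used by the brute-force oracle; agreement with total_cost is tested.
pair_gain_matrix <- function(mln, params) {
  M <- mln$M
  C <- matrix(0, M, M)
  for (l in mln$layers) {
    idx <- mln$node_index$node[mln$node_index$species == l$species_id]
    classes <- if (params$signed) list(c(1L, 1), c(-1L, -1)) else list(c(1L, 1))
    for (cl in classes) {
      sub <- if (params$signed) sign_class(l, cl[1]) else l
      m <- nrow(sub$edges)
      if (m == 0L) next
      ia <- match(sub$edges$from, l$nodes); ib <- match(sub$edges$to, l$nodes)
      A <- matrix(0, length(idx), length(idx))
      A[cbind(ia, ib)] <- 1; A[cbind(ib, ia)] <- 1
      k <- rowSums(A)
      lam <- A - params$lambda * outer(k, k) / (2 * m)
      coef <- sign(cl[2]) * if (params$normalize_layers) 1 / (2 * m) else 1
      C[idx, idx] <- C[idx, idx] + coef * lam
    }
  }
  for (om in mln$orthologies) {
    p <- om$pairs
    tot <- if (params$normalize_orthology) sum(p$weight) else 1
    hw <- params$kappa * p$weight / tot / 2
    for (r in seq_len(nrow(p))) {
      C[p$idx_a[r], p$idx_b[r]] <- C[p$idx_a[r], p$idx_b[r]] + hw[r]
      C[p$idx_b[r], p$idx_a[r]] <- C[p$idx_b[r], p$idx_a[r]] + hw[r]
    }
  }
  C
}

# All set partitions of M items into at most q blocks, as restricted-growth
# strings (canonical up to label permutation).
rgs_enumerate <- function(M, q) {
  out <- list(c(1L))
  for (t in seq_len(M - 1L)) {
    out <- unlist(lapply(out, function(s) {
      top <- min(max(s) + 1L, q)
      lapply(seq_len(top), function(lbl) c(s, lbl))
    }), recursive = FALSE)
  }
  out
}

#' Exhaustive ground state of the Potts cost (small instances)
#'
#' Enumerates all label assignments up to label permutation (restricted
#' growth strings with at most q blocks) and returns a minimizer of
#' [total_cost()]. Guarded to q^M <= 1e7; intended as a test oracle for the
#' annealer.
#'
#' @param mln A `multilayer_network`.
#' @param params A [cost_params()].
#' @param q Number of labels.
#' @return List with `labeling` (a [labeling()]) and `cost`.
#' @export
ground_state_bruteforce <- function(mln, params, q) {
  M <- mln$M
  if (q^M > 1e7)
    stop("instance too large for enumeration: q^M = ", q, "^", M, " > 1e7")
  C <- pair_gain_matrix(mln, params)
  tri <- mln$triplets
  tnorm <- if (params$normalize_orthology && nrow(tri)) nrow(tri) else 1
  cands <- rgs_enumerate(M, q)
  best <- NULL; best_cost <- Inf
  for (s in cands) {
    D <- outer(s, s, "==")
    g <- sum(C[D])
    if (nrow(tri))
      g <- g + params$kappa_triplet / tnorm *
        sum(s[tri$i] == s[tri$j] & s[tri$j] == s[tri$k])
    cost <- -g
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- s }
  }
  list(labeling = labeling(best, q), cost = best_cost)
}
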