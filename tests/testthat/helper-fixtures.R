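# Shared in-code fixtures. Everything is generated; nothing is read from disk.

# Two disjoint triangles in one layer.
two_triangles <- function() {
  species_network("tri", letters[1:6],
                  data.frame(from = c("a", "b", "a", "d", "e", "d"),
                             to   = c("b", "c", "c", "e", "f", "f")))
}

# Minimal two-layer network: two 3-cliques joined by one 1-1 ortholog pair.
toy_mln <- function() {
  l1 <- species_network("A", c("a1", "a2", "a3"),
                        data.frame(from = c("a1", "a1", "a2"),
                                   to = c("a2", "a3", "a3")))
  l2 <- species_network("B", c("b1", "b2", "b3"),
                        data.frame(from = c("b1", "b1", "b2"),
                                   to = c("b2", "b3", "b3")))
  build_multilayer(list(l1, l2),
                   data.frame(species_a = "A", gene_a = "a1",
                              species_b = "B", gene_b = "b1"))
}

# Random small two-layer instance for oracle comparisons (M <= 10).
random_small_mln <- function() {
  n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
  mk <- function(sp, nn) {
    pairs <- t(utils::combn(nn, 2))
    keep <- stats::runif(nrow(pairs)) < 0.5
    if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
    species_network(sp, paste0(sp, seq_len(nn)),
                    data.frame(from = paste0(sp, pairs[keep, 1]),
                               to = paste0(sp, pairs[keep, 2]),
                               sign = sample(c(1L, 1L, 1L, -1L), sum(keep),
                                             replace = TRUE)))
  }
  l1 <- mk("a", n1); l2 <- mk("b", n2)
  np <- sample(1:3, 1)
  ot <- unique(data.frame(
    species_a = "a", gene_a = paste0("a", sample(n1, np, replace = TRUE)),
    species_b = "b", gene_b = paste0("b", sample(n2, np, replace = TRUE))))
  build_multilayer(list(l1, l2), ot)
}

# Default planted scenario plus the co-expression-derived multilayer
# network; cached per test file.
.fixture_env <- new.env()
planted_scenario <- function() {
  if (!is.null(.fixture_env$scenario)) return(.fixture_env$scenario)
  gen <- generate_planted_multilayer(seed = 7)
  expr <- generate_expression_from_truth(gen$truth, n_conditions = 30,
                                         rho = 0.7, seed = 8)
  layers <- lapply(names(expr), function(sp)
    rank_network(correlation_matrix(expr[[sp]]), 5, sp))
  ot <- do.call(rbind, lapply(gen$mln$orthologies, function(om)
    data.frame(species_a = om$species_a, gene_a = om$pairs$gene_a,
               species_b = om$species_b, gene_b = om$pairs$gene_b)))
  mln <- build_multilayer(layers, ot)
  .fixture_env$scenario <- list(gen = gen, expr = expr, mln = mln)
  .fixture_env$scenario
}

sign_class_for_test <- function(net, sgn) crossclust:::sign_class(net, sgn)

# Adjusted Rand index of a labeling against per-species truth.
species_ari <- function(sigma, mln, truth) {
  vapply(truth$species, function(sp) {
    idx <- mln$node_index$species == sp
    mclust::adjustedRandIndex(sigma[idx],
                              truth$modules[[sp]][mln$node_index$gene[idx]])
  }, 0)
}

# Planted-truth blocks as node-index lists, one per species module.
truth_blocks <- function(mln, truth, sp) {
  lapply(seq_len(truth$params$modules_per_species), function(k)
    which(mln$node_index$species == sp)[
      truth$modules[[sp]][mln$node_index$gene[mln$node_index$species == sp]] == k])
}
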