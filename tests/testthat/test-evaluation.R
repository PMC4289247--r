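test_that("GO similarity is an idf-weighted cosine kernel", {
  B <- matrix(c(1, 1, 0,
                0, 1, 1,
                1, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("t1", "t2", "t3")))
  gs <- go_similarity(B)
  W <- gs$W
  expect_true(isSymmetric(W))
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(diag(W), setNames(rep(0, 3), rownames(B)))  # network view
  # t2 annotates every gene: idf = 0, so g1 ~ g2 share nothing informative
  expect_equal(W["g1", "g2"], 0)
  # hand cosine for g1 ~ g3 with idf = log(3 / c(2, 3, 2))
  idf <- log(3 / c(2, 3, 2))
  v1 <- c(idf[1], 0, 0); v3 <- c(idf[1], 0, idf[3])
  expect_equal(W["g1", "g3"], sum(v1 * v3) / sqrt(sum(v1^2) * sum(v3^2)))
  # identical annotation vectors: similarity 1
  B2 <- rbind(B, g4 = B["g1", ])
  expect_equal(go_similarity(B2)$W["g1", "g4"], 1)
  # genes without terms are excluded with a message
  B3 <- rbind(B, g0 = c(0, 0, 0))
  expect_message(gs3 <- go_similarity(B3), "without GO terms")
  expect_equal(gs3$genes, rownames(B))
})

test_that("weighted modularity reproduces closed forms and a permutation null", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("g", 1:10)
  gsn <- structure(list(W = W, genes = rownames(W)),
                   class = "go_similarity_network")
  labs <- setNames(rep(1:2, each = 5), rownames(W))
  expect_equal(weighted_modularity(gsn, labs), 0.5)
  expect_equal(weighted_modularity(gsn, setNames(rep(1, 10), rownames(W))), 0)
  # random labels score near zero: a fresh draw stays within 3 sigma of the
  # permutation distribution, whose center is close to (but, on a finite
  # graph, not exactly) zero
  set.seed(12)
  nulls <- replicate(200, weighted_modularity(gsn, setNames(sample(labs),
                                                            rownames(W))))
  draw <- weighted_modularity(gsn, setNames(sample(labs), rownames(W)))
  expect_lt(abs(draw - mean(nulls)), 3 * stats::sd(nulls) + 1e-9)
  expect_lt(abs(mean(nulls)), 0.1)
})

test_that("metagene recovery counts intact metagenes", {
  ni <- data.frame(node = 1:8, species = rep(c("w", "f"), each = 4),
                   gene = c(paste0("w", 1:4), paste0("f", 1:4)))
  ms <- structure(list(modules = list(M1 = c(1:2, 5:6), M2 = c(3:4, 7:8)),
                       unassigned = integer(0), node_index = ni),
                  class = "module_set")
  mg <- list(a = c("w1", "f1"), b = c("w2", "f2"),
             c = c("w3", "f3"), d = c("w1", "f3"))  # d split across modules
  expect_equal(metagene_recovery(ms, mg), 0.75)
  expect_equal(metagene_recovery(ms, mg[1:3]), 1)
  expect_error(metagene_recovery(ms, list()), "empty")
  # unresolvable members dropped (message) or failed in strict mode
  mg2 <- list(a = c("w1", "f1", "zz"))
  expect_message(r <- metagene_recovery(ms, mg2), "not in the network")
  expect_equal(r, 1)
  expect_equal(suppressMessages(metagene_recovery(ms, c(mg2, mg["d"]),
                                                  strict = TRUE)), 0)
})

test_that("ortholog enrichment matches fold and exact tail oracles", {
  sc <- planted_scenario()
  om <- sc$mln$orthologies[["sp1|sp2"]]
  ni <- sc$mln$node_index
  wa <- ni$node[ni$species == "sp1"]; wb <- ni$node[ni$species == "sp2"]
  # whole genomes: fold exactly 1
  full <- ortholog_enrichment(wa, wb, om,
                              list(N_a = 200, N_b = 200, O = nrow(om$pairs)))
  expect_equal(full$fold, 1)
  expect_equal(full$observed, nrow(om$pairs))
  # no orthologs between the modules: fold 0
  none <- ortholog_enrichment(wa[151:160], wb[151:160], om,
                              list(N_a = 200, N_b = 200, O = nrow(om$pairs)))
  expect_equal(none$observed, 0)
  expect_equal(none$fold, 0)
  # worked numeric case: expected = 50 * (10/100) * (10/100) = 0.5
  l1 <- species_network("w", paste0("w", 1:20),
                        data.frame(from = "w1", to = "w2"))
  l2 <- species_network("f", paste0("f", 1:20),
                        data.frame(from = "f1", to = "f2"))
  ot <- data.frame(species_a = "w", gene_a = paste0("w", 1:4),
                   species_b = "f", gene_b = paste0("f", 1:4))
  m2 <- build_multilayer(list(l1, l2), ot)
  om2 <- m2$orthologies[["w|f"]]
  e <- ortholog_enrichment(m2$node_index$node[1:10], m2$node_index$node[21:30],
                           om2, list(N_a = 100, N_b = 100, O = 50))
  expect_equal(e$expected, 0.5)
  expect_equal(e$fold, e$observed / 0.5)
  # exact hypergeometric tail as independent oracle
  oracle_p <- sum(stats::dhyper(e$observed:min(50, 100), 50, 100 * 100 - 50, 100))
  expect_equal(e$p_value, oracle_p, tolerance = 1e-12)
})

test_that("clustering overlap implements I/(I+II+III) on pair sets", {
  expect_equal(clustering_overlap(list(c(1, 2), c(3, 4)),
                                  list(c(1, 2, 3), 4)), 0.25)
  expect_equal(clustering_overlap(list(1:5, 6:9), list(6:9, 1:5)), 1)
  expect_equal(clustering_overlap(list(1:6), as.list(1:6)), 0)
  expect_equal(clustering_overlap(as.list(1:4), as.list(1:4)), 1)
  # symmetry
  A <- list(c(1, 2, 3), c(4, 5)); B <- list(c(2, 3, 4), c(1, 5))
  expect_equal(clustering_overlap(A, B), clustering_overlap(B, A))
  # equals 1 iff pair sets coincide
  expect_lt(clustering_overlap(A, list(c(1, 2, 3), c(4, 5, 6))), 1)
})

test_that("regulatory coherence detects planted regulators and stays null on noise", {
  sc <- planted_scenario()
  bm <- generate_benchmarks_from_truth(sc$gen$truth, sc$expr, seed = 9)
  truth_ms <- truth_to_moduleset(sc$gen$truth, sc$mln)
  rc <- regulatory_coherence(bm$regulators, truth_ms, n_perm = 200, seed = 2)
  expect_gt(rc$fold, 1)
  expect_lte(rc$p_value, 1 / 100)
  # random regulator targets: fold near 1, p not extreme
  set.seed(31)
  rand <- data.frame(regulator = sample(paste0("TF", 1:20), 800, replace = TRUE),
                     target = sample(sc$mln$node_index$gene, 800, replace = TRUE))
  rc0 <- regulatory_coherence(rand, truth_ms, n_perm = 200, seed = 2)
  expect_lt(abs(rc0$fold - 1), 0.3)
  expect_gt(rc0$p_value, 0.01)
  # single all-covering module: no between pairs
  allmod <- structure(list(modules = list(M1 = seq_len(sc$mln$M)),
                           unassigned = integer(0),
                           node_index = sc$mln$node_index),
                      class = "module_set")
  expect_error(regulatory_coherence(bm$regulators, allmod), "between")
})

test_that("ncRNAs map to their planted modules and noise stays unmapped", {
  sc <- planted_scenario()
  bm <- generate_benchmarks_from_truth(sc$gen$truth, sc$expr, seed = 9)
  truth_ms <- truth_to_moduleset(sc$gen$truth, sc$mln)
  coding <- rbind(sc$expr$sp1, sc$expr$sp2)
  mp <- map_ncrna(bm$ncrna_expr, coding, truth_ms, seed = 3)
  expect_gt(nrow(mp), 0)
  # every planted ncRNA of conserved module k should hit module Ck
  planted_mod <- paste0("C", sub(".*:", "", bm$ncrna_truth[mp$ncrna]))
  expect_gt(mean(mp$module_id == planted_mod), 0.9)
  # pure-noise ncRNAs are mostly unmapped
  set.seed(5)
  noise <- matrix(stats::rnorm(20 * ncol(coding)), 20, ncol(coding),
                  dimnames = list(paste0("n", 1:20), colnames(coding)))
  mpn <- map_ncrna(noise, coding, truth_ms, seed = 3)
  expect_lte(length(unique(mpn$ncrna)), 3)
  expect_error(map_ncrna(bm$ncrna_expr, coding, truth_ms, n_shuffles = 0),
               "n_shuffles")
})

test_that("ncRNA class enrichment matches the exact hypergeometric", {
  asg <- data.frame(ncrna = c("a1", "a2", "a3", "b1", "b2", "b3"),
                    module_id = c("M1", "M1", "M1", "M2", "M2", "M2"),
                    p_value = 0.001, n_neighbors = 5, threshold = 0.5)
  cls <- setNames(c("mir", "mir", "mir", "sno", "sno", "sno"), asg$ncrna)
  en <- ncrna_class_enrichment(asg, cls)
  # module with all mapped members of a class: minimal attainable p
  row <- en[en$module_id == "M1" & en$class == "mir", ]
  expect_equal(row$p_value, stats::phyper(2, 3, 3, 3, lower.tail = FALSE))
  expect_equal(row$p_value, 1 / choose(6, 3))  # only one way to draw all 3
  expect_equal(nrow(ncrna_class_enrichment(asg[0, ], cls)), 0)
  # class missing from the map triggers a message, not an error
  expect_message(ncrna_class_enrichment(asg, cls[1:3]), "without a class")
})

test_that("cross-layer co-appearance test separates coupling from chance", {
  # synthetic co-appearance over 4 blocks per layer: the two matched block
  # pairs perfectly aligned, everything else at zero
  n <- 40
  v <- matrix(0, n, n); diag(v) <- 1
  b1 <- split(1:20, rep(1:4, each = 5))
  b2 <- split(21:40, rep(1:4, each = 5))
  v[b1[[1]], b2[[1]]] <- 1; v[b2[[1]], b1[[1]]] <- 1
  v[b1[[2]], b2[[2]]] <- 1; v[b2[[2]], b1[[2]]] <- 1
  coap <- structure(list(values = v, R = 16,
                         node_index = data.frame(node = 1:n, species = "s",
                                                 gene = as.character(1:n))),
                    class = "coappearance_matrix")
  hit <- cross_coappearance_test(coap, b1, b2, cbind(1:2, 1:2),
                                 n_perm = 500, seed = 1)
  expect_equal(hit$statistic, 1)
  expect_lt(hit$p_value, 0.05)
  # unaligned: statistic 0, p = 1
  miss <- cross_coappearance_test(coap, b1, b2, cbind(1:2, 2:1),
                                  n_perm = 500, seed = 1)
  expect_equal(miss$statistic, 0)
  expect_gt(miss$p_value, 0.5)
})

test_that("a single-point kappa scan degenerates to one pipeline run", {
  gen <- generate_planted_multilayer(genes_per_species = 60,
                                     modules_per_species = 3, n_conserved = 1,
                                     p_in = 0.4, p_out = 0.02, seed = 12)
  ks <- kappa_scan(gen$mln, kappa_grid = 1, q = 10,
                   schedule = anneal_schedule(seed = 40), R = 4)
  expect_equal(nrow(ks$report), 1L)
  expect_equal(ks$recommended, 1)
  direct <- run_pipeline(gen$mln, cost_params(kappa = 1), q = 10,
                         anneal_schedule(seed = 40), R = 4)
  expect_equal(lengths(ks$modules[["1"]]$modules),
               lengths(direct$modules$modules))
})
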