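test_that("modularity identities hold exactly", {
  tri <- two_triangles()
  expect_equal(modularity_term(tri, rep(1, 6)), 0)
  expect_equal(modularity_term(tri, c(1, 1, 1, 2, 2, 2)), 0.5)
  # raw variant of the null identity
  expect_equal(modularity_term(tri, rep(1, 6), normalize = FALSE), 0)
  # all-one labeling is exactly 0 on arbitrary graphs
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < 0.5
    if (!any(keep)) keep[1] <- TRUE
    net <- species_network("r", paste0("g", 1:n),
                           data.frame(from = paste0("g", pairs[keep, 1]),
                                      to = paste0("g", pairs[keep, 2])))
    expect_equal(modularity_term(net, rep(1, n)), 0)
  }
  expect_error(modularity_term(species_network("e", c("a", "b")), c(1, 1)),
               "m = 0")
})

test_that("modularity_term equals the ordered-pair double sum", {
  # independent O(n^2) oracle, sum over ordered pairs including i = j
  oracle <- function(net, sigma, lambda) {
    n <- length(net$nodes)
    A <- matrix(0, n, n)
    ia <- match(net$edges$from, net$nodes); ib <- match(net$edges$to, net$nodes)
    A[cbind(ia, ib)] <- 1; A[cbind(ib, ia)] <- 1
    k <- rowSums(A); m <- sum(k) / 2
    tot <- 0
    for (i in 1:n) for (j in 1:n)
      if (sigma[i] == sigma[j])
        tot <- tot + A[i, j] - lambda * k[i] * k[j] / (2 * m)
    tot / (2 * m)
  }
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < 0.6
    if (!any(keep)) keep[1] <- TRUE
    net <- species_network("r", paste0("g", 1:n),
                           data.frame(from = paste0("g", pairs[keep, 1]),
                                      to = paste0("g", pairs[keep, 2])))
    sigma <- sample(1:3, n, replace = TRUE)
    lambda <- sample(c(0.5, 1, 2), 1)
    expect_equal(modularity_term(net, sigma, lambda), oracle(net, sigma, lambda))
  }
})

test_that("signed modularity separates the sign classes", {
  tri <- two_triangles()
  expect_equal(signed_modularity_term(tri, c(1, 1, 1, 2, 2, 2)),
               modularity_term(tri, c(1, 1, 1, 2, 2, 2)))
  neg <- species_network("n", letters[1:4],
                         data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "d"), sign = -1L))
  expect_equal(signed_modularity_term(neg, rep(1, 4)), 0)

  # planted two-module graph, negative edges only between modules
  nodes <- paste0("g", 1:8)
  within <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)))
  between <- cbind(1:4, 5:8)
  net <- species_network("s", nodes, data.frame(
    from = nodes[c(within[, 1], between[, 1])],
    to = nodes[c(within[, 2], between[, 2])],
    sign = c(rep(1L, nrow(within)), rep(-1L, nrow(between)))))
  sigma <- rep(1:2, each = 4)
  qp <- modularity_term(sign_class_for_test(net, 1L), sigma)
  qn <- modularity_term(sign_class_for_test(net, -1L), sigma)
  expect_gt(qp, 0)
  # cross-module negatives enter no delta term, so Q- is pure null (< 0)
  # and its subtraction rewards the labeling
  expect_gt(-qn, 0)
  merged <- species_network("m", nodes,
                            data.frame(from = net$edges$from, to = net$edges$to))
  expect_gt(signed_modularity_term(net, sigma),
            modularity_term(merged, sigma))
})

test_that("orthology_term sums weights of co-labeled pairs", {
  mln <- toy_mln()
  om <- mln$orthologies[["A|B"]]
  expect_equal(orthology_term(om, c(1, 1, 1, 2, 2, 2)), 0)
  expect_equal(orthology_term(om, rep(1, 6)), sum(om$pairs$weight))
  # 3 pairs with weights {1, .75, .75}, two co-labeled
  l1 <- species_network("A", c("a1", "a2"), data.frame(from = "a1", to = "a2"))
  l2 <- species_network("B", c("b1", "b2", "b3"),
                        data.frame(from = c("b1", "b2"), to = c("b2", "b3")))
  m2 <- build_multilayer(list(l1, l2), data.frame(
    species_a = "A", gene_a = c("a1", "a2", "a2"),
    species_b = "B", gene_b = c("b1", "b2", "b3")))
  om2 <- m2$orthologies[["A|B"]]
  expect_equal(sort(om2$pairs$weight), c(0.75, 0.75, 1))
  # co-label a1~b1 (w=1) and a2~b2 (w=.75); a2~b3 split
  sigma <- c(1, 2, 1, 2, 3)
  expect_equal(orthology_term(om2, sigma), 1.75)
})

test_that("total_cost composes its terms with the coupling constant", {
  mln <- toy_mln()
  sall <- labeling(rep(1L, 6), 3)
  ssplit <- labeling(c(1, 1, 1, 2, 2, 2), 3)
  # kappa = 0 reduces to independent layer scores
  p0 <- cost_params(kappa = 0)
  expect_equal(total_cost(mln, sall, p0),
               -(modularity_term(mln$layers$A, rep(1, 3), normalize = FALSE) +
                   modularity_term(mln$layers$B, rep(1, 3), normalize = FALSE)))
  # co-labeling the single ortholog pair lowers H by exactly kappa * w
  for (kap in c(0.5, 1, 4)) {
    pk <- cost_params(kappa = kap)
    expect_equal(total_cost(mln, sall, pk) - total_cost(mln, ssplit, pk), -kap)
  }
})

test_that("a single co-labeled 1-1-1 triplet changes H by -kappa_triplet", {
  mk <- function(sp) species_network(sp, paste0(sp, 1:2),
                                     data.frame(from = paste0(sp, 1),
                                                to = paste0(sp, 2)))
  ot <- do.call(rbind, lapply(list(c("A", "B"), c("A", "C"), c("B", "C")),
    function(sp) data.frame(species_a = sp[1], gene_a = paste0(sp[1], 1),
                            species_b = sp[2], gene_b = paste0(sp[2], 1))))
  mln <- build_multilayer(list(mk("A"), mk("B"), mk("C")),
                          ot, detect_triplets = TRUE)
  expect_equal(nrow(mln$triplets), 1L)
  # kappa = 0 isolates the triplet term from the pairwise couplings
  pr <- cost_params(kappa = 0, kappa_triplet = 2.5)
  co  <- labeling(c(1, 2, 1, 2, 1, 2), 3)   # triplet co-labeled
  apart <- labeling(c(1, 2, 3, 2, 1, 2), 3) # first member moved off
  expect_equal(total_cost(mln, co, pr) - total_cost(mln, apart, pr), -2.5)
})

test_that("total_cost is invariant under label permutation and monotone in kappa", {
  set.seed(31)
  for (rep in 1:10) {
    mln <- random_small_mln()
    q <- 4
    sigma <- sample.int(q, mln$M, replace = TRUE)
    perm <- sample(q)
    pr <- cost_params(kappa = stats::runif(1, 0, 3),
                      signed = sample(c(TRUE, FALSE), 1))
    expect_equal(total_cost(mln, labeling(sigma, q), pr),
                 total_cost(mln, labeling(perm[sigma], q), pr))
    # dH/dkappa = -orthology sum <= 0
    p1 <- cost_params(kappa = 1); p2 <- cost_params(kappa = 2)
    dh <- total_cost(mln, labeling(sigma, q), p2) -
      total_cost(mln, labeling(sigma, q), p1)
    expect_lte(dh, 1e-12)
  }
})

test_that("the pair-gain shortcut agrees with total_cost", {
  set.seed(8)
  for (rep in 1:10) {
    mln <- random_small_mln()
    pr <- cost_params(kappa = stats::runif(1, 0, 3),
                      signed = sample(c(TRUE, FALSE), 1),
                      normalize_layers = sample(c(TRUE, FALSE), 1))
    C <- crossclust:::pair_gain_matrix(mln, pr)
    q <- 3
    for (k in 1:5) {
      sigma <- sample.int(q, mln$M, replace = TRUE)
      expect_equal(-sum(C[outer(sigma, sigma, "==")]),
                   total_cost(mln, labeling(sigma, q), pr))
    }
  }
})

test_that("brute-force ground states match hand-derivable optima", {
  # single edge, q = 2: both endpoints co-labeled
  l1 <- species_network("A", c("a1", "a2"), data.frame(from = "a1", to = "a2"))
  l2 <- species_network("B", c("b1", "b2"), data.frame(from = "b1", to = "b2"))
  m1 <- build_multilayer(list(l1, l2), NULL)
  gs <- ground_state_bruteforce(m1, cost_params(kappa = 0), 2)
  s <- as.integer(gs$labeling)
  expect_equal(s[1], s[2]); expect_equal(s[3], s[4])

  # large kappa: orthologs co-labeled in the minimizer
  mln <- toy_mln()
  gs2 <- ground_state_bruteforce(mln, cost_params(kappa = 50), 2)
  s2 <- as.integer(gs2$labeling)
  om <- mln$orthologies[["A|B"]]
  expect_equal(s2[om$pairs$idx_a], s2[om$pairs$idx_b])

  # kappa = 0 with two disconnected cliques per layer: cliques split
  ll <- species_network("A", paste0("a", 1:6),
                        data.frame(from = paste0("a", c(1, 1, 2, 4, 4, 5)),
                                   to = paste0("a", c(2, 3, 3, 5, 6, 6))))
  m3 <- build_multilayer(list(ll,
                              species_network("B", c("b1", "b2"),
                                              data.frame(from = "b1", to = "b2"))),
                         NULL)
  gs3 <- ground_state_bruteforce(m3, cost_params(kappa = 0), 3)
  s3 <- as.integer(gs3$labeling)
  expect_equal(length(unique(s3[1:3])), 1L)
  expect_equal(length(unique(s3[4:6])), 1L)
  expect_false(s3[1] == s3[4])

  expect_error(ground_state_bruteforce(
    generate_planted_multilayer(genes_per_species = 20, seed = 1)$mln,
    cost_params(), 10), "too large")
})
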