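#' Generate a planted multi-layer network with known module structure
#'
#' Each species' genes are partitioned into modules of (near-)equal size;
#' intra-layer edges are Bernoulli(p_in) within modules and Bernoulli(p_out)
#' between. The first `n_conserved` modules of every species correspond
#' across species: for each species pair, positionally matched genes of a
#' conserved module are orthologous with probability `ortholog_fidelity`.
#' An optional many-to-many specification adds a bipartite ortholog clique
#' spanning two conserved module pairs, the regime in which uniform
#' ortholog weights glue distinct conserved structures together.
#'
#' @param n_species Number of layers (>= 2).
#' @param genes_per_species Genes per layer.
#' @param modules_per_species Planted modules per layer.
#' @param n_conserved Number of module pairs conserved across species
#'   (<= modules_per_species).
#' @param p_in,p_out Within/between-module edge probabilities (p_in > p_out).
#' @param ortholog_fidelity Probability that a matched conserved gene pair
#'   is listed as orthologous.
#' @param many_to_many Optional list `list(size =, modules = c(a, b))`:
#'   adds a size x size bipartite ortholog clique between the first two
#'   species, with size/2 genes drawn from each of the two (conserved)
#'   modules on each side.
#' @param seed Integer seed.
#' @param scheme Ortholog weighting scheme for [build_multilayer()].
#' @param detect_triplets Passed to [build_multilayer()].
#' @return List `mln` (a `multilayer_network`) and `truth` (class
#'   `planted_truth`: per-species module assignments named by gene,
#'   `n_conserved`, generation parameters).
#' @export
generate_planted_multilayer <- function(n_species = 2L,
                                        genes_per_species = 200L,
                                        modules_per_species = 4L,
                                        n_conserved = 2L,
                                        p_in = 0.3, p_out = 0.01,
                                        ortholog_fidelity = 1,
                                        many_to_many = NULL,
                                        seed = 1L,
                                        scheme = "mean_recip",
                                        detect_triplets = FALSE) {
  stopifnot(p_in > p_out, ortholog_fidelity >= 0, ortholog_fidelity <= 1,
            n_conserved <= modules_per_species, n_species >= 2L)
  set.seed(seed)
  species <- paste0("sp", seq_len(n_species))
  assign_mod <- sort(rep_len(seq_len(modules_per_species), genes_per_species))
  msize <- tabulate(assign_mod)
  if (p_in * (min(msize) - 1) < 1)
    warning("expected within-module degree < 1; layers may disconnect")
  genes <- lapply(species, function(sp)
    sprintf("%s_g%03d", sp, seq_len(genes_per_species)))
  names(genes) <- species
  layers <- list()
  for (sp in species) {
    n <- genes_per_species
    iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    p <- ifelse(assign_mod[iu[, 1]] == assign_mod[iu[, 2]], p_in, p_out)
    keep <- stats::runif(nrow(iu)) < p
    layers[[sp]] <- species_network(
      sp, genes[[sp]],
      data.frame(from = genes[[sp]][iu[keep, 1]],
                 to = genes[[sp]][iu[keep, 2]], sign = 1L))
  }
  # The many-to-many clique links `size` genes of one conserved module in
  # the first species to `size` genes of a different conserved module in
  # the second species, and those genes take part in no 1-1 pair: with
  # uniform weights the 8x8 clique (64 links) out-pulls the ~42 one-to-one
  # links and glues the two conserved structures into one module, whereas
  # per-ortholog-count weights shrink each clique link to ~1/size and the
  # one-to-one evidence wins.
  clique_a <- clique_b <- integer(0)
  if (!is.null(many_to_many)) {
    sz <- many_to_many$size
    mods <- many_to_many$modules
    stopifnot(length(mods) == 2L, sz >= 2L, mods[1] != mods[2])
    clique_a <- utils::head(which(assign_mod == mods[1]), sz)  # species 1 side
    clique_b <- utils::head(which(assign_mod == mods[2]), sz)  # species 2 side
  }
  orth <- list()
  for (a in seq_len(n_species - 1L)) for (b in (a + 1L):n_species) {
    for (k in seq_len(n_conserved)) {
      members <- which(assign_mod == k)
      if (a == 1L) members <- setdiff(members, clique_a)
      if (b == 2L) members <- setdiff(members, clique_b)
      hit <- stats::runif(length(members)) < ortholog_fidelity
      if (!any(hit)) next
      orth[[length(orth) + 1L]] <- data.frame(
        species_a = species[a], gene_a = genes[[a]][members[hit]],
        species_b = species[b], gene_b = genes[[b]][members[hit]])
    }
  }
  if (length(clique_a)) {
    grid <- expand.grid(a = clique_a, b = clique_b)
    orth[[length(orth) + 1L]] <- data.frame(
      species_a = species[1], gene_a = genes[[1]][grid$a],
      species_b = species[2], gene_b = genes[[2]][grid$b])
  }
  ot <- if (length(orth)) unique(do.call(rbind, orth)) else NULL
  mln <- build_multilayer(layers, ot, detect_triplets = detect_triplets,
                          scheme = scheme)
  truth <- structure(list(
    species = species,
    modules = stats::setNames(lapply(species, function(sp)
      stats::setNames(assign_mod, genes[[sp]])), species),
    n_conserved = n_conserved,
    many_to_many = many_to_many,
    params = list(n_species = n_species,
                  genes_per_species = genes_per_species,
                  modules_per_species = modules_per_species,
                  n_conserved = n_conserved, p_in = p_in, p_out = p_out,
                  ortholog_fidelity = ortholog_fidelity, seed = seed)),
    class = "planted_truth")
  list(mln = mln, truth = truth)
}

#' Generate per-species expression matrices from a planted truth
#'
#' Every module draws a latent profile across conditions (conserved modules
#' share one latent across species, so orthologous genes co-vary); each
#' member gene is `sqrt(rho) * latent + sqrt(1 - rho) * noise`, giving an
#' expected within-module Pearson correlation of about `rho` when
#' `noise_sd = 1`.
#'
#' @param truth A `planted_truth`.
#' @param n_conditions Number of conditions (developmental stages).
#' @param rho Target within-module correlation in [0, 1).
#' @param noise_sd Standard deviation of the per-gene noise.
#' @param seed Integer seed.
#' @return Named list of gene x condition matrices, one per species, with
#'   attribute `latents` (list per species of module x condition matrices).
#' @export
generate_expression_from_truth <- function(truth, n_conditions = 30L,
                                           rho = 0.7, noise_sd = 1,
                                           seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"), rho >= 0, rho < 1)
  set.seed(seed)
  n_mod <- truth$params$modules_per_species
  shared <- matrix(stats::rnorm(truth$n_conserved * n_conditions),
                   truth$n_conserved, n_conditions)
  out <- list(); lat <- list()
  for (sp in truth$species) {
    mods <- truth$modules[[sp]]
    L <- matrix(stats::rnorm(n_mod * n_conditions), n_mod, n_conditions)
    if (truth$n_conserved > 0)
      L[seq_len(truth$n_conserved), ] <- shared
    eps <- matrix(stats::rnorm(length(mods) * n_conditions, sd = noise_sd),
                  length(mods), n_conditions)
    X <- sqrt(rho) * L[mods, , drop = FALSE] + sqrt(1 - rho) * eps
    rownames(X) <- names(mods)
    colnames(X) <- paste0("cond", seq_len(n_conditions))
    out[[sp]] <- X
    lat[[sp]] <- L
  }
  attr(out, "latents") <- lat
  out
}

#' Generate evaluation benchmarks from a planted truth
#'
#' Produces: a GO annotation matrix in which conserved module pairs share
#' module-specific terms across species (plus near-ubiquitous background
#' terms that exercise the idf down-weighting); a metagene set sampled from
#' the positional ortholog groups of conserved modules; a regulator table
#' whose regulators each target one planted module; and, when expression
#' matrices are supplied, ncRNA profiles copying module mean profiles with
#' noise (with the planted memberships returned for assertion).
#'
#' @param truth A `planted_truth`.
#' @param expr Optional output of [generate_expression_from_truth()]
#'   (needed for ncRNA profiles).
#' @param go_terms_per_module Specific terms per module.
#' @param n_background_terms Ubiquitous background terms.
#' @param n_metagenes Metagenes to sample.
#' @param regulators_per_module Regulators targeting each module.
#' @param ncrna_per_module ncRNAs planted per conserved module.
#' @param ncrna_noise_sd Noise added to ncRNA profiles.
#' @param seed Integer seed.
#' @return List `go` (binary gene x term matrix), `metagenes` (named list),
#'   `regulators` (data frame `regulator`, `target`), `ncrna_expr` (matrix
#'   or NULL), `ncrna_truth` (named vector of planted module ids).
#' @export
generate_benchmarks_from_truth <- function(truth, expr = NULL,
                                           go_terms_per_module = 5L,
                                           n_background_terms = 10L,
                                           n_metagenes = 20L,
                                           regulators_per_module = 2L,
                                           ncrna_per_module = 5L,
                                           ncrna_noise_sd = 0.5,
                                           seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(seed)
  n_mod <- truth$params$modules_per_species
  ann <- list()
  for (k in seq_len(n_mod)) {
    conserved <- k <= truth$n_conserved
    for (sp in truth$species) {
      members <- names(truth$modules[[sp]])[truth$modules[[sp]] == k]
      # conserved modules share terms across species; specific ones do not
      terms <- if (conserved) sprintf("GO:C%02d_%02d", k, seq_len(go_terms_per_module))
               else sprintf("GO:S_%s_%02d_%02d", sp, k, seq_len(go_terms_per_module))
      hit <- expand.grid(gene = members, term = terms,
                         stringsAsFactors = FALSE)
      hit <- hit[stats::runif(nrow(hit)) < 0.8, , drop = FALSE]
      ann[[length(ann) + 1L]] <- hit
    }
  }
  all_genes <- unlist(lapply(truth$modules, names), use.names = FALSE)
  for (b in seq_len(n_background_terms)) {
    carriers <- all_genes[stats::runif(length(all_genes)) < 0.9]
    ann[[length(ann) + 1L]] <- data.frame(
      gene = carriers, term = sprintf("GO:BG%02d", b),
      stringsAsFactors = FALSE)
  }
  go <- go_annotation_matrix(do.call(rbind, ann))

  mg <- list()
  if (truth$n_conserved > 0) {
    cons_pos <- which(truth$modules[[1]] %in% seq_len(truth$n_conserved))
    picks <- sample(cons_pos, min(n_metagenes, length(cons_pos)))
    for (i in seq_along(picks)) {
      pos <- picks[i]
      mg[[sprintf("meta%03d", i)]] <-
        vapply(truth$species, function(sp) names(truth$modules[[sp]])[pos], "")
    }
  }

  reg <- list()
  for (sp in truth$species) for (k in seq_len(n_mod)) {
    members <- names(truth$modules[[sp]])[truth$modules[[sp]] == k]
    for (r in seq_len(regulators_per_module)) {
      tgt <- members[stats::runif(length(members)) < 0.7]
      reg[[length(reg) + 1L]] <- data.frame(
        regulator = sprintf("TF_%s_m%d_%d", sp, k, r), target = tgt,
        stringsAsFactors = FALSE)
    }
  }
  regulators <- do.call(rbind, reg)

  ncrna_expr <- NULL; ncrna_truth <- NULL
  if (!is.null(expr) && truth$n_conserved > 0) {
    rows <- list(); labs <- character()
    for (sp in truth$species) for (k in seq_len(truth$n_conserved)) {
      members <- names(truth$modules[[sp]])[truth$modules[[sp]] == k]
      prof <- colMeans(expr[[sp]][members, , drop = FALSE])
      for (i in seq_len(ncrna_per_module)) {
        nm <- sprintf("ncRNA_%s_m%d_%d", sp, k, i)
        rows[[nm]] <- prof + stats::rnorm(length(prof), sd = ncrna_noise_sd)
        labs[nm] <- paste0(sp, ":", k)
      }
    }
    ncrna_expr <- do.call(rbind, rows)
    ncrna_truth <- labs
  }
  list(go = go, metagenes = mg, regulators = regulators,
       ncrna_expr = ncrna_expr, ncrna_truth = ncrna_truth)
}

#' Planted truth as a module set
#'
#' Builds the `module_set` the pipeline should ideally recover: one module
#' per conserved module pair (spanning all species) and one per remaining
#' species-specific module.
#'
#' @param truth A `planted_truth`.
#' @param mln The `multilayer_network` generated with it (or one sharing its
#'   gene names).
#' @return A `module_set`.
#' @export
truth_to_moduleset <- function(truth, mln) {
  mods <- list()
  key <- paste(mln$node_index$species, mln$node_index$gene, sep = "\r")
  node_of <- function(sp, gene) match(paste(sp, gene, sep = "\r"), key)
  for (k in seq_len(truth$params$modules_per_species)) {
    if (k <= truth$n_conserved) {
      nodes <- unlist(lapply(truth$species, function(sp)
        node_of(sp, names(truth$modules[[sp]])[truth$modules[[sp]] == k])))
      mods[[paste0("C", k)]] <- sort(nodes[!is.na(nodes)])
    } else {
      for (sp in truth$species) {
        nodes <- node_of(sp, names(truth$modules[[sp]])[truth$modules[[sp]] == k])
        mods[[paste0("S", k, "_", sp)]] <- sort(nodes[!is.na(nodes)])
      }
    }
  }
  structure(list(modules = mods, unassigned = integer(0),
                 node_index = mln$node_index),
            class = "module_set")
}

#' Sample from a discrete power law
#'
#' P(X = k) proportional to k^(-alpha) for k in `xmin..kmax`. Used to test
#' the size-distribution estimator against a known exponent.
#'
#' @param n Sample size.
#' @param alpha Exponent (> 1).
#' @param xmin Lower cutoff.
#' @param kmax Upper truncation of the support.
#' @return Integer vector of length n.
#' @export
rpowerlaw_discrete <- function(n, alpha, xmin = 1L, kmax = 100000L) {
  k <- xmin:kmax
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}
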