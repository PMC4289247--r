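#' Co-appearance matrix of an annealing ensemble
#'
#' Entry (i, j) is the fraction of runs in which nodes i and j carried the
#' same label. Entries lie on the grid k/R; the diagonal is exactly 1.
#'
#' @param results List of `anneal_result` sharing one node index.
#' @param mln Optional `multilayer_network` supplying the node index for
#'   downstream output.
#' @return `coappearance_matrix`: `values` (dense symmetric matrix), `R`,
#'   `node_index`.
#' @export
coappearance <- function(results, mln = NULL) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "anneal_result")))
  M <- length(results[[1]]$labeling)
  if (!all(vapply(results, function(r) length(r$labeling), 0L) == M))
    stop("annealing results have mismatched node sets")
  acc <- matrix(0, M, M)
  for (r in results) {
    s <- as.integer(r$labeling)
    S <- Matrix::sparseMatrix(i = seq_len(M), j = s, x = 1,
                              dims = c(M, max(s)))
    acc <- acc + as.matrix(Matrix::tcrossprod(S))
  }
  v <- acc / length(results)
  diag(v) <- 1
  ni <- if (is.null(mln)) data.frame(node = seq_len(M),
                                     species = NA_character_,
                                     gene = as.character(seq_len(M)))
        else mln$node_index
  structure(list(values = v, R = length(results), node_index = ni),
            class = "coappearance_matrix")
}

#' Extract consensus modules from a co-appearance matrix
#'
#' Builds the auxiliary graph with an edge wherever co-appearance meets the
#' threshold and takes its connected components; components smaller than
#' `min_size` are reported as unassigned rather than as modules. Components
#' (not cliques) implement the transitivity of "assigned to the same
#' module"; raising the threshold can only refine modules.
#'
#' @param coap A `coappearance_matrix`.
#' @param threshold Co-appearance fraction required for an auxiliary edge
#'   (default 0.95; compared with `>=`).
#' @param min_size Smallest module kept (default 5).
#' @return `module_set`: named list `modules` of global node-index vectors
#'   (decreasing size, ids "M1", "M2", ...), `unassigned`, `node_index`.
#' @export
extract_modules <- function(coap, threshold = 0.95, min_size = 5L) {
  stopifnot(inherits(coap, "coappearance_matrix"),
            threshold > 0, threshold <= 1)
  v <- coap$values
  M <- nrow(v)
  idx <- which(v >= threshold & upper.tri(v), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(idx[, 1], idx[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, M - igraph::vcount(g)))
  comp <- igraph::components(g)
  groups <- split(seq_len(M), comp$membership)
  sizes <- lengths(groups)
  keep <- groups[sizes >= min_size]
  keep <- keep[order(-lengths(keep), vapply(keep, min, 0L))]
  names(keep) <- if (length(keep)) paste0("M", seq_along(keep)) else character()
  structure(list(modules = lapply(keep, as.integer),
                 unassigned = as.integer(sort(unlist(groups[sizes < min_size]))),
                 node_index = coap$node_index),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(x$modules), "modules,",
      length(x$unassigned), "unassigned nodes\n")
  if (length(x$modules))
    cat("  sizes:", paste(utils::head(lengths(x$modules), 10), collapse = " "),
        if (length(x$modules) > 10) "...\n" else "\n")
  invisible(x)
}

#' Classify modules as conserved or species-specific
#'
#' A module is conserved when it holds at least `min_cross` genes from each
#' of two or more species and contains at least one orthologous pair
#' internal to the module; otherwise it is specific to its majority species.
#'
#' @param modules A `module_set`.
#' @param mln The `multilayer_network` the modules live on.
#' @param min_cross Minimum genes per species for conserved status.
#' @return Named character vector: `"conserved"` or `"specific:<species>"`.
#' @export
classify_modules <- function(modules, mln, min_cross = 3L) {
  sp <- mln$node_index$species
  opairs <- do.call(rbind, lapply(mln$orthologies, function(om)
    om$pairs[c("idx_a", "idx_b")]))
  vapply(modules$modules, function(nodes) {
    comp <- table(sp[nodes])
    comp <- comp[comp > 0]
    has_orth <- !is.null(opairs) && nrow(opairs) > 0 &&
      any(opairs$idx_a %in% nodes & opairs$idx_b %in% nodes)
    if (sum(comp >= min_cross) >= 2L && has_orth) "conserved"
    else paste0("specific:", names(comp)[which.max(comp)])
  }, "")
}

#' Species composition counts per module
#' @param modules A `module_set`.
#' @param mln The underlying `multilayer_network`.
#' @return Data frame `module_id`, `species`, `count`.
#' @export
module_composition <- function(modules, mln) {
  do.call(rbind, lapply(names(modules$modules), function(id) {
    tab <- table(mln$node_index$species[modules$modules[[id]]])
    data.frame(module_id = id, species = names(tab), count = as.integer(tab))
  }))
}

#' Turn a module set into a full labeling
#'
#' Modules receive labels 1..K in id order; every unassigned node gets its
#' own fresh label (singleton), so the result is a total labeling usable
#' with the cost functions.
#'
#' @param modules A `module_set`.
#' @param M Total number of nodes.
#' @return A [labeling()].
#' @export
modules_to_labeling <- function(modules, M) {
  sigma <- integer(M)
  for (i in seq_along(modules$modules)) sigma[modules$modules[[i]]] <- i
  free <- which(sigma == 0L)
  sigma[free] <- length(modules$modules) + seq_along(free)
  labeling(sigma, max(sigma))
}

# Hurwitz zeta by direct summation with an Euler-Maclaurin tail.
hurwitz_zeta <- function(alpha, xmin, kmax = 1e5) {
  k <- xmin:kmax
  sum(k^(-alpha)) + (kmax + 0.5)^(1 - alpha) / (alpha - 1)
}

#' Maximum-likelihood fit of a discrete power law to module sizes
#'
#' Fits P(s) proportional to s^(-alpha) for s >= xmin (xmin = smallest
#' observed module size) by maximizing the discrete log-likelihood
#' `-n log zeta(alpha, xmin) - alpha sum(log s)`. The exponent is reported
#' as a negative number, matching the usual "exponent of the size
#' distribution" convention.
#'
#' @param modules A `module_set`, or a numeric vector of sizes.
#' @return List `exponent` (negative), `xmin`, `n`, `low_confidence`
#'   (TRUE when fewer than 3 distinct sizes are observed).
#' @export
fit_size_distribution <- function(modules) {
  sizes <- if (inherits(modules, "module_set")) lengths(modules$modules)
           else as.numeric(modules)
  n <- length(sizes)
  if (n < 10L) stop("need at least 10 modules to fit a size distribution")
  if (length(unique(sizes)) == 1L) stop("no spread in module sizes")
  xmin <- min(sizes)
  slog <- sum(log(sizes))
  nll <- function(alpha) n * log(hurwitz_zeta(alpha, xmin)) + alpha * slog
  opt <- stats::optimize(nll, c(1.01, 10))
  list(exponent = -opt$minimum, xmin = xmin, n = n,
       low_confidence = length(unique(sizes)) < 3L)
}
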