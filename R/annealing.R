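# Compile a multilayer network + cost params into the flat CSR form the C++
# engine consumes. 0-based node indices throughout.
mln_compile <- function(mln, params) {
  stopifnot(inherits(mln, "multilayer_network"), inherits(params, "cost_params"))
  M <- mln$M
  csr <- function(from0, to0, w = NULL) {
    ord <- order(from0, to0)
    from0 <- from0[ord]; to0 <- to0[ord]
    ptr <- c(0L, cumsum(tabulate(from0 + 1L, nbins = M)))
    out <- list(ptr = as.integer(ptr), idx = as.integer(to0))
    if (!is.null(w)) out$w <- as.numeric(w[ord])
    out
  }
  classes <- list()
  for (l in mln$layers) {
    if (nrow(l$edges) == 0L)
      stop("layer '", l$species_id, "' has no edges (m = 0)")
    offset <- min(mln$node_index$node[mln$node_index$species == l$species_id]) - 1L
    signs <- if (params$signed) c(1L, -1L) else NA
    for (sg in signs) {
      e <- if (is.na(sg)) l$edges else l$edges[l$edges$sign == sg, , drop = FALSE]
      m <- nrow(e)
      if (m == 0L) next
      ia <- match(e$from, l$nodes) + offset - 1L
      ib <- match(e$to, l$nodes) + offset - 1L
      a <- csr(c(ia, ib), c(ib, ia))
      k <- numeric(M)
      tab <- tabulate(c(ia, ib) + 1L, nbins = M)
      k <- as.numeric(tab)
      coef <- (if (is.na(sg)) 1 else sg) *
        (if (params$normalize_layers) 1 / (2 * m) else 1)
      classes[[length(classes) + 1L]] <-
        list(k = k, aptr = a$ptr, aidx = a$idx, coef = coef,
             lam2m = params$lambda / (2 * m))
    }
  }
  oa <- integer(0); ob <- integer(0); ow <- numeric(0)
  for (om in mln$orthologies) {
    p <- om$pairs
    tot <- if (params$normalize_orthology) sum(p$weight) else 1
    oa <- c(oa, p$idx_a - 1L, p$idx_b - 1L)
    ob <- c(ob, p$idx_b - 1L, p$idx_a - 1L)
    ow <- c(ow, rep(params$kappa * p$weight / tot, 2))
  }
  o <- if (length(oa)) csr(oa, ob, ow) else
    list(ptr = integer(M + 1L), idx = integer(0), w = numeric(0))
  tri <- mln$triplets
  if (nrow(tri)) {
    tf <- c(tri$i, tri$j, tri$k) - 1L
    t1 <- c(tri$j, tri$i, tri$i) - 1L
    t2 <- c(tri$k, tri$k, tri$j) - 1L
    ordt <- order(tf)
    tptr <- c(0L, cumsum(tabulate(tf + 1L, nbins = M)))
    tcsr <- list(ptr = as.integer(tptr), a = as.integer(t1[ordt]),
                 b = as.integer(t2[ordt]))
  } else {
    tcsr <- list(ptr = integer(M + 1L), a = integer(0), b = integer(0))
  }
  list(M = M,
       layer_of = as.integer(match(mln$node_index$species,
                                   vapply(mln$layers, `[[`, "", "species_id"))),
       classes = classes,
       optr = o$ptr, oidx = o$idx, ow = if (is.null(o$w)) numeric(0) else o$w,
       tptr = tcsr$ptr, ta = tcsr$a, tb = tcsr$b,
       tw = params$kappa_triplet /
         (if (params$normalize_orthology && nrow(tri)) nrow(tri) else 1))
}

#' Annealing schedule
#'
#' @param cooling_factor Geometric cooling factor in (0,1); default 0.9.
#' @param stop_fliprate Stop once the per-sweep flipping rate falls below
#'   this (default 1%).
#' @param sweeps_per_temperature Full sweeps at each temperature (default 20).
#' @param group_sweeps_per_temperature Collective sweeps per temperature
#'   (default 1): each (layer, label) group is offered a heat-bath
#'   relabeling of the whole group, which lets fragments of a module
#'   coalesce and lets a crystallized module align with its orthologous
#'   counterpart in another layer; single-node moves alone face a barrier
#'   proportional to module size for both. 0 disables.
#' @param max_temperatures Guard on the number of cooling steps.
#' @param seed Integer seed; run r of an ensemble uses `seed + r - 1`.
#' @param target_initial_fliprate Flip rate the initial temperature must
#'   exceed; default `1 - 1/q` (set at calibration time).
#' @return List of class `anneal_schedule`.
#' @export
anneal_schedule <- function(cooling_factor = 0.9, stop_fliprate = 0.01,
                            sweeps_per_temperature = 20L,
                            group_sweeps_per_temperature = 1L,
                            max_temperatures = 1000L, seed = 1L,
                            target_initial_fliprate = NULL) {
  stopifnot(cooling_factor > 0, cooling_factor < 1,
            stop_fliprate > 0, stop_fliprate < 1,
            sweeps_per_temperature >= 1L, max_temperatures >= 1L,
            group_sweeps_per_temperature >= 0L)
  if (!is.null(target_initial_fliprate))
    stopifnot(stop_fliprate < target_initial_fliprate,
              target_initial_fliprate < 1)
  structure(list(cooling_factor = cooling_factor,
                 stop_fliprate = stop_fliprate,
                 sweeps_per_temperature = as.integer(sweeps_per_temperature),
                 group_sweeps_per_temperature =
                   as.integer(group_sweeps_per_temperature),
                 max_temperatures = as.integer(max_temperatures),
                 seed = as.integer(seed),
                 target_initial_fliprate = target_initial_fliprate),
            class = "anneal_schedule")
}

#' One heat-bath update of a single node
#'
#' Resamples the node's label from the Gibbs distribution of the local cost
#' at temperature T: label s is chosen with probability proportional to
#' exp(-H(s)/T), where H(s) is the total cost with only this node's label
#' varied (computed from local terms; overflow guarded by max-subtraction).
#' Uses R's random number stream.
#'
#' @param mln A `multilayer_network`.
#' @param sigma Current [labeling()].
#' @param node Global node index (1-based).
#' @param T Temperature (> 0).
#' @param params A [cost_params()].
#' @param inst Optional precompiled instance from repeated calls.
#' @return Sampled label (integer in 1..q).
#' @export
heat_bath_update <- function(mln, sigma, node, T, params = cost_params(),
                             inst = NULL) {
  stopifnot(T > 0)
  q <- attr(sigma, "q")
  if (is.null(q)) stop("sigma must be a labeling() with attribute q")
  if (is.null(inst)) inst <- mln_compile(mln, params)
  g <- cpp_local_gains(inst, as.integer(sigma), q, as.integer(node))
  p <- exp((g - max(g)) / T)
  sample.int(q, 1L, prob = p)
}

#' Calibrate the initial annealing temperature
#'
#' Doubling (or halving) search for the smallest temperature whose measured
#' per-sweep flipping rate, estimated over 3 sweeps from a random labeling,
#' exceeds the target rate `1 - 1/q`. The search trace (temperatures and
#' measured rates) is attached as attribute `"trace"`.
#'
#' @param mln A `multilayer_network`.
#' @param params A [cost_params()].
#' @param q Number of labels (>= 2).
#' @param schedule An [anneal_schedule()] (supplies the optional target
#'   override).
#' @param inst Optional precompiled instance.
#' @return Numeric T0 with attribute `trace`.
#' @export
calibrate_initial_temperature <- function(mln, params, q, schedule =
                                            anneal_schedule(), inst = NULL) {
  stopifnot(q >= 2L)
  if (is.null(inst)) inst <- mln_compile(mln, params)
  target <- schedule$target_initial_fliprate
  if (is.null(target)) target <- 1 - 1 / q
  sigma0 <- sample.int(q, inst$M, replace = TRUE)
  rate_at <- function(T) cpp_measure_fliprate(inst, sigma0, q, T, 3L)
  trace <- data.frame(T = numeric(), rate = numeric())
  T <- 1
  r <- rate_at(T)
  trace <- rbind(trace, data.frame(T = T, rate = r))
  steps <- 0L
  if (r > target) {
    repeat {
      Tlow <- T / 2
      rlow <- rate_at(Tlow)
      trace <- rbind(trace, data.frame(T = Tlow, rate = rlow))
      if (rlow <= target) break
      T <- Tlow; r <- rlow
      steps <- steps + 1L
      if (steps > 60L) stop("temperature calibration failed to bracket target")
    }
  } else {
    repeat {
      T <- T * 2
      r <- rate_at(T)
      trace <- rbind(trace, data.frame(T = T, rate = r))
      steps <- steps + 1L
      if (r > target) break
      if (steps > 60L) stop("temperature calibration failed after 60 doublings")
    }
  }
  structure(T, trace = trace)
}

#' One simulated-annealing run
#'
#' Labels are randomly initialized from the schedule seed; each temperature
#' runs `sweeps_per_temperature` full heat-bath sweeps in a fresh random
#' node order; the temperature is then multiplied by the cooling factor.
#' The run stops when the last sweep's flipping rate falls below
#' `stop_fliprate` (or the temperature guard is hit, in which case the
#' result is flagged non-converged). The returned labeling is the
#' minimum-cost configuration encountered, not necessarily the final one.
#'
#' @param mln A `multilayer_network`.
#' @param params A [cost_params()].
#' @param q Number of labels; choose generously, surplus labels die out.
#' @param schedule An [anneal_schedule()].
#' @param inst Optional precompiled instance (ensembles reuse one).
#' @return `anneal_result`: `labeling`, `final_cost`, `temperature_trace`
#'   (data frame T / flip_rate / cost), `seed`, `converged`.
#' @export
anneal <- function(mln, params = cost_params(), q = 50L,
                   schedule = anneal_schedule(), inst = NULL) {
  stopifnot(q >= 2L)
  if (is.null(inst)) inst <- mln_compile(mln, params)
  set.seed(schedule$seed)
  T0 <- calibrate_initial_temperature(mln, params, q, schedule, inst = inst)
  sigma0 <- sample.int(q, inst$M, replace = TRUE)
  res <- cpp_anneal(inst, sigma0, q, as.numeric(T0),
                    schedule$cooling_factor, schedule$stop_fliprate,
                    schedule$sweeps_per_temperature,
                    schedule$max_temperatures,
                    schedule$group_sweeps_per_temperature)
  if (!res$converged)
    warning("annealing hit max_temperatures before the stop flip rate")
  structure(list(labeling = labeling(res$sigma_best, q),
                 final_cost = res$cost_best,
                 temperature_trace = data.frame(T = res$trace_T,
                                                flip_rate = res$trace_fliprate,
                                                cost = res$trace_cost),
                 seed = schedule$seed, converged = res$converged),
            class = "anneal_result")
}

#' Ensemble of independent annealing runs
#'
#' Runs [anneal()] R times with seeds `seed, seed+1, ..., seed+R-1`. Because
#' every run seeds its own stream, parallel execution gives results
#' identical to serial execution.
#'
#' @inheritParams anneal
#' @param R Number of runs.
#' @param parallel Use `parallel::mclapply` over runs.
#' @return List of `anneal_result`, in seed order.
#' @export
run_ensemble <- function(mln, params = cost_params(), q = 50L,
                         schedule = anneal_schedule(), R = 32L,
                         parallel = FALSE) {
  stopifnot(R >= 1L)
  inst <- mln_compile(mln, params)
  one <- function(r) {
    sch <- schedule
    sch$seed <- schedule$seed + r - 1L
    anneal(mln, params, q, sch, inst = inst)
  }
  if (parallel) parallel::mclapply(seq_len(R), one)
  else lapply(seq_len(R), one)
}
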