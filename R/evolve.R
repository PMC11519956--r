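# Genetic-algorithm parametrization: population initialization, roulette-
# wheel selection, single-point crossover, adaptive Gaussian mutation,
# weighted-sum + EMD cost, and the generation loop with protocol tiers.

#' Default per-gene bounds for the six membrane force-field parameters
#'
#' epsilon is carried in kBT (converted at evaluation time); distances in
#' nm; bonded constants in kJ/mol/nm^2 and kJ/mol/rad^2.
#'
#' @return named list of \code{c(lo, hi)} per gene
#' @export
default_gene_bounds <- function() {
  list(epsilon = c(2, 10), r_min = c(0.7, 1.4), r1 = c(1.2, 2.2),
       rc = c(1.8, 3.0), k_bond = c(500, 5000), k_angle = c(50, 1000))
}

# enforce r_min < r1 < rc by sorting the violated triple, then re-clipping
repair_genome <- function(genes, bounds) {
  nm <- names(bounds)
  for (i in seq_along(nm))
    genes[i] <- min(max(genes[i], bounds[[i]][1]), bounds[[i]][2])
  geo <- match(c("r_min", "r1", "rc"), nm)
  if (!anyNA(geo)) {
    v <- sort(genes[geo])
    # keep strict ordering even after clipping collapses values
    for (k in 2:3) if (v[k] <= v[k - 1]) v[k] <- v[k - 1] + 1e-3
    genes[geo] <- v
  }
  names(genes) <- nm
  genes
}

#' Initialize a GA population
#'
#' Uniform sampling per gene within its bounds, with geometric repair
#' (\code{r_min < r1 < rc}); deterministic per seed.
#'
#' @param size population size (even, at least 4)
#' @param bounds named list of per-gene \code{c(lo, hi)}
#' @param seed seed
#' @return object of class \code{ga_population}: list with \code{genomes}
#'   (matrix, one row per genome), \code{cost} (NA until evaluated),
#'   \code{generation}, \code{sigmas}, \code{bounds}
#' @export
init_population <- function(size, bounds = default_gene_bounds(), seed = 1) {
  if (size %% 2 != 0 || size < 4) stop("population size must be even and >= 4")
  set.seed(seed)
  g <- vapply(bounds, function(b) stats::runif(size, b[1], b[2]),
              numeric(size))
  g <- t(apply(g, 1, repair_genome, bounds = bounds))
  colnames(g) <- names(bounds)
  structure(list(genomes = g, cost = rep(NA_real_, size), generation = 0L,
                 sigmas = NULL, bounds = bounds),
            class = "ga_population")
}

#' Target specification for the membrane parametrization
#'
#' Point targets, acceptance bands and cost weights for the seven
#' objectives: five scalars (area per lipid, area compressibility, line
#' tension, bending modulus, transition temperature) at weight 0.15 each,
#' and two distributions (tail-tail RDF, head density profile) compared by
#' EMD at weight 0.125 each; the weights sum to 1.
#'
#' @param rdf,density reference \code{profile_1d} objects
#' @return list of class \code{target_spec}
#' @export
target_spec <- function(rdf = reference_rdf(), density = reference_density()) {
  structure(list(
    targets = c(apl = 0.68, ka = 230, lt = 10, kc = 12, ptt = 270),
    bands = list(apl = c(0.55, 0.77), ka = c(180, 330), lt = c(6.5, 30),
                 kc = c(8, 42), ptt = c(250, 315)),
    w_scalar = 0.15, w_dist = 0.125,
    rdf = normalize_profile(rdf), density = normalize_profile(density)),
    class = "target_spec")
}

#' Weighted-sum cost of a property report
#'
#' \code{Cost1 = sum_i w1 (sim_i / target_i - 1)^2} over the scalar
#' properties measured by the report's tier, plus
#' \code{Cost2 = sum_i w2 EMD(sim_i, ref_i)} over the distributions.
#' A non-finite property marks the genome unfit (sentinel cost).
#'
#' @param report \code{property_report}
#' @param targets \code{target_spec}
#' @return list of class \code{cost_report} with per-term breakdown,
#'   \code{cost1}, \code{cost2}, \code{total}, \code{unfit}
#' @export
ga_cost <- function(report, targets) {
  scalars <- c(apl = report$apl, ka = report$ka, lt = report$lt,
               kc = report$kc, ptt = report$ptt)
  # NA marks "not measured by this tier"; NaN / Inf marks a failed run
  if (any(is.nan(scalars) | is.infinite(scalars)))
    return(structure(list(terms = NULL, cost1 = Inf, cost2 = Inf,
                          total = Inf, unfit = TRUE, tier = report$tier),
                     class = "cost_report"))
  present <- !is.na(scalars)
  terms <- targets$w_scalar *
    (scalars[present] / targets$targets[names(scalars)[present]] - 1)^2
  cost2 <- 0
  dterms <- numeric(0)
  if (!is.null(report$rdf)) {
    ref <- targets$rdf
    obs <- normalize_profile(resample_profile(report$rdf, ref$x))
    dterms["rdf"] <- targets$w_dist * emd(obs, ref)
  }
  if (!is.null(report$density)) {
    ref <- targets$density
    obs <- normalize_profile(resample_profile(report$density, ref$x))
    dterms["density"] <- targets$w_dist * emd(obs, ref)
  }
  cost1 <- sum(terms)
  cost2 <- sum(dterms)
  structure(list(terms = c(terms, dterms), cost1 = cost1, cost2 = cost2,
                 total = cost1 + cost2, unfit = FALSE, tier = report$tier),
            class = "cost_report")
}

#' Roulette-wheel selection
#'
#' Fitness-proportionate sampling by cumulative-probability inversion.
#' Fitness is the decreasing transform \code{F = 1 / (cost + delta)} so
#' lower-cost genomes get larger wheel segments; selection probabilities
#' are \code{P_i = F_i / sum F_j}.
#'
#' @param costs evaluated costs (finite; Inf marks unfit genomes, which get
#'   zero fitness)
#' @param n number of draws
#' @param seed seed
#' @param delta regularizer in the fitness transform
#' @return integer indices of the selected genomes
#' @export
select_rws <- function(costs, n, seed = 1, delta = 1e-6) {
  fit <- ifelse(is.finite(costs), 1 / (costs + delta), 0)
  if (all(fit == 0)) stop("all genomes unfit: cannot select")
  p <- fit / sum(fit)
  cum <- cumsum(p)
  set.seed(seed)
  u <- stats::runif(n)
  findInterval(u, cum, left.open = TRUE) + 1L
}

#' Single-point crossover
#'
#' A random cut point k in 1..(len-1); the children exchange the segments
#' beyond the cut, then undergo geometric repair.
#'
#' @param a,b parent gene vectors (equal length, named)
#' @param bounds per-gene bounds for repair
#' @param k cut point (drawn uniformly when NULL)
#' @param seed seed for the draw
#' @return list of two child gene vectors
#' @export
crossover_sp <- function(a, b, bounds = default_gene_bounds(), k = NULL,
                         seed = 1) {
  len <- length(a)
  if (len < 2) stop("genome too short for crossover")
  stopifnot(length(b) == len)
  if (is.null(k)) {
    set.seed(seed)
    k <- sample.int(len - 1, 1)
  }
  ca <- c(a[seq_len(k)], b[(k + 1):len])
  cb <- c(b[seq_len(k)], a[(k + 1):len])
  list(repair_genome(ca, bounds), repair_genome(cb, bounds))
}

#' Adaptive Gaussian mutation
#'
#' Each gene mutates independently with probability \code{pm}; an accepted
#' mutation adds \code{sigma_gene * N(0, 1)} where \code{sigma_gene} is the
#' per-gene spread of the previous generation (floored at 1% of the gene's
#' bound range). The result is clipped to bounds and geometry-repaired.
#'
#' @param genes named gene vector
#' @param sigmas per-gene standard deviations
#' @param pm mutation probability per gene
#' @param bounds per-gene bounds
#' @param seed seed
#' @return mutated gene vector
#' @export
mutate_adaptive_gaussian <- function(genes, sigmas, pm = 0.05,
                                     bounds = default_gene_bounds(), seed = 1) {
  stopifnot(pm >= 0, pm <= 1, all(sigmas >= 0))
  set.seed(seed)
  hit <- stats::runif(length(genes)) < pm
  if (any(hit))
    genes[hit] <- genes[hit] + sigmas[hit] * stats::rnorm(sum(hit))
  repair_genome(genes, bounds)
}

# per-gene sigma of a population, floored at 1% of the bound range
population_sigmas <- function(pop) {
  s <- apply(pop$genomes, 2, stats::sd)
  floor_s <- vapply(pop$bounds, function(b) 0.01 * (b[2] - b[1]), 0)
  pmax(s, floor_s)
}

#' Advance a population by one generation
#'
#' Evaluate unevaluated genomes, build a mating pool by roulette-wheel
#' selection, apply pairwise single-point crossover and adaptive Gaussian
#' mutation, replace unfit genomes with fresh random ones, and keep the
#' population size constant. With \code{elitism > 0} the best genomes pass
#' through unchanged.
#'
#' @param pop \code{ga_population}
#' @param evaluator function(genes, seed) -> cost (scalar) or a
#'   \code{cost_report}
#' @param pm mutation probability
#' @param elitism number of elite genomes preserved unchanged
#' @param seed seed for this generation's stochastic operators
#' @return the next \code{ga_population} (costs of new genomes NA)
#' @export
step_generation <- function(pop, evaluator, pm = 0.05, elitism = 0, seed = 1) {
  size <- nrow(pop$genomes)
  # evaluate (derived seeds bounded to keep 32-bit arithmetic exact)
  sb <- as.integer(abs(seed) %% 20000L)
  for (i in seq_len(size)) {
    if (is.na(pop$cost[i])) {
      res <- tryCatch(evaluator(pop$genomes[i, ], seed = sb * 1000L + i),
                      error = function(e) Inf)
      pop$cost[i] <- if (inherits(res, "cost_report")) res$total else res
    }
  }
  sigmas <- if (is.null(pop$sigmas)) population_sigmas(pop) else pop$sigmas
  elite_idx <- if (elitism > 0) order(pop$cost)[seq_len(elitism)] else integer(0)
  n_children <- size - length(elite_idx)
  parents <- select_rws(pop$cost, n_children + n_children %% 2, seed = seed)
  children <- matrix(NA_real_, 0, ncol(pop$genomes))
  for (k in seq_len(length(parents) / 2)) {
    pa <- pop$genomes[parents[2 * k - 1], ]
    pb <- pop$genomes[parents[2 * k], ]
    ch <- crossover_sp(pa, pb, pop$bounds, seed = sb * 7717L + k)
    ch[[1]] <- mutate_adaptive_gaussian(ch[[1]], sigmas, pm, pop$bounds,
                                        seed = sb * 33331L + 2 * k)
    ch[[2]] <- mutate_adaptive_gaussian(ch[[2]], sigmas, pm, pop$bounds,
                                        seed = sb * 33331L + 2 * k + 1)
    children <- rbind(children, ch[[1]], ch[[2]])
  }
  children <- children[seq_len(n_children), , drop = FALSE]
  # unfit parents were already excluded from the wheel; replace any unfit
  # child slots (evaluator failures surface next generation) by fresh draws
  new_genomes <- rbind(pop$genomes[elite_idx, , drop = FALSE], children)
  new_cost <- c(pop$cost[elite_idx], rep(NA_real_, n_children))
  colnames(new_genomes) <- colnames(pop$genomes)
  structure(list(genomes = new_genomes, cost = new_cost,
                 generation = pop$generation + 1L,
                 sigmas = population_sigmas(pop), bounds = pop$bounds),
            class = "ga_population")
}

#' Run the full evolutionary loop
#'
#' Iterates \code{step_generation} until the mean cost of the best decile
#' drops below \code{threshold} or \code{max_iters} generations elapse.
#'
#' @param evaluator function(genes, seed) -> cost or \code{cost_report}
#' @param pop_size population size (even)
#' @param bounds per-gene bounds
#' @param pm mutation probability
#' @param max_iters generation cap
#' @param threshold termination threshold on the top-decile mean cost
#' @param elitism elite count
#' @param seed master seed
#' @return list with \code{history} (data.frame: generation, best, mean,
#'   top_decile), \code{best_genes}, \code{best_cost}, \code{population}
#' @export
run_evolution <- function(evaluator, pop_size = 32,
                          bounds = default_gene_bounds(), pm = 0.05,
                          max_iters = 50, threshold = 0, elitism = 0,
                          seed = 1) {
  pop <- init_population(pop_size, bounds, seed)
  history <- NULL
  best_genes <- NULL
  best_cost <- Inf
  sb <- as.integer(abs(seed) %% 20000L)
  for (gen in seq_len(max_iters)) {
    # evaluate current generation (derived seeds bounded below 2^31)
    for (i in seq_len(pop_size)) {
      if (is.na(pop$cost[i])) {
        res <- tryCatch(evaluator(pop$genomes[i, ], seed = sb * 100000L + gen * 1000L + i),
                        error = function(e) Inf)
        pop$cost[i] <- if (inherits(res, "cost_report")) res$total else res
      }
    }
    finite <- pop$cost[is.finite(pop$cost)]
    ndec <- max(1, floor(pop_size / 10))
    top_decile <- mean(sort(finite)[seq_len(min(ndec, length(finite)))])
    if (min(pop$cost) < best_cost) {
      best_cost <- min(pop$cost)
      best_genes <- pop$genomes[which.min(pop$cost), ]
    }
    history <- rbind(history,
                     data.frame(generation = pop$generation,
                                best = min(finite), mean = mean(finite),
                                top_decile = top_decile))
    if (top_decile < threshold) break
    if (gen == max_iters) break
    pop <- step_generation(pop, evaluator, pm = pm, elitism = elitism,
                           seed = seed + gen)
  }
  list(history = history, best_genes = best_genes, best_cost = best_cost,
       population = pop)
}

#' Toy quadratic evaluator for GA sanity checks
#'
#' \code{cost = sum (gene_i - center_i)^2} over the (rescaled-to-[0,1])
#' genes; smooth, separable, minimum at the center.
#'
#' @param center target in rescaled units (recycled)
#' @param bounds the bounds used to rescale
#' @return evaluator function(genes, seed)
#' @export
evaluator_toy_quadratic <- function(center = 0.5,
                                    bounds = default_gene_bounds()) {
  lo <- vapply(bounds, `[`, 0, 1)
  hi <- vapply(bounds, `[`, 0, 2)
  function(genes, seed = 1) sum(((genes - lo) / (hi - lo) - center)^2)
}

#' Membrane evaluator with protocol tiers
#'
#' Builds a bilayer, runs tensionless Langevin dynamics with the candidate
#' parameters and measures the tier's properties: "smoke" (72 lipids, area
#' per lipid only), "desk" (128 lipids; APL, area compressibility, line
#' tension, RDF and density profile), "full" (all seven properties, large
#' systems and long runs). Genes named as in \code{default_gene_bounds};
#' missing genes fall back to the reference set.
#'
#' @param tier protocol tier
#' @param targets \code{target_spec}
#' @param equil_steps,prod_steps override the tier's step counts
#' @param temperature temperature, K
#' @return evaluator function(genes, seed) -> \code{cost_report}
#' @export
evaluator_membrane <- function(tier = c("smoke", "desk", "full"),
                               targets = target_spec(),
                               equil_steps = NULL, prod_steps = NULL,
                               temperature = 315) {
  tier <- match.arg(tier)
  defaults <- list(smoke = c(n = 36, eq = 4000, pr = 8000),
                   desk = c(n = 64, eq = 30000, pr = 60000),
                   full = c(n = 512, eq = 100000, pr = 400000))[[tier]]
  eq <- equil_steps %||% defaults["eq"]
  pr <- prod_steps %||% defaults["pr"]
  ref <- ff_reference(temperature)
  gene <- function(genes, nm, fallback)
    if (nm %in% names(genes)) genes[[nm]] else fallback
  function(genes, seed = 1) {
    p <- forcefield_params(
      epsilon = kbt_to_kjmol(gene(genes, "epsilon", kjmol_to_kbt(ref$epsilon)),
                             temperature),
      r_min = gene(genes, "r_min", ref$r_min),
      r1 = gene(genes, "r1", ref$r1),
      rc = gene(genes, "rc", ref$rc),
      k_bond = gene(genes, "k_bond", ref$k_bond),
      k_angle = gene(genes, "k_angle", ref$k_angle))
    sys <- build_bilayer(defaults[["n"]], p)
    sys <- minimize(sys, p, max_steps = 200)
    cfg_eq <- sim_config(temperature = temperature, n_steps = eq,
                         barostat = "semi-isotropic-xy", seed = seed,
                         report_interval = max(eq %/% 10, 1))
    sys <- run_ld(sys, p, cfg_eq)$system
    cfg_pr <- sim_config(temperature = temperature, n_steps = pr,
                         barostat = "semi-isotropic-xy", seed = seed + 1,
                         report_interval = 25,
                         snapshot_interval = if (tier == "smoke") 0 else max(pr %/% 50, 1))
    out <- run_ld(sys, p, cfg_pr)
    apl <- area_per_lipid(out$frames, defaults[["n"]])$apl
    # reject configurations that stopped being a bilayer: heads at midplane
    rep <- if (tier == "smoke") {
      property_report(apl = apl, tier = tier)
    } else {
      ka <- area_compressibility(out$frames, temperature)$ka
      rdf <- lateral_rdf(out$snapshots, out$system$types, out$system$box)
      den <- density_profile(out$snapshots, out$system$types,
                             out$system$masses, out$system$box)
      property_report(apl = apl, ka = ka, rdf = rdf, density = den,
                      tier = tier)
    }
    ga_cost(rep, targets)
  }
}

# NULL-coalescing access for possibly-missing named genes
`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
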