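# The generation loop: initialisation, phase schedule, one-generation step,
# and the full run with logging and snapshots.

#' Initialise the founder population
#'
#' Creates `popSize` diploid genomes with every preference allele drawn
#' uniformly from `initWeightRange` (default (-1, 1), a standard perceptron
#' initialisation producing non-discriminating phenotypes with high
#' preference for every niche) and all mating alleles set to r, which is what
#' enforces random mating during the first phase.
#'
#' @param config a [SimulationConfig-class].
#' @return an [ExploiterPop-class] of founders.
#' @export
initPopulation <- function(config = simulationConfig()) {
  n <- config@popSize
  if (n < 1L) stop("popSize must be positive")
  L <- nLoci(config@nHidden)
  lo <- config@initWeightRange[1]; hi <- config@initWeightRange[2]
  hapA <- matrix(stats::runif(n * L, lo, hi), n, L)
  hapB <- matrix(stats::runif(n * L, lo, hi), n, L)
  exploiterPop(hapA, hapB, matA = "r", matB = "r")
}

#' Mutation flags for a generation under the three-phase schedule
#'
#' Phase 1 (generation < `matingMutStart`): mating-gene mutation off, point
#' mutation and crossover on — random mating is enforced because the founder
#' population is all-rr and the r allele cannot mutate.  Phase 2
#' (`matingMutStart` <= generation < `mutStop`): all mutational processes on.
#' Phase 3 (generation >= `mutStop`): point and mating-gene mutations off so
#' that selection alone sorts standing variation; crossover is retained by
#' default (recombination is not a mutation) unless `retainCrossover` is
#' FALSE.
#'
#' @param generation integer generation index (0-based).
#' @param config a [SimulationConfig-class].
#' @return named logical vector with elements `matingMut`, `pointMut`,
#'   `crossover`.
#' @export
phaseFlags <- function(generation, config = simulationConfig()) {
  stopifnot(generation >= 0)
  if (generation < config@matingMutStart) {
    c(matingMut = FALSE, pointMut = TRUE, crossover = TRUE)
  } else if (generation < config@mutStop) {
    c(matingMut = TRUE, pointMut = TRUE, crossover = TRUE)
  } else {
    c(matingMut = FALSE, pointMut = FALSE,
      crossover = config@retainCrossover)
  }
}

#' Phenotype classes of single haplotypes expressed as homozygotes
#'
#' A haplotype's "own" phenotype is what it would express in homozygous form
#' (codominant expression of two identical haplotypes is the haplotype
#' itself).  Comparing the two haplotype classes within an individual gives a
#' phenotypic heterozygosity measure that needs no reference haplotypes.
#'
#' @param pop an [ExploiterPop-class].
#' @param env a [SimEnvironment-class].
#' @param omega sigmoid gain.
#' @return list with `clsA`, `clsB` (binary class matrices of the two
#'   haplotypes) and `het` (logical; TRUE where the classes differ).
#' @export
haplotypePhenotypes <- function(pop, env = simEnvironment(), omega = 4) {
  clsA <- classifyPhenotype(perceptronResponse(pop@hapA, signalSet(env),
                                               omega = omega))
  clsB <- classifyPhenotype(perceptronResponse(pop@hapB, signalSet(env),
                                               omega = omega))
  list(clsA = clsA, clsB = clsB, het = rowSums(clsA != clsB) > 0)
}

allClassLabels <- function(K) {
  apply(as.matrix(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE],
        1, paste0, collapse = "")
}

#' Summarise one generation
#'
#' Builds the per-generation record row: population size, abundance of every
#' binary phenotype class, mating-allele frequencies, count of phenotypic
#' heterozygotes (individuals whose two haplotypes express different classes
#' in homozygous form), and the count of unfit phenotypes (classes preferring
#' at least one unsuitable niche).
#'
#' @param pop an [ExploiterPop-class].
#' @param config a [SimulationConfig-class].
#' @param generation integer generation index.
#' @return one-row data.frame.
#' @export
generationRecord <- function(pop, config = simulationConfig(),
                             generation = 0L) {
  env <- config@environment
  K <- nrow(signalSet(env))
  labs <- allClassLabels(K)
  n <- nInd(pop)
  if (n > 0) {
    cls <- classifyPhenotype(responseArray(pop, env, omega = config@omega))
    counts <- table(factor(phenotypeLabels(cls), levels = labs))
    alleles <- c(pop@matA, pop@matB)
    freqA <- mean(alleles == "a")
    het <- sum(haplotypePhenotypes(pop, env, config@omega)$het)
    unfit <- sum(rowSums(cls[, !suitability(env), drop = FALSE] == 1L) > 0)
  } else {
    counts <- stats::setNames(rep(0L, length(labs)), labs)
    freqA <- NA_real_; het <- 0L; unfit <- 0L
  }
  rec <- data.frame(generation = as.integer(generation), popSize = n,
                    freqR = 1 - freqA, freqA = freqA,
                    hetPhen = as.integer(het), unfit = as.integer(unfit))
  cnt <- as.data.frame(as.list(as.integer(counts)))
  names(cnt) <- paste0("n", labs)
  cbind(rec, cnt)
}

#' Advance the population by one generation
#'
#' Composes the full life cycle: response arrays for all individuals (Eq. of
#' the perceptron), reproductive-output allocation, niche totals,
#' density-dependent fitness, mating-pool assignment, sequential pair
#' formation, offspring counts (each parent of a pair is assigned the nearest
#' integer to the pair's mean fitness, so a pair recruits twice that count),
#' and gamete formation under the generation's mutation flags.  Offspring
#' replace their parents (non-overlapping generations).
#'
#' Random draws occur in a fixed documented order — pool sampling, pairing,
#' then gametes (first-parent preference gametes, second-parent preference
#' gametes, first-parent mating gametes, second-parent mating gametes) — so a
#' run is fully reproducible from (seed, config).
#'
#' @param pop an [ExploiterPop-class], the current generation.
#' @param config a [SimulationConfig-class].
#' @param generation integer generation index (drives [phaseFlags()]).
#' @return list with `pop` (the next generation, possibly with 0 individuals)
#'   and `extinct` (logical; TRUE when no offspring were produced).
#' @export
stepGeneration <- function(pop, config = simulationConfig(),
                           generation = 0L) {
  env <- config@environment
  n <- nInd(pop)
  if (n < 1L) return(list(pop = pop, extinct = TRUE))
  psi <- responseArray(pop, env, omega = config@omega)
  e <- reproductiveOutput(psi, phi = config@ecology@phi)
  E <- nicheTotals(e)
  f <- fitnessValues(e, E, env, config@ecology)
  cls <- classifyPhenotype(psi)
  behavior <- expressedMating(pop, aDominant = config@aDominant)
  pools <- assignPools(cls, behavior)
  pairs <- formPairs(pools, strictP0 = config@strictP0)
  if (nrow(pairs) == 0L)
    return(list(pop = pop[0], extinct = TRUE))
  # each parent of a pair is assigned round(mean pair fitness) recruits, so a
  # pair contributes twice the per-parent count; phi is a per-parent maximum
  counts <- 2L * offspringCount(f[pairs[, 1]], f[pairs[, 2]])
  keep <- counts > 0L
  if (!any(keep)) return(list(pop = pop[0], extinct = TRUE))
  mothers <- rep(pairs[keep, 1], counts[keep])
  fathers <- rep(pairs[keep, 2], counts[keep])
  flags <- phaseFlags(generation, config)
  off <- makeOffspring(pop, mothers, fathers, config@rates,
                       pointMut = flags[["pointMut"]],
                       crossover = flags[["crossover"]],
                       matingMut = flags[["matingMut"]])
  list(pop = off, extinct = FALSE)
}

#' Run a full simulation
#'
#' Seeds the RNG from the config, initialises the founder population, and
#' iterates [stepGeneration()] for `generations` steps (default
#' `config@endGen`) or until extinction.  The per-generation record stream
#' starts with the initial state (generation 0); full-genome snapshots are
#' kept every `snapshotEvery` generations (always including generation 0 and
#' the final generation when snapshots are enabled).
#'
#' @param config a [SimulationConfig-class].
#' @param generations optional override of the number of generations.
#' @param recordEvery cadence of record rows (default 1 = every generation).
#' @param verbose print progress every 1000 generations.
#' @return a [SimulationResult-class].
#' @examples
#' cfg <- simulationConfig(popSize = 60, endGen = 30, matingMutStart = 10,
#'                         mutStop = 20, snapshotEvery = 10, seed = 7)
#' res <- runSimulation(cfg)
#' head(records(res))
#' @export
runSimulation <- function(config = simulationConfig(), generations = NULL,
                          recordEvery = 1L, verbose = FALSE) {
  validObject(config)
  G <- if (is.null(generations)) config@endGen else as.integer(generations)
  set.seed(config@seed)
  pop <- initPopulation(config)
  recs <- vector("list", G %/% recordEvery + 2L)
  snaps <- list()
  ri <- 1L
  recs[[ri]] <- generationRecord(pop, config, 0L)
  if (config@snapshotEvery > 0L) snaps[["0"]] <- pop
  termination <- "completed"
  gen <- 0L
  while (gen < G) {
    stp <- stepGeneration(pop, config, gen)
    pop <- stp$pop
    gen <- gen + 1L
    if (gen %% recordEvery == 0L || gen == G || stp$extinct) {
      ri <- ri + 1L
      recs[[ri]] <- generationRecord(pop, config, gen)
    }
    if (config@snapshotEvery > 0L &&
        (gen %% config@snapshotEvery == 0L || gen == G) && nInd(pop) > 0L)
      snaps[[as.character(gen)]] <- pop
    if (stp$extinct) { termination <- "extinct"; break }
    if (verbose && gen %% 1000L == 0L)
      message(sprintf("generation %d: N = %d", gen, nInd(pop)))
  }
  new("SimulationResult",
      records = do.call(rbind, recs[seq_len(ri)]),
      snapshots = snaps, config = config, seed = config@seed,
      termination = termination)
}

#' Run replicate simulations over a set of seeds
#'
#' @param config a [SimulationConfig-class] (its seed slot is overridden).
#' @param seeds integer vector of seeds, one replicate per seed.
#' @param ... passed to [runSimulation()].
#' @return named list of [SimulationResult-class] objects (names = seeds).
#' @export
replicateRuns <- function(config = simulationConfig(), seeds = 1:10, ...) {
  out <- lapply(seeds, function(s) {
    cfg <- config
    cfg@seed <- as.integer(s)
    runSimulation(cfg, ...)
  })
  names(out) <- as.character(seeds)
  out
}
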