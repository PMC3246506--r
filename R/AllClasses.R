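#' @import methods
NULL

# locus layout ---------------------------------------------------------------

#' Locus names for a preference haplotype
#'
#' A preference haplotype carries, for each hidden node j, the triple
#' (w1j, w2j, bhj) followed by the output weights wout_j of every node and the
#' single output bias bo.  With `nHidden` hidden nodes the haplotype has
#' `4 * nHidden + 1` loci; the default perceptron (3 hidden nodes) has 13.
#'
#' @param nHidden integer, number of hidden nodes.
#' @return character vector of locus names in chromosomal order.
#' @examples
#' locusNames(3)
#' @export
locusNames <- function(nHidden = 3L) {
  stopifnot(nHidden >= 1)
  j <- seq_len(nHidden)
  c(as.vector(rbind(paste0("w1", j), paste0("w2", j), paste0("bh", j))),
    paste0("wout", j), "bo")
}

#' Number of preference loci for a given hidden-layer size
#' @param nHidden integer, number of hidden nodes.
#' @return integer locus count (13 for the default 3-node perceptron).
#' @export
nLoci <- function(nHidden = 3L) 4L * as.integer(nHidden) + 1L

# SimEnvironment -------------------------------------------------------------

#' SimEnvironment: the selective landscape
#'
#' Holds the resource (carrying-capacity) values N_k, the two-channel signal
#' set through which consumers perceive each resource, and the threshold above
#' which a resource counts as suitable.  The default is the four-niche
#' environment with resources [250, 0.01, 250, 0.01] and signals lined up on
#' the diagonal of the unit signal square:
#' (0.2, 0.8), (0.4, 0.6), (0.6, 0.4), (0.8, 0.2).
#'
#' @slot resourceValues numeric vector of carrying capacities N_k (> 0; the
#'   value 0.01 marks an unsuitable niche while avoiding division by zero).
#' @slot signals numeric matrix with one row per resource and two columns
#'   (s_k1, s_k2), every entry in \[0, 1\].
#' @slot suitabilityThreshold numeric scalar; niche k is suitable when
#'   `resourceValues[k] >= suitabilityThreshold`.
#' @export
setClass("SimEnvironment",
  representation(
    resourceValues = "numeric",
    signals = "matrix",
    suitabilityThreshold = "numeric"
  )
)

setValidity("SimEnvironment", function(object) {
  msg <- character()
  n <- length(object@resourceValues)
  if (n < 1) msg <- c(msg, "at least one resource is required")
  if (any(!is.finite(object@resourceValues)) || any(object@resourceValues <= 0))
    msg <- c(msg, "resourceValues must be finite and > 0")
  if (!is.numeric(object@signals) || ncol(object@signals) != 2L)
    msg <- c(msg, "signals must be a numeric matrix with 2 columns")
  if (nrow(object@signals) != n)
    msg <- c(msg, "signals must have one row per resource")
  if (any(!is.finite(object@signals)) ||
      any(object@signals < 0) || any(object@signals > 1))
    msg <- c(msg, "signal channel values must lie in [0, 1]")
  if (length(object@suitabilityThreshold) != 1L ||
      !is.finite(object@suitabilityThreshold))
    msg <- c(msg, "suitabilityThreshold must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation environment
#'
#' @param resourceValues carrying capacities N_k; defaults to
#'   `c(250, 0.01, 250, 0.01)` (two suitable, two unsuitable niches).
#' @param signals numeric matrix (one row per resource, columns s_k1 and
#'   s_k2); defaults to the diagonal arrangement
#'   `(0.2,0.8), (0.4,0.6), (0.6,0.4), (0.8,0.2)`.
#' @param suitabilityThreshold resources at or above this value count as
#'   suitable (default 1, separating 250 from 0.01).
#' @return a [SimEnvironment-class] object.
#' @examples
#' env <- simEnvironment()
#' suitability(env)
#' @export
simEnvironment <- function(resourceValues = c(250, 0.01, 250, 0.01),
                           signals = defaultSignals(length(resourceValues)),
                           suitabilityThreshold = 1) {
  new("SimEnvironment",
      resourceValues = as.numeric(resourceValues),
      signals = signals,
      suitabilityThreshold = as.numeric(suitabilityThreshold))
}

#' Default diagonal signal set
#'
#' Places `n` resources evenly along the anti-diagonal of the unit signal
#' square, s_k2 = 1 - s_k1, the arrangement that makes discrimination hardest.
#' For n = 4 this is (0.2,0.8), (0.4,0.6), (0.6,0.4), (0.8,0.2).
#'
#' @param n number of resources.
#' @return an n x 2 numeric matrix of signal channel values.
#' @export
defaultSignals <- function(n = 4L) {
  s1 <- seq_len(n) / (n + 1)
  m <- cbind(s1 = s1, s2 = 1 - s1)
  rownames(m) <- paste0("niche", seq_len(n))
  m
}

# EcologyParams ---------------------------------------------------------------

#' EcologyParams: reproduction and competition constants
#'
#' @slot phi maximum reproductive output per individual before density
#'   dependence (default 3).
#' @slot eps half-saturation coefficient: the total reproductive output in a
#'   niche at which the density-dependent discount reaches one half, in
#'   proportion to the niche carrying capacity (default 1.5).
#' @slot abruptness Hill-type exponent controlling how sharply the discount
#'   switches on around the half-saturation density (default 2.5).
#' @export
setClass("EcologyParams",
  representation(phi = "numeric", eps = "numeric", abruptness = "numeric"))

setValidity("EcologyParams", function(object) {
  msg <- character()
  for (s in c("phi", "eps", "abruptness")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a finite scalar > 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct ecology parameters
#' @param phi maximum reproductive output (default 3).
#' @param eps half-saturation coefficient (default 1.5).
#' @param abruptness onset abruptness of density dependence (default 2.5).
#' @return an [EcologyParams-class] object.
#' @export
ecologyParams <- function(phi = 3, eps = 1.5, abruptness = 2.5) {
  new("EcologyParams", phi = as.numeric(phi), eps = as.numeric(eps),
      abruptness = as.numeric(abruptness))
}

# MutationRates ---------------------------------------------------------------

#' MutationRates: recombination and mutation constants
#'
#' @slot crossoverPerLocus per-locus probability that gamete copying switches
#'   template haplotype (default 1e-4).
#' @slot pointMutPerAllele per-allele point-mutation probability on the
#'   preference chromosome (default 0.01).
#' @slot perturbRange range of the uniform additive weight perturbation
#'   (default (-10, 10)).
#' @slot alleleRange hard clamp applied to mutated weights
#'   (default (-20, 20)).
#' @slot matingMutRate probability that a copied mating allele flips r <-> a
#'   (default 5e-4).
#' @export
setClass("MutationRates",
  representation(
    crossoverPerLocus = "numeric",
    pointMutPerAllele = "numeric",
    perturbRange = "numeric",
    alleleRange = "numeric",
    matingMutRate = "numeric"
  )
)

setValidity("MutationRates", function(object) {
  msg <- character()
  for (s in c("crossoverPerLocus", "pointMutPerAllele", "matingMutRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0, 1]", s))
  }
  for (s in c("perturbRange", "alleleRange")) {
    v <- slot(object, s)
    if (length(v) != 2L || any(!is.finite(v)) || v[1] >= v[2])
      msg <- c(msg, sprintf("%s must be an increasing pair of finite values", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct mutation/recombination rates
#' @param crossoverPerLocus per-locus template-switch probability
#'   (default 1e-4).
#' @param pointMutPerAllele per-allele point-mutation probability
#'   (default 0.01).
#' @param perturbRange uniform perturbation range (default `c(-10, 10)`).
#' @param alleleRange clamp interval for weight values (default `c(-20, 20)`).
#' @param matingMutRate mating-allele flip probability (default 5e-4).
#' @return a [MutationRates-class] object.
#' @export
mutationRates <- function(crossoverPerLocus = 1e-4,
                          pointMutPerAllele = 0.01,
                          perturbRange = c(-10, 10),
                          alleleRange = c(-20, 20),
                          matingMutRate = 5e-4) {
  new("MutationRates",
      crossoverPerLocus = as.numeric(crossoverPerLocus),
      pointMutPerAllele = as.numeric(pointMutPerAllele),
      perturbRange = as.numeric(perturbRange),
      alleleRange = as.numeric(alleleRange),
      matingMutRate = as.numeric(matingMutRate))
}

# ExploiterPop ----------------------------------------------------------------

#' ExploiterPop: a population of diploid exploiters
#'
#' One generation of individuals.  Each individual carries two preference
#' haplotypes (rows of `hapA` and `hapB`; the storage order of the two
#' chromosomes is preserved, which is what later duplicates heterozygotes into
#' AB and BA clouds in genotype-space PCA) and two alleles at the unlinked
#' mating gene (`"r"` random / `"a"` assortative).
#'
#' @slot hapA numeric matrix, one row per individual, one column per locus:
#'   first preference haplotype.
#' @slot hapB numeric matrix of identical shape: second preference haplotype.
#' @slot matA character vector of first mating alleles ("r" or "a").
#' @slot matB character vector of second mating alleles ("r" or "a").
#' @export
setClass("ExploiterPop",
  representation(
    hapA = "matrix",
    hapB = "matrix",
    matA = "character",
    matB = "character"
  )
)

setValidity("ExploiterPop", function(object) {
  msg <- character()
  n <- nrow(object@hapA)
  if (!identical(dim(object@hapA), dim(object@hapB)))
    msg <- c(msg, "hapA and hapB must have identical dimensions")
  if ((ncol(object@hapA) - 1L) %% 4L != 0L)
    msg <- c(msg, "haplotype length must be 4 * nHidden + 1 (13 by default)")
  if (length(object@matA) != n || length(object@matB) != n)
    msg <- c(msg, "one pair of mating alleles per individual is required")
  if (n > 0 && (!all(object@matA %in% c("r", "a")) ||
                !all(object@matB %in% c("r", "a"))))
    msg <- c(msg, "mating alleles must be 'r' or 'a'")
  if (any(!is.finite(object@hapA)) || any(!is.finite(object@hapB)))
    msg <- c(msg, "preference alleles must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an exploiter population
#'
#' @param hapA,hapB numeric matrices of preference alleles (individuals x
#'   loci); a single haplotype may be given as a numeric vector.
#' @param matA,matB character vectors of mating alleles ("r"/"a"); scalars are
#'   recycled.
#' @return an [ExploiterPop-class] object.
#' @examples
#' pop <- exploiterPop(hapA = matrix(0, 2, 13), hapB = matrix(0, 2, 13))
#' nInd(pop)
#' @export
exploiterPop <- function(hapA, hapB, matA = "r", matB = "r") {
  if (is.null(dim(hapA))) hapA <- matrix(hapA, nrow = 1)
  if (is.null(dim(hapB))) hapB <- matrix(hapB, nrow = 1)
  storage.mode(hapA) <- "double"
  storage.mode(hapB) <- "double"
  n <- nrow(hapA)
  if ((ncol(hapA) - 1L) %% 4L != 0L)
    stop("haplotype length must be 4 * nHidden + 1 (13 by default)")
  colnames(hapA) <- colnames(hapB) <- locusNames((ncol(hapA) - 1L) %/% 4L)
  new("ExploiterPop", hapA = hapA, hapB = hapB,
      matA = rep_len(as.character(matA), n),
      matB = rep_len(as.character(matB), n))
}

# SimulationConfig ------------------------------------------------------------

#' SimulationConfig: everything that determines a run
#'
#' A run is fully determined by (config, seed): the environment, ecology and
#' mutation constants, population initialisation, the three-phase mutation
#' schedule, and logging cadence.
#'
#' The phase schedule follows the study design: mating-gene mutations are
#' disabled for the first `matingMutStart` generations (enforcing random
#' mating via the all-`r` initial population), enabled until `mutStop`, after
#' which all mutations are switched off for the remaining generations up to
#' `endGen` so that selection alone sorts the standing variation.
#'
#' @slot popSize initial population size (default 500).
#' @slot nHidden hidden-layer size of the perceptron (default 3).
#' @slot initWeightRange uniform range for initial preference alleles
#'   (default (-1, 1)).
#' @slot omega sigmoid gain of the perceptron activation (default 4).
#' @slot environment a [SimEnvironment-class].
#' @slot ecology an [EcologyParams-class].
#' @slot rates a [MutationRates-class].
#' @slot matingMutStart first generation at which mating-gene mutation is
#'   allowed (default 20000).
#' @slot mutStop generation at which all mutations stop (default 80000).
#' @slot endGen total number of generations (default 100000).
#' @slot aDominant logical; TRUE makes the assortative allele a dominant over
#'   r (default), FALSE reverses dominance.
#' @slot strictP0 logical; FALSE (default) lets a randomly mating individual
#'   drawn first pick its partner from the whole population, TRUE restricts
#'   the partner to pool p0.
#' @slot retainCrossover logical; TRUE (default) keeps recombination active
#'   after `mutStop` (crossover is not a mutation), FALSE disables it too.
#' @slot snapshotEvery cadence (in generations) of full-genome snapshots
#'   (default 1000; 0 disables snapshots).
#' @slot seed integer RNG seed for the run.
#' @export
setClass("SimulationConfig",
  representation(
    popSize = "integer",
    nHidden = "integer",
    initWeightRange = "numeric",
    omega = "numeric",
    environment = "SimEnvironment",
    ecology = "EcologyParams",
    rates = "MutationRates",
    matingMutStart = "integer",
    mutStop = "integer",
    endGen = "integer",
    aDominant = "logical",
    strictP0 = "logical",
    retainCrossover = "logical",
    snapshotEvery = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@popSize < 1L) msg <- c(msg, "popSize must be >= 1")
  if (object@nHidden < 1L) msg <- c(msg, "nHidden must be >= 1")
  if (length(object@initWeightRange) != 2L ||
      object@initWeightRange[1] >= object@initWeightRange[2])
    msg <- c(msg, "initWeightRange must be an increasing pair")
  if (length(object@omega) != 1L || !is.finite(object@omega) ||
      object@omega <= 0)
    msg <- c(msg, "omega must be a finite scalar > 0")
  if (object@matingMutStart < 0L || object@mutStop < object@matingMutStart ||
      object@endGen < object@mutStop)
    msg <- c(msg, "phase boundaries must satisfy 0 <= matingMutStart <= mutStop <= endGen")
  if (object@snapshotEvery < 0L) msg <- c(msg, "snapshotEvery must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' All defaults are the reference parameterisation of the model: 500 founders
#' with preference alleles uniform on (-1, 1) and mating genotype rr,
#' resources \[250, 0.01, 250, 0.01\] with the diagonal signal set, phi = 3,
#' eps = 1.5, abruptness = 2.5, crossover 1e-4 per locus, point mutation 0.01
#' per allele with uniform (-10, 10) perturbations clamped to (-20, 20),
#' mating-gene mutation 5e-4, and the 20000 / 80000 / 100000 phase schedule.
#'
#' @param popSize,nHidden,initWeightRange,omega see
#'   [SimulationConfig-class].
#' @param environment a [SimEnvironment-class].
#' @param ecology an [EcologyParams-class].
#' @param rates a [MutationRates-class].
#' @param matingMutStart,mutStop,endGen phase boundaries (generations).
#' @param aDominant,strictP0,retainCrossover behaviour flags, see
#'   [SimulationConfig-class].
#' @param snapshotEvery snapshot cadence in generations (0 = none).
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(popSize = 100, endGen = 500,
#'                         matingMutStart = 100, mutStop = 400)
#' @export
simulationConfig <- function(popSize = 500L,
                             nHidden = 3L,
                             initWeightRange = c(-1, 1),
                             omega = 4,
                             environment = simEnvironment(),
                             ecology = ecologyParams(),
                             rates = mutationRates(),
                             matingMutStart = 20000L,
                             mutStop = 80000L,
                             endGen = 100000L,
                             aDominant = TRUE,
                             strictP0 = FALSE,
                             retainCrossover = TRUE,
                             snapshotEvery = 1000L,
                             seed = 1L) {
  new("SimulationConfig",
      popSize = as.integer(popSize),
      nHidden = as.integer(nHidden),
      initWeightRange = as.numeric(initWeightRange),
      omega = as.numeric(omega),
      environment = environment,
      ecology = ecology,
      rates = rates,
      matingMutStart = as.integer(matingMutStart),
      mutStop = as.integer(mutStop),
      endGen = as.integer(endGen),
      aDominant = isTRUE(aDominant),
      strictP0 = isTRUE(strictP0),
      retainCrossover = isTRUE(retainCrossover),
      snapshotEvery = as.integer(snapshotEvery),
      seed = as.integer(seed))
}

# SimulationResult ------------------------------------------------------------

#' SimulationResult: the outputs of one run
#'
#' @slot records data.frame of per-generation summaries (one row per logged
#'   generation, starting with the initial state at generation 0).
#' @slot snapshots named list of [ExploiterPop-class] objects, names are the
#'   generation indices at which the snapshot was taken.
#' @slot config the [SimulationConfig-class] that produced the run.
#' @slot seed the integer seed actually used.
#' @slot termination character, `"completed"` or `"extinct"`.
#' @export
setClass("SimulationResult",
  representation(
    records = "data.frame",
    snapshots = "list",
    config = "SimulationConfig",
    seed = "integer",
    termination = "character"
  )
)
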