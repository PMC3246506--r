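# Generics and accessors for the core classes.

#' Number of individuals in a population
#' @param x an [ExploiterPop-class].
#' @return integer count.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname nInd
#' @export
setMethod("nInd", "ExploiterPop", function(x) nrow(x@hapA))

#' Preference haplotypes of a population
#'
#' @param x an [ExploiterPop-class].
#' @param which `"A"`, `"B"`, or `"stacked"` (both haplotypes stacked row-wise,
#'   all A rows first — the layout used for haplotype-space PCA).
#' @return numeric matrix of allele values.
#' @export
setGeneric("prefHaplotypes", function(x, which = c("A", "B", "stacked"))
  standardGeneric("prefHaplotypes"))

#' @rdname prefHaplotypes
#' @export
setMethod("prefHaplotypes", "ExploiterPop", function(x, which = c("A", "B", "stacked")) {
  which <- match.arg(which)
  switch(which, A = x@hapA, B = x@hapB, stacked = rbind(x@hapA, x@hapB))
})

#' Mating alleles of a population
#' @param x an [ExploiterPop-class].
#' @return character matrix with columns `matA`, `matB`.
#' @export
setGeneric("matingAlleles", function(x) standardGeneric("matingAlleles"))

#' @rdname matingAlleles
#' @export
setMethod("matingAlleles", "ExploiterPop",
          function(x) cbind(matA = x@matA, matB = x@matB))

#' Subset a population by individual
#' @param x an [ExploiterPop-class].
#' @param i integer or logical index of individuals.
#' @param j,drop,... ignored.
#' @return an [ExploiterPop-class] with the selected individuals.
#' @export
setMethod("[", "ExploiterPop", function(x, i, j, ..., drop = FALSE) {
  new("ExploiterPop",
      hapA = x@hapA[i, , drop = FALSE],
      hapB = x@hapB[i, , drop = FALSE],
      matA = x@matA[i], matB = x@matB[i])
})

#' Niche suitability of an environment
#' @param x a [SimEnvironment-class].
#' @return logical vector, TRUE where N_k is at or above the suitability
#'   threshold.
#' @export
setGeneric("suitability", function(x) standardGeneric("suitability"))

#' @rdname suitability
#' @export
setMethod("suitability", "SimEnvironment",
          function(x) x@resourceValues >= x@suitabilityThreshold)

#' Resource carrying capacities of an environment
#' @param x a [SimEnvironment-class].
#' @return numeric vector N_k.
#' @export
setGeneric("resourceValues", function(x) standardGeneric("resourceValues"))

#' @rdname resourceValues
#' @export
setMethod("resourceValues", "SimEnvironment", function(x) x@resourceValues)

#' Signal set of an environment
#' @param x a [SimEnvironment-class].
#' @return numeric matrix, one row (s_k1, s_k2) per resource.
#' @export
setGeneric("signalSet", function(x) standardGeneric("signalSet"))

#' @rdname signalSet
#' @export
setMethod("signalSet", "SimEnvironment", function(x) x@signals)

#' Per-generation records of a run
#' @param x a [SimulationResult-class].
#' @return data.frame of generation summaries.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "SimulationResult", function(x) x@records)

#' Genome snapshots of a run
#' @param x a [SimulationResult-class].
#' @return named list of [ExploiterPop-class] objects (names = generation).
#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))

#' @rdname snapshots
#' @export
setMethod("snapshots", "SimulationResult", function(x) x@snapshots)

setMethod("show", "SimEnvironment", function(object) {
  cat("SimEnvironment with", length(object@resourceValues), "niches\n")
  cat("  N_k        :", paste(object@resourceValues, collapse = ", "), "\n")
  cat("  suitable   :", paste(ifelse(suitability(object), "yes", "no"),
                              collapse = ", "), "\n")
  cat("  signals    :",
      paste(apply(object@signals, 1, function(s)
        sprintf("(%g, %g)", s[1], s[2])), collapse = " "), "\n")
})

setMethod("show", "ExploiterPop", function(object) {
  n <- nInd(object)
  cat("ExploiterPop:", n, "diploid individuals,",
      ncol(object@hapA), "preference loci per haplotype\n")
  if (n > 0) {
    fa <- mean(c(object@matA, object@matB) == "a")
    cat(sprintf("  mating-allele frequencies: r = %.3f, a = %.3f\n",
                1 - fa, fa))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  popSize %d | nHidden %d | omega %g | seed %d\n",
              object@popSize, object@nHidden, object@omega, object@seed))
  cat(sprintf("  phases: mating mutation from %d, all mutations stop %d, end %d\n",
              object@matingMutStart, object@mutStop, object@endGen))
  cat(sprintf("  ecology: phi %g, eps %g, abruptness %g\n",
              object@ecology@phi, object@ecology@eps,
              object@ecology@abruptness))
  cat(sprintf("  rates: crossover %g/locus, point mut %g/allele, mating mut %g\n",
              object@rates@crossoverPerLocus, object@rates@pointMutPerAllele,
              object@rates@matingMutRate))
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", nrow(object@records) - 1L, "generations,",
      "termination:", object@termination, "\n")
  cat("  final population size:",
      object@records$popSize[nrow(object@records)], "\n")
  cat("  snapshots at:", paste(utils::head(names(object@snapshots), 10),
                               collapse = ", "),
      if (length(object@snapshots) > 10) "...", "\n")
})
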