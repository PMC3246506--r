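# Gamete formation: crossover, point mutation, the mating gene, and the
# Mendelian expectation used as an oracle.

#' Form preference-chromosome gametes
#'
#' For each requested gamete a template haplotype is chosen uniformly from the
#' parent's two chromosomes; loci are then copied in chromosomal order, with
#' the template switching to the homologous chromosome with probability
#' `crossoverPerLocus` at every locus (a template-switching walk, so linkage
#' between neighbouring loci is preserved).  If point mutation is enabled,
#' each copied allele then independently mutates with probability
#' `pointMutPerAllele` by adding a perturbation drawn uniformly from
#' `perturbRange`, and the result is clamped to `alleleRange`.
#'
#' Vectorised: `parents` indexes rows of the population, one gamete per entry.
#'
#' @param pop an [ExploiterPop-class] holding the parents.
#' @param parents integer vector of parent row indices (one gamete each).
#' @param rates a [MutationRates-class].
#' @param pointMut logical, enable point mutations.
#' @param crossover logical, enable crossover (template switching).
#' @return numeric matrix of gametes (length(parents) x loci).
#' @export
makePreferenceGametes <- function(pop, parents, rates = mutationRates(),
                                  pointMut = TRUE, crossover = TRUE) {
  m <- length(parents)
  L <- ncol(pop@hapA)
  if (m == 0L) return(matrix(numeric(0), 0L, L,
                             dimnames = list(NULL, colnames(pop@hapA))))
  A <- pop@hapA[parents, , drop = FALSE]
  B <- pop@hapB[parents, , drop = FALSE]
  start <- sample.int(2L, m, replace = TRUE) - 1L  # 0 -> hapA template
  if (crossover && rates@crossoverPerLocus > 0) {
    sw <- matrix(stats::runif(m * L) < rates@crossoverPerLocus, m, L)
    cum <- sw
    for (l in seq_len(L)[-1L]) cum[, l] <- cum[, l - 1L] + cum[, l]
  } else {
    cum <- matrix(0L, m, L)
  }
  useB <- (start + cum) %% 2L == 1L
  g <- A
  g[useB] <- B[useB]
  if (pointMut && rates@pointMutPerAllele > 0) {
    mut <- matrix(stats::runif(m * L) < rates@pointMutPerAllele, m, L)
    nm <- sum(mut)
    if (nm > 0L) {
      pert <- stats::runif(nm, rates@perturbRange[1], rates@perturbRange[2])
      g[mut] <- pmin(pmax(g[mut] + pert,
                          rates@alleleRange[1]), rates@alleleRange[2])
    }
  }
  g
}

#' Form mating-gene gametes
#'
#' Each gamete receives one of the parent's two mating alleles, chosen
#' uniformly; when mating-gene mutation is enabled the copied allele flips
#' r <-> a with probability `matingMutRate`.
#'
#' @param pop an [ExploiterPop-class] holding the parents.
#' @param parents integer vector of parent row indices (one gamete each).
#' @param rates a [MutationRates-class].
#' @param matingMut logical, enable mating-gene mutation.
#' @return character vector of mating alleles ("r"/"a").
#' @export
makeMatingGametes <- function(pop, parents, rates = mutationRates(),
                              matingMut = FALSE) {
  m <- length(parents)
  if (m == 0L) return(character(0))
  pick <- sample.int(2L, m, replace = TRUE)
  al <- ifelse(pick == 1L, pop@matA[parents], pop@matB[parents])
  if (matingMut && rates@matingMutRate > 0) {
    flip <- stats::runif(m) < rates@matingMutRate
    al[flip] <- ifelse(al[flip] == "r", "a", "r")
  }
  al
}

#' Produce offspring genomes from paired parents
#'
#' Each offspring receives one preference gamete and one mating gamete from
#' each parent.  The gamete from the first parent of the pair is stored as
#' haplotype A and the second parent's as haplotype B, so chromosome storage
#' order records parental origin.
#'
#' @param pop an [ExploiterPop-class] holding the parents.
#' @param mothers,fathers integer vectors of parent row indices, one entry
#'   per offspring (repeat indices for multiple offspring of one pair).
#' @param rates a [MutationRates-class].
#' @param pointMut,crossover,matingMut logicals controlling which mutational
#'   processes are active (see [phaseFlags()]).
#' @return an [ExploiterPop-class] of offspring.
#' @export
makeOffspring <- function(pop, mothers, fathers, rates = mutationRates(),
                          pointMut = TRUE, crossover = TRUE,
                          matingMut = FALSE) {
  stopifnot(length(mothers) == length(fathers))
  hapA <- makePreferenceGametes(pop, mothers, rates, pointMut, crossover)
  hapB <- makePreferenceGametes(pop, fathers, rates, pointMut, crossover)
  matA <- makeMatingGametes(pop, mothers, rates, matingMut)
  matB <- makeMatingGametes(pop, fathers, rates, matingMut)
  new("ExploiterPop", hapA = hapA, hapB = hapB, matA = matA, matB = matB)
}

#' Mendelian expectation for a single cross
#'
#' Exact offspring genotype distribution for parents whose haplotypes are
#' labelled with reference letters (e.g. parent "AB" carries reference
#' haplotypes A and B), ignoring crossover and mutation.  Offspring genotype
#' classes are unordered ("AB" == "BA"), matching a Punnett square: an
#' AB x AB cross yields AA : AB : BB = 1 : 2 : 1.
#'
#' Used as the independent oracle against which empirical [makeOffspring()]
#' frequencies are tested.
#'
#' @param g1,g2 character vectors of length 2: the haplotype labels of each
#'   parent, e.g. `c("A", "B")`.
#' @return named numeric vector of genotype-class probabilities.
#' @examples
#' punnettExpectation(c("A", "B"), c("A", "B"))  # AA 0.25, AB 0.5, BB 0.25
#' @export
punnettExpectation <- function(g1, g2) {
  stopifnot(length(g1) == 2L, length(g2) == 2L)
  if (!is.character(g1) || !is.character(g2))
    stop("parents must be given as pairs of haplotype labels")
  combos <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
  cls <- apply(combos, 1, function(x) paste(sort(x), collapse = ""))
  tab <- table(cls) / length(cls)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}
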