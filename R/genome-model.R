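# Genotype -> phenotype map: codominant expression, perceptron forward pass,
# phenotype classification, and expression of the mating gene.

#' Codominant expression of the preference chromosome pair
#'
#' The expressed perceptron weight at each locus is the mean of the two
#' allelic values, recomputed on demand from the haplotypes so expression can
#' never go stale after mutation.
#'
#' @param pop an [ExploiterPop-class].
#' @return numeric matrix (individuals x loci) of expressed weights.
#' @examples
#' pop <- fixtureGenomes("specialist1", 2)
#' expressPreference(pop)[, 1:4]
#' @export
expressPreference <- function(pop) {
  stopifnot(is(pop, "ExploiterPop"))
  (pop@hapA + pop@hapB) / 2
}

#' Perceptron forward pass
#'
#' Propagates each niche signal through the 2-input / nHidden / 1-output
#' perceptron encoded by a row of expressed weights.  For hidden node j the
#' internal activity is `xi_j = s1*w1j + s2*w2j - bhj` and its output is
#' `theta_j = sigma(omega * xi_j)` with `sigma` the logistic function; the
#' output node computes `xi_out = sum_j theta_j * wout_j - bo` and responds
#' `psi = sigma(omega * xi_out)`.  With the default gain omega = 4 a negative
#' activity yields an output close to 0 and a positive one close to 1, while
#' psi remains strictly inside (0, 1) for finite weights.
#'
#' @param weights numeric matrix (individuals x loci) of expressed weights in
#'   chromosomal locus order, or a single weight vector.
#' @param signals numeric matrix of niche signals (rows = niches, columns =
#'   the two channels), or a single `c(s1, s2)` pair.
#' @param omega sigmoid gain (default 4).
#' @return numeric matrix (individuals x niches) of responses psi in (0, 1).
#' @examples
#' perceptronResponse(rep(0, 13), c(0.2, 0.8))  # symmetric zero case: 0.5
#' @export
perceptronResponse <- function(weights, signals, omega = 4) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  stopifnot(ncol(signals) == 2L, omega > 0)
  if (any(!is.finite(weights))) stop("non-finite perceptron weight")
  L <- ncol(weights)
  if ((L - 1L) %% 4L != 0L)
    stop("weight vector length must be 4 * nHidden + 1")
  h <- (L - 1L) %/% 4L
  i1 <- 3L * seq_len(h) - 2L            # w1j
  i2 <- i1 + 1L                         # w2j
  ib <- i1 + 2L                         # bhj
  io <- 3L * h + seq_len(h)             # wout_j
  W1 <- weights[, i1, drop = FALSE]
  W2 <- weights[, i2, drop = FALSE]
  Bh <- weights[, ib, drop = FALSE]
  Wo <- weights[, io, drop = FALSE]
  bo <- weights[, L]
  psi <- matrix(NA_real_, nrow(weights), nrow(signals))
  for (k in seq_len(nrow(signals))) {
    xi <- signals[k, 1] * W1 + signals[k, 2] * W2 - Bh
    theta <- stats::plogis(omega * xi)
    xiOut <- rowSums(theta * Wo) - bo
    psi[, k] <- stats::plogis(omega * xiOut)
  }
  colnames(psi) <- rownames(signals)
  psi
}

#' Response array of a population over an environment's signal set
#'
#' Expresses each genome codominantly and propagates every niche signal
#' through its perceptron, one resource at a time, giving the response array
#' Psi = (psi_1, ..., psi_K) per individual.
#'
#' @param pop an [ExploiterPop-class].
#' @param env a [SimEnvironment-class] (its signal set is used).
#' @param omega sigmoid gain (default 4).
#' @return numeric matrix (individuals x niches) of responses.
#' @examples
#' responseArray(fixtureGenomes("generalist", 1), simEnvironment())
#' @export
responseArray <- function(pop, env = simEnvironment(), omega = 4) {
  perceptronResponse(expressPreference(pop), signalSet(env), omega = omega)
}

#' Classify response arrays into binary phenotype classes
#'
#' Each response is rounded to the nearest integer, giving one of 2^K binary
#' phenotype classes (16 in the four-niche environment); e.g. `[0,0,1,0]` is
#' the niche-III specialist and `[1,1,1,1]` the non-discriminating generalist.
#' The tie psi = 0.5 rounds up to 1 (a measure-zero event for continuous
#' weights, but fixed deterministically).
#'
#' @param psi numeric matrix of responses in \[0, 1\] (individuals x niches),
#'   or a single response vector.
#' @return integer matrix of 0/1 phenotype bits, same shape.
#' @examples
#' classifyPhenotype(c(0.1, 0.2, 0.9, 0.3))  # niche-III specialist
#' @export
classifyPhenotype <- function(psi) {
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = 1)
  cls <- floor(psi + 0.5)
  storage.mode(cls) <- "integer"
  cls
}

#' Compact labels for binary phenotype classes
#' @param cls integer matrix of phenotype bits (rows = individuals).
#' @return character vector like `"1000"`, `"1010"`.
#' @export
phenotypeLabels <- function(cls) {
  if (is.null(dim(cls))) cls <- matrix(cls, nrow = 1)
  apply(cls, 1, paste0, collapse = "")
}

#' Expressed mating behaviour of each individual
#'
#' The mating gene is biallelic (r = random, a = assortative) with complete
#' dominance; by default a dominates r, so rr expresses random mating and
#' ra/ar/aa assortative mating.  `aDominant = FALSE` reverses the dominance.
#'
#' @param pop an [ExploiterPop-class].
#' @param aDominant logical (default TRUE).
#' @return character vector, `"random"` or `"assortative"` per individual.
#' @examples
#' pop <- exploiterPop(matrix(0, 2, 13), matrix(0, 2, 13),
#'                     matA = c("r", "r"), matB = c("r", "a"))
#' expressedMating(pop)
#' @export
expressedMating <- function(pop, aDominant = TRUE) {
  hasA <- pop@matA == "a" | pop@matB == "a"
  hasR <- pop@matA == "r" | pop@matB == "r"
  if (aDominant) ifelse(hasA, "assortative", "random")
  else ifelse(hasR, "random", "assortative")
}
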