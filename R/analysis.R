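# Analysis battery: unfit-phenotype statistics, the likelihood-ratio
# (maximum-likelihood chi-square) G-test, the mutation-robustness resampling
# assay, PCA clustering of haplotypes/genotypes, and trajectory smoothing.

#' Fraction of unfit phenotypes
#'
#' A phenotype is unfit when its binary class shows preference (a 1-bit) for
#' at least one unsuitable niche.
#'
#' @param cls integer matrix of binary phenotype classes (individuals x
#'   niches) or a single class vector.
#' @param suitable logical vector of niche suitability (from
#'   [suitability()]).
#' @return proportion of unfit individuals.
#' @examples
#' unfitFraction(rbind(c(1,0,0,0), c(0,1,0,0)), c(TRUE, FALSE, TRUE, FALSE))
#' @export
unfitFraction <- function(cls, suitable) {
  if (is.null(dim(cls))) cls <- matrix(cls, nrow = 1)
  if (nrow(cls) == 0L) stop("empty phenotype list")
  stopifnot(length(suitable) == ncol(cls))
  mean(rowSums(cls[, !suitable, drop = FALSE] == 1L) > 0)
}

#' Maximum-likelihood chi-square (G-test) on a 2x2 table
#'
#' Likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` with expectations E
#' from the independence model (row x column margins / total); the p-value is
#' from the chi-square distribution with 1 degree of freedom.  Zero cells
#' contribute 0 to the sum; a zero row or column margin makes the
#' independence model degenerate and is an error.
#'
#' @param tab 2x2 numeric matrix of counts (group x outcome).
#' @return list with elements `G`, `p`, and `df` (= 1).
#' @examples
#' mlChi2(matrix(c(312, 260, 1914, 1986), 2))
#' @export
mlChi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero row or column marginal")
  E <- outer(rs, cs) / n
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(terms)
  list(G = G, p = stats::pchisq(G, df = 1L, lower.tail = FALSE), df = 1L)
}

#' Mutation-robustness resampling assay
#'
#' Quantifies how fragile a genotype pool's phenotype is to single point
#' mutations.  From a pool of P genomes, `K = P * (P - 1)` mutants are
#' generated by sampling individuals with replacement and applying one
#' point mutation — a uniform perturbation from `perturbRange`, clamped to
#' `alleleRange`, exactly as in the simulation — at one random locus of one
#' random haplotype.  The assay reports the baseline unfit count in the pool,
#' the unfit percentage among the K mutants, the expected unfit count after
#' mutation (`round(percentage * P)`), and the increase as a percentage of
#' the original count.
#'
#' @param pool an [ExploiterPop-class]: one genotype class, P >= 2.
#' @param env a [SimEnvironment-class].
#' @param rates a [MutationRates-class] (perturbation and clamp ranges).
#' @param omega sigmoid gain.
#' @param K optional override of the number of mutants (default P*(P-1)).
#' @return list with `P`, `K`, `baselineUnfit` (count),
#'   `baselineUnfitPct`, `mutantUnfitPct`, `expectedUnfit` (count),
#'   `increasePct` (NA when the baseline count is 0 and mutants are unfit).
#' @export
robustnessTest <- function(pool, env = simEnvironment(),
                           rates = mutationRates(), omega = 4, K = NULL) {
  P <- nInd(pool)
  if (P < 2L) stop("robustness assay needs a pool of at least 2 genomes")
  if (is.null(K)) K <- P * (P - 1L)
  suit <- suitability(env)
  baseCls <- classifyPhenotype(responseArray(pool, env, omega = omega))
  baseUnfit <- sum(rowSums(baseCls[, !suit, drop = FALSE] == 1L) > 0)

  idx <- sample.int(P, K, replace = TRUE)
  L <- ncol(pool@hapA)
  hapA <- pool@hapA[idx, , drop = FALSE]
  hapB <- pool@hapB[idx, , drop = FALSE]
  whichHap <- sample.int(2L, K, replace = TRUE)
  locus <- sample.int(L, K, replace = TRUE)
  pert <- stats::runif(K, rates@perturbRange[1], rates@perturbRange[2])
  sel <- cbind(seq_len(K), locus)
  onA <- whichHap == 1L
  hapA[sel[onA, , drop = FALSE]] <-
    pmin(pmax(hapA[sel[onA, , drop = FALSE]] + pert[onA],
              rates@alleleRange[1]), rates@alleleRange[2])
  hapB[sel[!onA, , drop = FALSE]] <-
    pmin(pmax(hapB[sel[!onA, , drop = FALSE]] + pert[!onA],
              rates@alleleRange[1]), rates@alleleRange[2])
  mutants <- exploiterPop(hapA, hapB)
  mutCls <- classifyPhenotype(responseArray(mutants, env, omega = omega))
  mutUnfitPct <- 100 * mean(rowSums(mutCls[, !suit, drop = FALSE] == 1L) > 0)
  expectedUnfit <- as.integer(round(mutUnfitPct / 100 * P))
  increase <- if (baseUnfit > 0) {
    100 * (expectedUnfit - baseUnfit) / baseUnfit
  } else if (expectedUnfit == 0L) 0 else NA_real_
  list(P = P, K = as.integer(K), baselineUnfit = as.integer(baseUnfit),
       baselineUnfitPct = 100 * baseUnfit / P,
       mutantUnfitPct = mutUnfitPct,
       expectedUnfit = expectedUnfit, increasePct = increase)
}

#' PCA scores and centroid clustering of haplotype or genotype rows
#'
#' Principal-component analysis of allele-value rows — 13-dimensional
#' haplotypes, or 26-dimensional genotypes formed by concatenating the two
#' stored haplotypes (storage order preserved, which is why a heterozygote
#' appears as two mirror-image clouds, AB and BA) — followed by k-means
#' clustering.  When `k` is omitted it is chosen by mean silhouette width
#' over k = 2..6, falling back to a single cluster when the rows are
#' (near-)identical.
#'
#' @param mat numeric matrix of haplotype or genotype rows.
#' @param k number of clusters; NULL for silhouette selection.
#' @param npc number of principal components to return (default 2).
#' @return list with `scores` (rows x npc), `cluster` (integer labels),
#'   `k`, and `sdev` (component standard deviations).
#' @export
pcaCluster <- function(mat, k = NULL, npc = 2L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  if (!is.null(k) && k > nrow(mat)) stop("more clusters than rows")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  npc <- min(npc, ncol(pc$x))
  scores <- pc$x[, seq_len(npc), drop = FALSE]
  totVar <- sum(pc$sdev^2)
  if (totVar < 1e-12) {
    return(list(scores = scores, cluster = rep(1L, nrow(mat)), k = 1L,
                sdev = pc$sdev))
  }
  if (is.null(k)) {
    kmax <- min(6L, nrow(unique(mat)) - 1L)
    if (kmax < 2L) {
      km <- stats::kmeans(mat, centers = unique(mat), iter.max = 50)
      return(list(scores = scores, cluster = km$cluster,
                  k = nrow(unique(mat)), sdev = pc$sdev))
    }
    best <- NULL; bestSil <- -Inf
    d <- stats::dist(mat)
    for (kk in 2:kmax) {
      km <- stats::kmeans(mat, centers = kk, nstart = 5, iter.max = 50)
      sil <- mean(cluster::silhouette(km$cluster, d)[, 3])
      if (sil > bestSil) { bestSil <- sil; best <- km }
    }
    km <- best; k <- length(km$size)
  } else {
    km <- stats::kmeans(mat, centers = k, nstart = 5, iter.max = 50)
  }
  list(scores = scores, cluster = km$cluster, k = as.integer(k),
       sdev = pc$sdev)
}

#' Running-average smoothing of phenotype-class trajectories
#'
#' Centred running mean over `window` generations, emitted every `stride`
#' generations; series whose maximum never exceeds `threshold` individuals
#' are dropped (the display rule for abundance trajectories).
#'
#' @param series numeric matrix or data.frame of per-generation counts (rows
#'   = generations, columns = phenotype classes), or a single series.
#' @param window running-mean window in generations (default 80).
#' @param stride emit every `stride`-th generation (default 20).
#' @param threshold keep only series exceeding this count at least once
#'   (default 80); use `-Inf` to keep all.
#' @return data.frame with a `generation` column (centre of each window) and
#'   one column per retained series.
#' @export
smoothCounts <- function(series, window = 80L, stride = 20L,
                         threshold = 80) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1,
                                             dimnames = list(NULL, "series"))
  series <- as.matrix(series)
  n <- nrow(series)
  window <- as.integer(window)
  if (window > n) stop("window longer than the series")
  keep <- apply(series, 2, max) > threshold
  kept <- series[, keep, drop = FALSE]
  # centred window: index i averages rows [i - floor((w-1)/2), i + ceil((w-1)/2)]
  back <- (window - 1L) %/% 2L
  lo <- seq_len(n) - back
  hi <- lo + window - 1L
  valid <- which(lo >= 1L & hi <= n)
  centre <- valid[(valid - valid[1]) %% stride == 0L]
  runMean <- function(x) {
    cs <- c(0, cumsum(x))
    (cs[hi[centre] + 1L] - cs[lo[centre]]) / window
  }
  out <- data.frame(generation = centre - 1L)
  for (j in seq_len(ncol(kept)))
    out[[colnames(kept)[j]]] <- runMean(kept[, j])
  out
}

#' Analytic per-generation mutation-event expectations
#'
#' For a census of `nIndividuals` diploid individuals, one generation of
#' reproduction draws about `2 * nIndividuals` gametes of each chromosome
#' type.  The expected numbers of mutational events are then exact binomial
#' expectations: mating-gene flips `= gametes * matingMutRate`; preference
#' gametes carrying at least one point mutation
#' `= gametes * (1 - (1 - pointMutPerAllele)^L)`; gametes with at least one
#' crossover `= gametes * (1 - (1 - crossoverPerLocus)^L)`.  At the model's
#' typical census of ~400 individuals these are 0.4, ~98 ("around 100") and
#' ~1.04 ("about one") respectively.
#'
#' @param nIndividuals census size (default 400).
#' @param rates a [MutationRates-class].
#' @param nLociPerHap loci per preference haplotype (default 13).
#' @return named list: `gametes`, `matingMutations`, `pointMutatedGametes`,
#'   `crossoverGametes`.
#' @export
mutationEventExpectations <- function(nIndividuals = 400,
                                      rates = mutationRates(),
                                      nLociPerHap = 13L) {
  g <- 2 * nIndividuals
  list(gametes = g,
       matingMutations = g * rates@matingMutRate,
       pointMutatedGametes = g * (1 - (1 - rates@pointMutPerAllele)^nLociPerHap),
       crossoverGametes = g * (1 - (1 - rates@crossoverPerLocus)^nLociPerHap))
}

#' Summarise the genetic structure of a population
#'
#' Clusters the stacked haplotypes into two groups (k-means on raw allele
#' values) and, when the two clusters are well separated, labels every
#' individual's genotype as AA, AB, or BB by the cluster membership of its
#' two haplotypes.  The phenotype expressed by each cluster centroid in
#' homozygous and heterozygous combination determines whether a two-haplotype
#' polymorphism is present and whether it is of the "type" form in which the
#' heterozygote expresses the same phenotype as one of the homozygotes.
#'
#' Separation is judged by mean silhouette width of the 2-cluster solution
#' (>= `minSilhouette`); with fewer than two effective haplotype clusters the
#' population is reported monomorphic.
#'
#' @param pop an [ExploiterPop-class].
#' @param env a [SimEnvironment-class].
#' @param omega sigmoid gain.
#' @param minSilhouette separation threshold (default 0.6).
#' @param minMinorFreq minimum frequency of the minor haplotype cluster for a
#'   polymorphism call (default 0.1).
#' @return list with `polymorphic` (logical), `typePolymorphism` (logical:
#'   the heterozygote's modal phenotype equals that of exactly one
#'   homozygote), `silhouette`, `genotype` (per-individual AA/AB/BB labels or
#'   NULL), `genotypePhenotypes` (modal phenotype label per genotype group),
#'   `clusterPhenotypes` (classes of AA-, AB-, BB-centroid genotypes),
#'   `haplotypeFreq` (frequencies of the two clusters).
#' @export
polymorphismSummary <- function(pop, env = simEnvironment(), omega = 4,
                                minSilhouette = 0.6, minMinorFreq = 0.1) {
  n <- nInd(pop)
  if (n < 4L) stop("population too small to summarise")
  haps <- prefHaplotypes(pop, "stacked")
  # subsample for the distance matrix when large
  km <- stats::kmeans(haps, centers = 2L, nstart = 5, iter.max = 50)
  sub <- if (nrow(haps) > 600L) sample.int(nrow(haps), 600L) else
    seq_len(nrow(haps))
  sil <- tryCatch(
    mean(cluster::silhouette(km$cluster[sub], stats::dist(haps[sub, ]))[, 3]),
    error = function(e) 0)
  freq <- as.numeric(table(factor(km$cluster, levels = 1:2))) / nrow(haps)
  polymorphic <- sil >= minSilhouette && min(freq) >= minMinorFreq
  if (!polymorphic) {
    return(list(polymorphic = FALSE, typePolymorphism = FALSE,
                silhouette = sil, genotype = NULL,
                clusterPhenotypes = NULL, haplotypeFreq = freq))
  }
  cA <- km$centers[1, ]; cB <- km$centers[2, ]
  combo <- rbind(AA = cA, AB = (cA + cB) / 2, BB = cB)
  cls <- classifyPhenotype(perceptronResponse(combo, signalSet(env),
                                              omega = omega))
  rownames(cls) <- rownames(combo)
  gA <- km$cluster[seq_len(n)]
  gB <- km$cluster[n + seq_len(n)]
  genotype <- c("AA", "AB", "BB")[gA + gB - 1L]
  # type the polymorphism by the modal observed phenotype of each genotype
  # group (falling back to the centroid phenotype for absent groups)
  indLab <- phenotypeLabels(
    classifyPhenotype(perceptronResponse(expressPreference(pop),
                                         signalSet(env), omega = omega)))
  lab <- phenotypeLabels(cls)
  names(lab) <- rownames(cls)
  for (g in c("AA", "AB", "BB")) {
    if (any(genotype == g)) {
      t <- table(indLab[genotype == g])
      lab[g] <- names(t)[which.max(t)]
    }
  }
  typePoly <- lab["AA"] != lab["BB"] &&
    (lab["AB"] == lab["AA"] || lab["AB"] == lab["BB"])
  list(polymorphic = TRUE, typePolymorphism = unname(typePoly),
       silhouette = sil, genotype = genotype,
       genotypePhenotypes = lab,
       clusterPhenotypes = cls, haplotypeFreq = freq)
}
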