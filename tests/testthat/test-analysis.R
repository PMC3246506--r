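test_that("unfit phenotypes are those preferring any unsuitable niche", {
  suit <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(unfitFraction(c(1, 1, 0, 0), suit), 1)   # prefers niche II
  expect_equal(unfitFraction(c(1, 0, 1, 0), suit), 0)   # suitable only
  expect_equal(unfitFraction(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), suit), 0.5)
  expect_error(unfitFraction(matrix(integer(0), 0, 4), suit), "empty")
})

test_that("the G statistic matches an independent log-linear fit", {
  expect_equal(mlChi2(matrix(c(50, 50, 50, 50), 2))$G, 0)
  set.seed(13)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 80) + 1, 2)
    res <- mlChi2(tab)
    ref <- MASS::loglm(~ 1 + 2, data = tab)$lrt
    expect_equal(res$G, ref, tolerance = 1e-8)
    expect_gte(res$G, 0)
    expect_equal(res$p, pchisq(res$G, 1, lower.tail = FALSE))
    # G scales linearly with total count at fixed proportions
    expect_equal(mlChi2(2 * tab)$G, 2 * res$G, tolerance = 1e-8)
  }
  expect_error(mlChi2(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("robustness assay sizes and a robust pool under small perturbations", {
  # niche-1 specialists have comfortable activation margins, so perturbations
  # bounded by 0.1 can never flip a response bit: increase is exactly 0
  pool <- fixtureGenomes("specialist1", 10)
  tiny <- mutationRates(perturbRange = c(-0.1, 0.1))
  set.seed(2)
  res <- robustnessTest(pool, simEnvironment(), tiny)
  expect_equal(res$P, 10L)
  expect_equal(res$K, 90L)
  expect_equal(res$baselineUnfit, 0L)
  expect_equal(res$increasePct, 0)

  # the all-niche generalist is unfit by definition (prefers niches II/IV)
  gen <- fixtureGenomes("generalist", 5)
  set.seed(3)
  expect_equal(robustnessTest(gen, simEnvironment(), tiny)$baselineUnfit, 5L)

  expect_equal(robustnessTest(fixtureGenomes("specialist1", 2), rates = tiny)$K, 2L)
  expect_error(robustnessTest(fixtureGenomes("specialist1", 1)), "at least 2")
})

test_that("robustness assay matches an exhaustive single-mutation scan", {
  # fragile pool: specialist1 homozygotes whose node-1 bias sits near the
  # decision boundary; estimate the unfit probability of a random
  # single-site mutation by fine-grained enumeration and compare
  pool <- fixtureGenomes("specialist1", 40)
  env <- simEnvironment()
  rates <- mutationRates()
  w0 <- pool@hapA[1, ]
  suit <- suitability(env)
  pertGrid <- seq(-9.995, 9.995, by = 0.01)
  unfitProb <- 0
  for (locus in 1:13) {
    base <- perceptsim::expressPreference(pool[1])[1, ]
    hits <- vapply(pertGrid, function(d) {
      hap <- w0; hap[locus] <- min(max(hap[locus] + d, -20), 20)
      w <- (hap + w0) / 2  # mutation on one of the two identical haplotypes
      cls <- classifyPhenotype(perceptronResponse(w, signalSet(env)))
      any(cls[, !suit] == 1L)
    }, logical(1))
    unfitProb <- unfitProb + mean(hits) / 13
  }
  set.seed(3)
  res <- robustnessTest(pool, env, rates)
  expect_equal(res$mutantUnfitPct / 100, unfitProb, tolerance = 0.05)
})

test_that("PCA clustering recovers known haplotype and genotype structure", {
  set.seed(4)
  cloudA <- matrix(rnorm(50 * 13, mean = 5, sd = 0.3), 50)
  cloudB <- matrix(rnorm(50 * 13, mean = -5, sd = 0.3), 50)
  res <- pcaCluster(rbind(cloudA, cloudB), k = 2)
  labels <- res$cluster
  expect_true(all(labels[1:50] == labels[1]) &&
              all(labels[51:100] == labels[51]) &&
              labels[1] != labels[51])
  # silhouette selection finds the same k
  auto <- pcaCluster(rbind(cloudA, cloudB))
  expect_equal(auto$k, 2L)

  # identical rows collapse to one effective cluster
  same <- matrix(1, 30, 13)
  one <- pcaCluster(same)
  expect_equal(one$k, 1L)
  expect_equal(length(unique(one$cluster)), 1L)

  expect_error(pcaCluster(matrix(0, 3, 13), k = 5), "more clusters")
})

test_that("genotype-space PCA separates AA, BB and the two heterozygote orderings", {
  hapA <- rep(2, 13); hapB <- rep(-2, 13)
  jit <- function(h, n) matrix(rep(h, each = n), n) +
    matrix(rnorm(n * 13, 0, 0.05), n)
  set.seed(5)
  pops <- rbind(
    cbind(jit(hapA, 30), jit(hapA, 30)),   # AA
    cbind(jit(hapB, 30), jit(hapB, 30)),   # BB
    cbind(jit(hapA, 15), jit(hapB, 15)),   # AB
    cbind(jit(hapB, 15), jit(hapA, 15)))   # BA (same genotype, other order)
  res <- pcaCluster(pops, k = 4)
  truth <- rep(1:4, c(30, 30, 15, 15))
  # each true group maps to exactly one cluster
  expect_equal(length(unique(paste(truth, res$cluster))), 4L)
})

test_that("trajectory smoothing: constants, thresholds, and ramps", {
  const <- matrix(5, 200, 1, dimnames = list(NULL, "c"))
  sm <- smoothCounts(const, window = 80, stride = 20, threshold = -Inf)
  expect_true(all(sm$c == 5))

  # a series never exceeding the threshold is dropped
  two <- cbind(low = rep(79, 200), high = rep(100, 200))
  sm2 <- smoothCounts(two, window = 80, stride = 20, threshold = 80)
  expect_named(sm2, c("generation", "high"))

  # linear ramp: centred mean reproduces the centre value (odd window)
  ramp <- matrix(seq_len(201), dimnames = list(NULL, list("r")))
  sm3 <- smoothCounts(ramp, window = 81, stride = 10, threshold = -Inf)
  expect_equal(sm3$r, sm3$generation + 1)

  expect_error(smoothCounts(matrix(1, 10, 1), window = 80), "window")
})

test_that("analytic mutation-event expectations at the reference census", {
  ex <- mutationEventExpectations(400)
  expect_equal(ex$gametes, 800)
  expect_equal(ex$matingMutations, 0.4)
  expect_equal(ex$pointMutatedGametes, 800 * (1 - 0.99^13))
  expect_equal(ex$pointMutatedGametes, 98, tolerance = 0.01)
  expect_equal(ex$crossoverGametes, 800 * (1 - 0.9999^13))
  expect_equal(ex$crossoverGametes, 1.04, tolerance = 0.01)
})

test_that("polymorphism summary distinguishes structured from diffuse populations", {
  set.seed(6)
  # diffuse random population
  rnd <- exploiterPop(matrix(runif(60 * 13, -1, 1), 60),
                      matrix(runif(60 * 13, -1, 1), 60))
  expect_false(polymorphismSummary(rnd)$polymorphic)

  # synthetic two-haplotype population in Hardy-Weinberg-like proportions
  hapA <- fixtureGenomes("specialist1", 1)@hapA[1, ]
  hapB <- fixtureGenomes("specialist3", 1)@hapA[1, ]
  jitter <- function(h, n) matrix(rep(h, each = n), n) +
    matrix(rnorm(n * 13, 0, 0.02), n)
  pop <- exploiterPop(rbind(jitter(hapA, 25), jitter(hapA, 20),
                            jitter(hapB, 25)),
                      rbind(jitter(hapA, 25), jitter(hapB, 20),
                            jitter(hapB, 25)))
  ps <- polymorphismSummary(pop)
  expect_true(ps$polymorphic)
  expect_equal(sort(unique(ps$genotype)), c("AA", "AB", "BB"))
  expect_equal(as.vector(table(ps$genotype)[c("AA", "AB", "BB")]),
               c(25L, 20L, 25L))
})
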