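smallConfig <- function(seed = 1L, ...) {
  simulationConfig(popSize = 120L, matingMutStart = 30L, mutStop = 60L,
                   endGen = 80L, snapshotEvery = 0L, seed = seed, ...)
}

test_that("founders match the configured size, ranges, and rr genotype", {
  cfg <- smallConfig()
  set.seed(cfg@seed)
  pop <- initPopulation(cfg)
  expect_equal(nInd(pop), 120L)
  expect_true(all(matingAlleles(pop) == "r"))
  haps <- prefHaplotypes(pop, "stacked")
  expect_true(all(haps > -1 & haps < 1))
  expect_equal(ncol(haps), 13L)

  # single-individual boundary
  one <- simulationConfig(popSize = 1L)
  set.seed(1); expect_equal(nInd(initPopulation(one)), 1L)
  expect_error(initPopulation(simulationConfig(popSize = 0L)))
})

test_that("phase flags implement the three-phase mutation schedule", {
  cfg <- simulationConfig()
  expect_equal(phaseFlags(0, cfg),
               c(matingMut = FALSE, pointMut = TRUE, crossover = TRUE))
  expect_equal(phaseFlags(19999, cfg)[["matingMut"]], FALSE)
  expect_equal(phaseFlags(20000, cfg),
               c(matingMut = TRUE, pointMut = TRUE, crossover = TRUE))
  expect_equal(phaseFlags(79999, cfg)[["pointMut"]], TRUE)
  expect_equal(phaseFlags(80000, cfg),
               c(matingMut = FALSE, pointMut = FALSE, crossover = TRUE))
  cfgNoX <- simulationConfig(retainCrossover = FALSE)
  expect_equal(phaseFlags(80000, cfgNoX)[["crossover"]], FALSE)
})

test_that("one generation of identical specialists at low density grows at the fitness-predicted rate", {
  # 40 perfect niche-1 specialists: e = (3,0,0,0), E1 = 120,
  # f = 3 / (1 + (120/375)^2.5), each parent assigned round(f) recruits
  n <- 40L
  pop <- fixtureGenomes("specialist1", n)
  cfg <- smallConfig()
  f <- 3 / (1 + (120 / 375)^2.5)
  set.seed(9)
  stp <- stepGeneration(pop, cfg, 0L)
  expect_false(stp$extinct)
  expect_equal(nInd(stp$pop), n * round(f))  # 20 pairs x 2*round(f)
})

test_that("a lone individual cannot pair and the run signals extinction", {
  pop <- fixtureGenomes("specialist1", 1)
  set.seed(1)
  stp <- stepGeneration(pop, smallConfig(), 0L)
  expect_true(stp$extinct)
})

test_that("runs are bit-reproducible from (seed, config)", {
  cfg <- smallConfig(seed = 42L)
  r1 <- runSimulation(cfg)
  r2 <- runSimulation(cfg)
  expect_identical(records(r1), records(r2))
  r3 <- runSimulation(smallConfig(seed = 43L))
  expect_false(identical(records(r1), records(r3)))
})

test_that("zero-generation runs log only the initial state", {
  cfg <- smallConfig()
  res <- runSimulation(cfg, generations = 0)
  expect_equal(nrow(records(res)), 1L)
  expect_equal(records(res)$generation, 0L)
  expect_equal(records(res)$popSize, 120L)
})

test_that("the a allele is absent throughout phase 1", {
  cfg <- smallConfig(seed = 5L)
  res <- runSimulation(cfg)
  r <- records(res)
  expect_true(all(r$freqA[r$generation <= 30 & r$popSize > 0] == 0))
})

test_that("record invariants hold: class counts sum to census", {
  cfg <- smallConfig(seed = 6L)
  res <- runSimulation(cfg)
  r <- records(res)
  cls <- grep("^n[01]", names(r), value = TRUE)
  expect_equal(rowSums(r[, cls]), r$popSize, ignore_attr = TRUE)
  alive <- r$popSize > 0
  expect_equal(r$freqR[alive] + r$freqA[alive], rep(1, sum(alive)))
  expect_true(all(r$unfit <= r$popSize))
})

test_that("population size stays bounded by the growth-factor cap", {
  cfg <- smallConfig(seed = 7L)
  res <- runSimulation(cfg)
  n <- records(res)$popSize
  # each parent contributes at most round(phi) recruits
  expect_true(all(n[-1] <= 3 * n[-length(n)]))
  expect_lt(max(n), 2000)  # density dependence keeps the census bounded
})

test_that("after mutations stop, no new preference haplotypes appear without crossover", {
  # tiny run with crossover disabled in phase 3: the allele multiset can only
  # shrink
  cfg <- simulationConfig(popSize = 80L, matingMutStart = 5L, mutStop = 10L,
                          endGen = 30L, retainCrossover = FALSE,
                          snapshotEvery = 5L, seed = 11L)
  res <- runSimulation(cfg)
  snaps <- snapshots(res)
  gens <- as.integer(names(snaps))
  phase3 <- sort(gens[gens >= 10L])
  if (length(phase3) >= 2) {
    hapKey <- function(pop) apply(round(prefHaplotypes(pop, "stacked"), 9), 1,
                                  paste, collapse = ",")
    prev <- unique(hapKey(snaps[[as.character(phase3[1])]]))
    for (g in phase3[-1]) {
      cur <- unique(hapKey(snaps[[as.character(g)]]))
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("replicate runs differ only by seed and are reproducible", {
  cfg <- smallConfig()
  reps <- replicateRuns(cfg, seeds = c(2L, 3L))
  expect_named(reps, c("2", "3"))
  again <- runSimulation(smallConfig(seed = 3L))
  expect_identical(records(reps[["3"]]), records(again))
})
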