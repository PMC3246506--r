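zeroRates <- mutationRates(crossoverPerLocus = 0, pointMutPerAllele = 0,
                           matingMutRate = 0)

test_that("gametes copy a parental haplotype exactly when rates are zero", {
  set.seed(1)
  h1 <- runif(13, -1, 1); h2 <- runif(13, -1, 1)
  pop <- exploiterPop(h1, h2)
  g <- makePreferenceGametes(pop, rep(1L, 200), zeroRates)
  fromA <- apply(g, 1, function(x) all(x == h1))
  fromB <- apply(g, 1, function(x) all(x == h2))
  expect_true(all(fromA | fromB))
  expect_equal(mean(fromA), 0.5, tolerance = 0.1)
})

test_that("forced crossover alternates the template at every locus", {
  h1 <- rep(0, 13); h2 <- rep(1, 13)
  pop <- exploiterPop(h1, h2)
  rates <- mutationRates(crossoverPerLocus = 1, pointMutPerAllele = 0)
  set.seed(2)
  g <- makePreferenceGametes(pop, rep(1L, 20), rates)
  # a switch happens before every locus, so alleles alternate 0,1,0,... or
  # 1,0,1,... depending on the starting template
  alt1 <- rep(c(0, 1), length.out = 13)
  alt2 <- rep(c(1, 0), length.out = 13)
  ok <- apply(g, 1, function(x) all(x == alt1) || all(x == alt2))
  expect_true(all(ok))
})

test_that("point mutations perturb uniformly, symmetrically, and clamp", {
  pop <- exploiterPop(rep(15, 13), rep(15, 13))
  rates <- mutationRates(crossoverPerLocus = 0, pointMutPerAllele = 1)
  set.seed(3)
  g <- makePreferenceGametes(pop, rep(1L, 400), rates)
  expect_true(all(g >= -20 & g <= 20))
  expect_true(any(g == 20))  # perturbations beyond +5 clamp at the bound
  # below the clamp the distribution is uniform 15 + U(-10, 10): mean 15
  free <- g[g < 20]
  expect_equal(mean(free), mean(15 + seq(-10, 5, 0.01)), tolerance = 0.2)

  # symmetric perturbations around a central value
  pop0 <- exploiterPop(rep(0, 13), rep(0, 13))
  set.seed(4)
  g0 <- makePreferenceGametes(pop0, rep(1L, 400), rates)
  expect_equal(mean(g0), 0, tolerance = 0.2)
  expect_true(all(g0 >= -10 & g0 <= 10))
})

test_that("mating gametes copy and flip correctly", {
  pop <- exploiterPop(matrix(0, 1, 13), matrix(0, 1, 13), "r", "r")
  set.seed(5)
  expect_true(all(makeMatingGametes(pop, rep(1L, 50), zeroRates) == "r"))

  het <- exploiterPop(matrix(0, 1, 13), matrix(0, 1, 13), "r", "a")
  g <- makeMatingGametes(het, rep(1L, 4000), zeroRates)
  expect_equal(mean(g == "r"), 0.5, tolerance = 0.05)

  flipAll <- mutationRates(matingMutRate = 1)
  expect_true(all(makeMatingGametes(pop, rep(1L, 50), flipAll,
                                    matingMut = TRUE) == "a"))
  # disabled flag suppresses mutation even at rate 1
  expect_true(all(makeMatingGametes(pop, rep(1L, 50), flipAll,
                                    matingMut = FALSE) == "r"))
})

test_that("offspring of identical homozygous parents are identical to them", {
  h <- runif(13, -1, 1)
  pop <- exploiterPop(matrix(h, 2, 13, byrow = TRUE),
                      matrix(h, 2, 13, byrow = TRUE))
  set.seed(6)
  off <- makeOffspring(pop, rep(1L, 10), rep(2L, 10), zeroRates)
  expect_equal(off@hapA, matrix(h, 10, 13, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(off@hapB, matrix(h, 10, 13, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("AA x BB yields all heterozygotes; Punnett oracle is exact", {
  expect_equal(punnettExpectation(c("A", "A"), c("B", "B")), c(AB = 1))
  expect_equal(punnettExpectation(c("A", "B"), c("A", "B")),
               c(AA = 0.25, AB = 0.5, BB = 0.25))
  expect_equal(punnettExpectation(c("A", "A"), c("A", "B")),
               c(AA = 0.5, AB = 0.5))
  expect_equal(punnettExpectation(c("A", "A"), c("A", "A")), c(AA = 1))
  expect_error(punnettExpectation(1:2, c("A", "B")), "labels")
})

test_that("empirical offspring genotypes match the Punnett expectation", {
  hA <- rep(-1, 13); hB <- rep(1, 13)
  pop <- exploiterPop(rbind(hA, hA), rbind(hB, hB))  # two AB parents
  set.seed(7)
  n <- 10000L
  off <- makeOffspring(pop, rep(1L, n), rep(2L, n), zeroRates)
  geno <- paste0(ifelse(off@hapA[, 1] < 0, "A", "B"),
                 ifelse(off@hapB[, 1] < 0, "A", "B"))
  unord <- vapply(strsplit(geno, ""), function(x)
    paste(sort(x), collapse = ""), character(1))
  obs <- table(factor(unord, c("AA", "AB", "BB")))
  exp <- punnettExpectation(c("A", "B"), c("A", "B"))
  gof <- suppressWarnings(chisq.test(obs, p = exp[c("AA", "AB", "BB")]))
  expect_gt(gof$p.value, 1e-3)
  # heterozygote fraction among offspring of het x het is exactly 1/2 in
  # expectation
  expect_equal(mean(unord == "AB"), 0.5, tolerance = 0.02)
  # ordered storage: AB and BA arise equally often (storage-order symmetry)
  expect_lt(abs(mean(geno == "AB") - mean(geno == "BA")), 0.025)
})

test_that("the a allele cannot appear without mating-gene mutation", {
  pop <- exploiterPop(matrix(0, 20, 13), matrix(0, 20, 13), "r", "r")
  set.seed(8)
  for (i in 1:20) {
    off <- makeOffspring(pop, sample(20, 30, TRUE), sample(20, 30, TRUE),
                         mutationRates(), matingMut = FALSE)
    expect_true(all(matingAlleles(off) == "r"))
    pop <- off
  }
})
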