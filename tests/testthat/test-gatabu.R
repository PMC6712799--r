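test_that("configuration invariants are enforced", {
  cfg <- gaConfig()
  expect_equal(cfg@populationSize, 50L)
  expect_equal(cfg@crossoverProb, 0.7)
  expect_equal(cfg@mutationProb, 0.002)
  expect_equal(cfg@tabuLength, 30L)
  expect_equal(cfg@maxIterations, 60L)
  expect_equal(cfg@stagnationK, 3L)
  expect_error(gaConfig(crossoverProb = 1.4), "\\[0, 1\\]")
  expect_error(gaConfig(populationSize = 0), ">= 1")
  expect_error(gaConfig(kLoci = 4), "2 or 3")
})

test_that("the tabu list is a bounded FIFO with exact membership", {
  tl <- tabuList(2)
  a <- adjacency(emptyDag(c("A", "B")))
  b <- a; b["A", "B"] <- 1L
  c3 <- a; c3["B", "A"] <- 1L
  tabuInsert(tl, a)
  expect_true(tabuContains(tl, a))
  expect_false(tabuContains(tl, b))
  tabuInsert(tl, b)
  tabuInsert(tl, c3)               # capacity 2: evicts the oldest (a)
  expect_equal(tabuSize(tl), 2L)
  expect_false(tabuContains(tl, a))
  expect_true(tabuContains(tl, b))
  expect_true(tabuContains(tl, c3))
})

test_that("the seed network wires top pairs into the phenotype node", {
  ranked <- data.frame(snp1 = c(1L, 2L), snp2 = c(3L, 4L),
                       name1 = c("S1", "S2"), name2 = c("S3", "S4"),
                       mi = c(0.5, 0.1))
  net <- buildInitialNetwork(ranked, topN = 1, paste0("S", 1:4))
  a <- adjacency(net)
  expect_true(isAcyclic(net))
  expect_equal(a["S1", "Class"], 1L)
  expect_equal(a["S3", "Class"], 1L)
  expect_equal(a["S1", "S3"], 1L)
  # nodes S2, S4 are covered through the remaining pair, away from Class
  expect_equal(sum(a[, "Class"]), 2L)
  expect_equal(sum(a), 4L)
  # topN covering everything leaves nothing to scan
  net2 <- buildInitialNetwork(ranked, topN = 2, paste0("S", 1:4))
  expect_equal(sum(adjacency(net2)), 6L)
})

test_that("the initial population chains single edits from the seed", {
  set.seed(41)
  tab <- randomTable(30, 5)
  seedNet <- buildInitialNetwork(rankPairs(encodeBits(tab), 2), 1,
                                 snpNames(tab))
  one <- generateInitialPopulation(seedNet, gaConfig(populationSize = 1))
  expect_length(one, 1L)
  expect_identical(adjacency(one[[1]]), adjacency(seedNet))

  pop <- generateInitialPopulation(seedNet, gaConfig(populationSize = 20))
  expect_length(pop, 20L)
  for (i in seq_along(pop)) {
    expect_true(isAcyclic(pop[[i]]))
    if (i > 1) {
      delta <- sum(adjacency(pop[[i]]) != adjacency(pop[[i - 1]]))
      expect_true(delta %in% 1:2)    # drop/add = 1 cell, reverse = 2
    }
  }
})

test_that("roulette selection follows the fitness proportions", {
  set.seed(42)
  draws <- rouletteSelect(rep(2, 4), 4000)
  expect_gt(chisq.test(tabulate(draws, 4))$p.value, 0.01)
  expect_error(rouletteSelect(c(1, 0)), "strictly positive")
  f <- shiftFitness(c(-100, -100))
  expect_true(all(f > 0) && f[1] == f[2])
  expect_equal(diff(shiftFitness(c(-50, -10))), 40)
})

test_that("crossover exchanges parent sets and never builds a ring", {
  set.seed(43)
  nodes <- c("A", "B", "C")
  a1 <- adjacency(emptyDag(nodes))
  p <- dagIndividual(a1)
  off <- crossover(p, p)
  expect_identical(adjacency(off[[1]]), a1)

  # hand-built skip: exchanging column A installs B->A into a graph that
  # already holds A->B, so that row is skipped and the rest exchanged
  x1 <- a1; x1["A", "B"] <- 1L            # ind1: A->B, col A empty
  x2 <- a1; x2["B", "A"] <- 1L; x2["Class", "A"] <- 1L
  off <- epistabu:::.crossoverAmat(x1, x2, cols = 1L)
  expect_equal(off[[1]]["B", "A"], 0L)    # skipped: would close the ring
  expect_equal(off[[1]]["Class", "A"], 1L)  # exchanged
  expect_equal(off[[2]]["Class", "A"], 0L)
  expect_equal(off[[2]]["B", "A"], 1L)    # retained in ind2
  expect_true(isAcyclic(off[[1]]) && isAcyclic(off[[2]]))

  for (rep in 1:200) {
    p1 <- dagIndividual(randomDagAmat(6, 0.3))
    p2 <- dagIndividual(randomDagAmat(6, 0.3))
    off <- crossover(p1, p2)
    expect_true(isAcyclic(off[[1]]))
    expect_true(isAcyclic(off[[2]]))
  }
})

test_that("tabu crossover refuses listed offspring and records accepted ones", {
  set.seed(44)
  p1 <- dagIndividual(randomDagAmat(5, 0.3))
  p2 <- dagIndividual(randomDagAmat(5, 0.3))
  tl <- tabuList(10)
  res <- tabuCrossover(p1, p2, tl)
  expect_true(res$accepted)
  expect_equal(tabuSize(tl), 2L)
  expect_true(tabuContains(tl, res$offspring[[1]]))

  # identical parents can only reproduce themselves: once the clone is
  # listed, every retry collides and the result comes back flagged
  tl2 <- tabuList(10)
  tabuInsert(tl2, p1)
  res2 <- tabuCrossover(p1, p1, tl2, maxRetries = 5)
  expect_false(res2$accepted)
  expect_identical(adjacency(res2$offspring[[1]]), adjacency(p1))
})

test_that("mutation only ever returns acyclic, non-degrading individuals", {
  set.seed(45)
  tab <- randomTable(40, 4)
  ind <- emptyDag(snpNames(tab))
  ind@score <- bicScore(ind, tab)
  expect_identical(mutateIndividual(ind, tab, pm = 0), ind)
  for (rep in 1:30) {
    out <- mutateIndividual(ind, tab, pm = 1)
    expect_true(isAcyclic(out))
    if (!identical(adjacency(out), adjacency(ind)))
      expect_gt(out@score, ind@score)
  }
})

test_that("population-level tabu mutation blocks listed mutants and keeps size", {
  set.seed(46)
  tab <- randomTable(40, 4)
  cfg <- gaConfig(populationSize = 10, mutationProb = 1)
  seedNet <- buildInitialNetwork(rankPairs(encodeBits(tab), 2), 1,
                                 snpNames(tab))
  pop <- generateInitialPopulation(seedNet, cfg)
  pop <- lapply(pop, function(p) { p@score <- bicScore(p, tab); p })
  tl <- tabuList(500)
  out <- tabuMutate(pop, tab, tl, cfg)
  expect_length(out, 10L)
  for (i in seq_along(out)) {
    expect_true(isAcyclic(out[[i]]))
    expect_gte(out[[i]]@score, pop[[i]]@score)
    # an accepted mutant is never one the tabu list already held
    expect_false(tabuContains(tl, out[[i]]) &&
                   !identical(adjacency(out[[i]]), adjacency(pop[[i]])))
  }
})

test_that("the search is elitist, terminating and reproducible", {
  set.seed(47)
  m <- buildPenetrance(2, maf = 0.4, h2 = 0.4)
  sim <- simulateDataset(m, nNoiseSnps = 6, nCases = 150, nControls = 150)
  cfg <- gaConfig(populationSize = 12, maxIterations = 8, seed = 5)

  fit0 <- epiSearch(sim$table, gaConfig(populationSize = 12,
                                        maxIterations = 0, seed = 5))
  expect_equal(fit0$generations, 0L)
  expect_s4_class(fit0$best, "DagIndividual")

  fit <- epiSearch(sim$table, cfg)
  expect_lte(fit$generations, 8L)
  expect_true(all(diff(fit$history$bestScore) >= 0))   # elitist tracking
  expect_true(isAcyclic(fit$best))

  fit2 <- epiSearch(sim$table, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(adjacency(fit$best), adjacency(fit2$best))
})

test_that("the full search recovers a strong planted interaction", {
  set.seed(48)
  m <- buildPenetrance(2, maf = 0.4, h2 = 0.4)
  sim <- simulateDataset(m, nNoiseSnps = 10, nCases = 250, nControls = 250)
  fit <- epiSearch(sim$table, gaConfig(seed = 3))
  rep <- suppressWarnings(extractPairs(fit$best, encodeBits(sim$table)))
  expect_true(any(apply(rep[, c("name1", "name2")], 1, setequal,
                        sim$truth)))
})
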