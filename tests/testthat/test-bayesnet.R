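test_that("acyclicity detection agrees with topological construction", {
  empty <- emptyDag(c("A", "B"))
  expect_true(isAcyclic(empty))
  a <- adjacency(empty)
  a["A", "B"] <- 1L; a["B", "A"] <- 1L
  expect_false(isAcyclic(a))
  expect_error(dagIndividual(a), "cycle")

  set.seed(31)
  for (rep in 1:20) {
    amat <- randomDagAmat(sample(4:10, 1), pEdge = 0.3)
    expect_true(isAcyclic(amat))
    e <- which(amat == 1L, arr.ind = TRUE)
    if (nrow(e)) {
      pick <- e[sample(nrow(e), 1L), ]   # reverse of an edge on a path
      back <- amat
      back[pick[2L], pick[1L]] <- 1L
      expect_false(isAcyclic(back))
    }
  }
})

test_that("cycle prediction for a candidate edge matches add-and-check", {
  chain <- emptyDag(c("A", "B", "C"))
  a <- adjacency(chain)
  a["A", "B"] <- 1L; a["B", "C"] <- 1L
  chain <- dagIndividual(a)
  expect_true(wouldCreateCycle(chain, 3, 1))   # C -> A closes the ring
  expect_false(wouldCreateCycle(chain, 1, 3))
  expect_true(wouldCreateCycle(chain, 2, 2))   # self-loop by convention

  set.seed(32)
  for (rep in 1:20) {
    amat <- randomDagAmat(6, pEdge = 0.25)
    ind <- dagIndividual(amat)
    absent <- which(amat == 0L & row(amat) != col(amat))
    pick <- absent[sample(length(absent), 1L)]
    from <- ((pick - 1L) %% 6L) + 1L
    to <- ((pick - 1L) %/% 6L) + 1L
    tent <- amat
    tent[from, to] <- 1L
    expect_identical(wouldCreateCycle(ind, from, to), !isAcyclic(tent))
  }
})

test_that("sufficient statistics match marginal counts and the row-scan oracle", {
  g <- matrix(0L, 146, 2, dimnames = list(NULL, c("A", "B")))
  tab <- GenotypeTable(g, c(rep(1L, 96), rep(0L, 50)))
  st <- sufficientStats(emptyDag(c("A", "B")), tab, 3L)
  expect_equal(st$q, 1)
  expect_equal(st$r, 2L)
  expect_equal(st$margins, 146)
  expect_equal(as.vector(st$counts), c(50, 96))  # value order 0, 1

  set.seed(33)
  tab <- randomTable(60, 3)
  dag <- emptyDag(snpNames(tab))
  a <- adjacency(dag)
  a[2, 1] <- 1L                                  # one ternary parent
  dag <- dagIndividual(a)
  st <- sufficientStats(dag, tab, 1L)
  expect_equal(st$q, 3)
  expect_equal(sum(st$counts), 60)
  # row-scan oracle over every observed parent configuration
  g <- genoMatrix(tab)
  for (jj in seq_along(st$j)) {
    pv <- st$j[jj] - 1                           # parent value (one parent)
    for (k in 0:2)
      expect_equal(st$counts[k + 1L, jj], sum(g[, 2] == pv & g[, 1] == k))
  }
  expect_error(sufficientStats(dag, tab, 1L, qMax = 2), "overparameterized")
})

test_that("BIC matches the closed form on a hand-computed 4-sample table", {
  g <- matrix(c(0L, 1L, 1L, 2L, 0L, 0L, 1L, 1L), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  tab <- GenotypeTable(g, c(0, 1, 1, 0))
  # empty graph, natural log, m = 4:
  #   A: counts (1,2,1) -> ll = -2 log 4 - 2 log 2, penalty (3-1)/2 log 4
  #   B: counts (2,2,0) -> ll = -4 log 2,          penalty (3-1)/2 log 4
  #   Class: counts (2,2) -> ll = -4 log 2,        penalty (2-1)/2 log 4
  hand <- (-2 * log(4) - 2 * log(2) - log(4)) +
          (-4 * log(2) - log(4)) +
          (-4 * log(2) - 0.5 * log(4))
  expect_equal(bicScore(emptyDag(c("A", "B")), tab), hand,
               tolerance = 1e-12)

  # adding A -> B: family B becomes counts {A=0:(1), A=1:(1,1), A=2:(1)}
  a <- adjacency(emptyDag(c("A", "B")))
  a["A", "B"] <- 1L
  handB <- -2 * log(2) - 3 * log(4)              # ll - q=3 penalty
  handEdge <- hand - (-4 * log(2) - log(4)) + handB
  expect_equal(bicScore(dagIndividual(a), tab), handEdge,
               tolerance = 1e-12)
})

test_that("the edgeless score is the sum of marginal terms for any base", {
  set.seed(34)
  tab <- randomTable(50, 4)
  nd <- cbind(genoMatrix(tab), Class = phenotype(tab))
  for (b in c(exp(1), 2, 10)) {
    hand <- 0
    for (i in 1:5) {
      cnt <- table(nd[, i])
      r <- if (i == 5) 2 else 3
      hand <- hand + sum(cnt * log(cnt / 50, base = b)) -
        (r - 1) / 2 * log(50, base = b)
    }
    expect_equal(bicScore(emptyDag(snpNames(tab)), tab, base = b), hand,
                 tolerance = 1e-10)
  }
})

test_that("BIC is decomposable and relabeling-invariant", {
  set.seed(35)
  tab <- randomTable(80, 4)
  amat <- randomDagAmat(5, pEdge = 0.3)
  dimnames(amat) <- list(c(snpNames(tab), "Class"),
                         c(snpNames(tab), "Class"))
  ind <- dagIndividual(amat)
  base <- bicScore(ind, tab)

  # change one node's parents: only that node's family term moves
  node <- 2L
  a2 <- amat
  a2[, node] <- 0L
  ind2 <- dagIndividual(a2)
  fam <- function(ind, node) {
    st <- sufficientStats(ind, tab, node)
    marg <- rep(st$margins, each = st$r)
    pos <- st$counts > 0
    sum(st$counts[pos] * log(st$counts[pos] / marg[pos])) -
      st$q * (st$r - 1) / 2 * log(st$m)
  }
  expect_equal(bicScore(ind2, tab) - base,
               fam(ind2, node) - fam(ind, node), tolerance = 1e-10)

  # permute SNP labels together with the data columns
  perm <- c(sample(4), 5L)
  permAmat <- amat[perm, perm]
  permTab <- GenotypeTable(genoMatrix(tab)[, perm[1:4], drop = FALSE],
                           phenotype(tab))
  expect_equal(bicScore(dagIndividual(permAmat), permTab), base,
               tolerance = 1e-10)
})

test_that("an edge from an independent SNP into Class lowers BIC on average", {
  set.seed(36)
  diffs <- replicate(20, {
    tab <- randomTable(100, 2)
    e <- emptyDag(snpNames(tab))
    a <- adjacency(e)
    a[1, 3] <- 1L
    bicScore(dagIndividual(a), tab) - bicScore(e, tab)
  })
  expect_lt(mean(diffs), 0)
})

test_that("single-edge edits preserve acyclicity or signal rejection", {
  e <- emptyDag(c("A", "B", "C"))
  one <- applyEdit(e, "add", 1, 2)
  expect_equal(sum(adjacency(one)), 1L)
  expect_null(applyEdit(one, "add", 2, 1))       # would close a 2-cycle
  expect_null(applyEdit(one, "drop", 2, 3))      # edge absent
  chain <- applyEdit(one, "add", 2, 3)
  rev1 <- applyEdit(chain, "reverse", 2, 3)      # A->B<-C stays acyclic
  expect_true(isAcyclic(rev1))
  expect_equal(adjacency(rev1)["C", "B"], 1L)
  # reverse of A->B with a second path A->C->B must be rejected
  a <- adjacency(emptyDag(c("A", "B", "C")))
  a["A", "B"] <- 1L; a["A", "C"] <- 1L; a["C", "B"] <- 1L
  expect_null(applyEdit(dagIndividual(a), "reverse", 1, 2))
})

test_that("network serialization lists every edge", {
  a <- adjacency(emptyDag(c("A", "B")))
  a["A", "B"] <- 1L; a["A", "Class"] <- 1L
  path <- tempfile()
  writeDag(dagIndividual(a), path)
  expect_setequal(readLines(path), c("A\tB", "A\tClass"))
  writeDag(dagIndividual(a), path, format = "dot")
  expect_match(readLines(path)[1], "digraph")
})
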