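# fixtures and independent counting oracles shared across the test files

randomTable <- function(n, m, pCase = 0.5) {
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(NULL, paste0("S", seq_len(m))))
  GenotypeTable(g, rbinom(n, 1L, pCase))
}

# entropy of a count table, 0 log 0 = 0
.entH <- function(counts, base = exp(1)) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# contingency-table mutual information I(Class | SNPs) by direct counting
naiveMI <- function(tab, idx, base = exp(1)) {
  g <- genoMatrix(tab)
  ph <- phenotype(tab)
  key <- apply(g[, idx, drop = FALSE], 1L, paste, collapse = ",")
  .entH(table(ph), base) + .entH(table(key), base) -
    .entH(table(paste(key, ph)), base)
}

# joint probability of an assignment by row scanning
naiveJointProb <- function(tab, assignment, classValue = NULL) {
  g <- genoMatrix(tab)
  keep <- rep(TRUE, nSamples(tab))
  for (a in assignment) keep <- keep & (g[, a[[1L]]] == a[[2L]])
  if (!is.null(classValue)) keep <- keep & (phenotype(tab) == classValue)
  sum(keep) / nSamples(tab)
}

# random DAG by topological construction: edges only low -> high index,
# then a random node permutation
randomDagAmat <- function(nNodes, pEdge = 0.2) {
  a <- matrix(0L, nNodes, nNodes)
  for (i in seq_len(nNodes - 1L))
    for (j in seq(i + 1L, nNodes))
      if (runif(1) < pEdge) a[i, j] <- 1L
  perm <- sample.int(nNodes)
  a <- a[perm, perm]
  dimnames(a) <- list(paste0("V", seq_len(nNodes)),
                      paste0("V", seq_len(nNodes)))
  a
}

writeTempGenotypes <- function(tab, delimiter = "\t") {
  path <- tempfile(fileext = ".txt")
  writeGenotypes(tab, path, delimiter = delimiter)
  path
}
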