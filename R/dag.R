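#' DagIndividual: one Bayesian-network structure
#'
#' An individual of the structure search: an `n x n` 0/1 adjacency matrix
#' over the SNP nodes plus the phenotype node, with `amat[i, j] = 1` iff
#' node *i* is a parent of node *j*.  The matrix is guaranteed acyclic;
#' the phenotype node is named `"Class"` and sits at the last index.
#'
#' @slot amat integer 0/1 adjacency matrix with node names as dimnames.
#' @slot score numeric, cached BIC score (`NA_real_` when not evaluated).
#'
#' @seealso [bicScore()], [applyEdit()], [epiSearch()]
#' @export
setClass("DagIndividual",
  representation(amat = "matrix", score = "numeric"),
  prototype(score = NA_real_))

setValidity("DagIndividual", function(object) {
  a <- object@amat
  if (nrow(a) != ncol(a)) return("adjacency matrix must be square")
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    return("adjacency matrix needs matching row/column node names")
  if (!all(a %in% 0:1)) return("adjacency entries must be 0/1")
  if (any(diag(a) != 0L)) return("self-loops are not allowed")
  if (!.isAcyclicAmat(a)) return("graph contains a directed cycle (ring)")
  TRUE
})

#' Construct a DagIndividual
#'
#' @param amat square 0/1 adjacency matrix; `amat[i, j] = 1` iff node *i*
#'   is a parent of node *j*.
#' @param nodeNames node names; defaults to existing dimnames.
#' @param score optional cached score.
#' @return A validated [DagIndividual-class].
#' @export
dagIndividual <- function(amat, nodeNames = rownames(amat),
                          score = NA_real_) {
  storage.mode(amat) <- "integer"
  dimnames(amat) <- list(nodeNames, nodeNames)
  new("DagIndividual", amat = amat, score = as.numeric(score))
}

#' Empty network over SNPs plus the phenotype node
#'
#' @param snps character vector of SNP names.
#' @return A [DagIndividual-class] with no edges, `"Class"` last.
#' @export
emptyDag <- function(snps) {
  nodes <- c(snps, "Class")
  dagIndividual(matrix(0L, length(nodes), length(nodes)), nodes)
}

#' @describeIn DagIndividual the adjacency matrix
#' @param x,object a `DagIndividual`
#' @export
adjacency <- function(x) x@amat

#' @describeIn DagIndividual node names, phenotype node last
#' @export
nodeNames <- function(x) rownames(x@amat)

setMethod("show", "DagIndividual", function(object) {
  a <- object@amat
  cat(sprintf("DagIndividual: %d nodes, %d edges%s\n", nrow(a), sum(a),
              if (is.na(object@score)) ""
              else sprintf(", BIC = %.4f", object@score)))
  e <- which(a == 1L, arr.ind = TRUE)
  if (nrow(e)) {
    shown <- utils::head(seq_len(nrow(e)), 8)
    cat("  ", paste(rownames(a)[e[shown, 1]], "->",
                    colnames(a)[e[shown, 2]], collapse = ", "),
        if (nrow(e) > 8) ", ..." else "", "\n", sep = "")
  }
})

# Kahn's algorithm on a plain 0/1 matrix
.isAcyclicAmat <- function(a) {
  n <- nrow(a)
  indeg <- colSums(a)
  alive <- rep(TRUE, n)
  repeat {
    src <- which(alive & indeg == 0L)
    if (!length(src)) break
    alive[src] <- FALSE
    if (length(src) == 1L) indeg <- indeg - a[src, ]
    else indeg <- indeg - colSums(a[src, , drop = FALSE])
  }
  !any(alive)
}

# TRUE iff `to` reaches `from` through directed edges (so adding
# from -> to would close a cycle); from == to counts as a self-loop.
.wouldCycleAmat <- function(a, from, to) {
  if (from == to) return(TRUE)
  n <- nrow(a)
  seen <- logical(n)
  frontier <- to
  seen[to] <- TRUE
  while (length(frontier)) {
    kids <- if (length(frontier) == 1L) which(a[frontier, ] == 1L)
            else which(colSums(a[frontier, , drop = FALSE]) > 0L)
    kids <- kids[!seen[kids]]
    if (from %in% kids) return(TRUE)
    seen[kids] <- TRUE
    frontier <- kids
  }
  FALSE
}

#' Test a network for acyclicity
#'
#' @param ind a [DagIndividual-class] (or plain 0/1 adjacency matrix).
#' @return `TRUE` iff a topological order exists.
#' @export
isAcyclic <- function(ind) {
  a <- if (is(ind, "DagIndividual")) ind@amat else ind
  .isAcyclicAmat(a)
}

#' Would adding an edge close a ring?
#'
#' Checks whether adding the directed edge `from -> to` would create a
#' directed cycle, i.e. whether `to` already reaches `from`.  Used by the
#' crossover and mutation operators to skip ring-generating exchanges.
#'
#' @param ind a [DagIndividual-class].
#' @param from,to node indices of the candidate edge; `from == to`
#'   returns `TRUE` (self-loops are forbidden).
#' @return Logical.
#' @export
wouldCreateCycle <- function(ind, from, to) {
  a <- if (is(ind, "DagIndividual")) ind@amat else ind
  .wouldCycleAmat(a, from, to)
}

# ---- sufficient statistics and BIC -----------------------------------------

# data matrix (samples x nodes, values 0-based) and arities for a table:
# SNP nodes are ternary, the class node binary, class last.
.nodeData <- function(table) {
  d <- cbind(genoMatrix(table), Class = phenotype(table))
  list(data = d, arity = c(rep(3L, nSnps(table)), 2L))
}

#' Sufficient statistics of one node given its parents
#'
#' Counts `m_ijk`: the number of samples in which the node takes its
#' *k*-th value while its parents take their *j*-th joint configuration.
#' Parent configurations are enumerated in mixed-radix order with the
#' lowest-index parent as the fastest-varying digit, so `j`-indexing is
#' reproducible.  Only observed configurations are materialised; `q`
#' always reports the full combinatorial count used by the BIC penalty.
#'
#' @param ind a [DagIndividual-class].
#' @param table the [GenotypeTable-class] the network is scored against.
#' @param node node index (SNPs in table order, phenotype last).
#' @param qMax cap on the number of parent configurations `q`; beyond it
#'   the family is rejected as overparameterized.
#' @return A list with elements `r` (node arity), `q` (parent
#'   configuration count), `counts` (r x observed-configs matrix
#'   `m_ijk`), `margins` (`m_ij*` per observed config), `j` (the
#'   mixed-radix indices, 1-based, of the observed configs) and `m`.
#' @export
sufficientStats <- function(ind, table, node, qMax = 3^25) {
  stopifnot(is(ind, "DagIndividual"), is(table, "GenotypeTable"))
  nd <- .nodeData(table)
  .suffStats(ind@amat, nd$data, nd$arity, node, qMax)
}

.suffStats <- function(amat, data, arity, node, qMax = 3^25) {
  m <- nrow(data)
  r <- arity[node]
  parents <- which(amat[, node] == 1L)
  q <- prod(arity[parents])
  if (q > qMax)
    stop("node ", node, " has ", length(parents),
         " parents (q = ", format(q), " > cap ", format(qMax),
         "): overparameterized family", call. = FALSE)
  x <- data[, node]
  if (!length(parents)) {
    counts <- matrix(tabulate(x + 1L, nbins = r), nrow = r)
    return(list(r = r, q = 1, counts = counts, margins = sum(counts),
                j = 1, m = m))
  }
  # mixed-radix parent index, lowest parent index = fastest digit
  radix <- cumprod(c(1, arity[parents][-length(parents)]))
  j <- as.vector(data[, parents, drop = FALSE] %*% radix) + 1
  obs <- sort(unique(j))
  jc <- match(j, obs)
  counts <- matrix(tabulate((jc - 1L) * r + x + 1L,
                            nbins = length(obs) * r), nrow = r)
  list(r = r, q = q, counts = counts, margins = colSums(counts),
       j = obs, m = m)
}

# BIC contribution of one node family (log-likelihood term minus penalty)
.familyScore <- function(st, base = exp(1)) {
  cnt <- st$counts
  marg <- rep(st$margins, each = st$r)
  pos <- cnt > 0
  ll <- sum(cnt[pos] * log(cnt[pos] / marg[pos], base = base))
  ll - st$q * (st$r - 1) / 2 * log(st$m, base = base)
}

#' BIC score of a network against a genotype table
#'
#' Decomposable Bayesian Information Criterion: the sum over nodes of
#' the fitted multinomial log-likelihood of each node given its parents,
#' minus the complexity penalty `q_i (r_i - 1) / 2 * log(m)`.  Cells with
#' zero count contribute zero to the likelihood sum.  Larger is better.
#'
#' @inheritParams sufficientStats
#' @param base logarithm base; rescales all scores uniformly and never
#'   changes their ranking (default natural log).
#' @param cache optional environment memoising per-node family scores
#'   across many networks over the same data (used by the search).
#' @return The BIC score (numeric scalar); also stored in the returned
#'   individual by search code that keeps individuals around.
#' @export
bicScore <- function(ind, table, base = exp(1), qMax = 3^25, cache = NULL) {
  stopifnot(is(ind, "DagIndividual"), is(table, "GenotypeTable"))
  nd <- .nodeData(table)
  .bicAmat(ind@amat, nd$data, nd$arity, base = base, qMax = qMax,
           cache = cache)
}

.bicAmat <- function(amat, data, arity, base = exp(1), qMax = 3^25,
                     cache = NULL) {
  n <- ncol(data)
  total <- 0
  for (i in seq_len(n)) {
    parents <- which(amat[, i] == 1L)
    if (!is.null(cache)) {
      key <- paste(i, paste(parents, collapse = "."), sep = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) { total <- total + hit; next }
      val <- .familyScore(.suffStats(amat, data, arity, i, qMax), base)
      cache[[key]] <- val
      total <- total + val
    } else {
      total <- total + .familyScore(.suffStats(amat, data, arity, i, qMax),
                                    base)
    }
  }
  total
}

#' Apply a single-edge edit to a network
#'
#' Adds, drops or reverses one directed edge, rejecting any edit that
#' would create a ring.  Rejection is signalled by returning `NULL` so
#' callers can pick another edit.
#'
#' @param ind a [DagIndividual-class].
#' @param edit one of `"add"`, `"drop"`, `"reverse"`.
#' @param from,to node indices of the edge.
#' @return The edited [DagIndividual-class] (score cache cleared), or
#'   `NULL` when the edit is inapplicable or would create a cycle.
#' @export
applyEdit <- function(ind, edit = c("add", "drop", "reverse"), from, to) {
  stopifnot(is(ind, "DagIndividual"))
  edit <- match.arg(edit)
  a <- ind@amat
  present <- a[from, to] == 1L
  if (edit == "add") {
    if (present || .wouldCycleAmat(a, from, to)) return(NULL)
    a[from, to] <- 1L
  } else if (edit == "drop") {
    if (!present) return(NULL)
    a[from, to] <- 0L
  } else {
    if (!present) return(NULL)
    a[from, to] <- 0L
    if (.wouldCycleAmat(a, to, from)) return(NULL)
    a[to, from] <- 1L
  }
  dagIndividual(a)
}

#' Serialize a network as an adjacency list
#'
#' Writes one `parent<TAB>child` line per edge; optionally a DOT digraph
#' for visualization.
#'
#' @param ind a [DagIndividual-class].
#' @param path output path.
#' @param format `"edges"` (default) or `"dot"`.
#' @return Invisibly, `path`.
#' @export
writeDag <- function(ind, path, format = c("edges", "dot")) {
  stopifnot(is(ind, "DagIndividual"))
  format <- match.arg(format)
  a <- ind@amat
  e <- which(a == 1L, arr.ind = TRUE)
  p <- rownames(a)[e[, 1L]]; ch <- colnames(a)[e[, 2L]]
  lines <- if (format == "edges") paste(p, ch, sep = "\t")
           else c("digraph bn {",
                  sprintf("  \"%s\" -> \"%s\";", p, ch), "}")
  writeLines(lines, path)
  invisible(path)
}
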