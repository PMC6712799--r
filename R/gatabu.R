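#' GAConfig: parameters of the genetic-tabu structure search
#'
#' Defaults follow the published tuning of the method: population 50,
#' crossover probability 0.7, mutation probability 0.002, tabu list
#' length 30, at most 60 iterations, and early stop after 3 generations
#' without improvement of the best fitness.
#'
#' @slot populationSize number of individuals per generation.
#' @slot crossoverProb probability that a selected parent pair crosses.
#' @slot mutationProb per-individual mutation probability `P_m`.
#' @slot tabuLength capacity of each tabu list (FIFO).
#' @slot maxIterations generation cap.
#' @slot stagnationK stop after this many generations without improvement
#'   of the best-ever fitness.
#' @slot fitnessThreshold optional early-stop score (`NA` = disabled).
#' @slot topN number of top mutual-information pairs seeding the initial
#'   network.
#' @slot kLoci interaction order screened for the seed network (2 or 3).
#' @slot logBase logarithm base shared by entropies and BIC.
#' @slot maxRetries retry bound of the tabu crossover.
#' @slot forbidClassOut disallow edges out of the phenotype node.
#' @slot seed RNG seed recorded in run metadata.
#' @export
setClass("GAConfig",
  representation(populationSize = "integer", crossoverProb = "numeric",
                 mutationProb = "numeric", tabuLength = "integer",
                 maxIterations = "integer", stagnationK = "integer",
                 fitnessThreshold = "numeric", topN = "integer",
                 kLoci = "integer", logBase = "numeric",
                 maxRetries = "integer", forbidClassOut = "logical",
                 seed = "integer"))

setValidity("GAConfig", function(object) {
  if (object@populationSize < 1L) return("populationSize must be >= 1")
  if (object@crossoverProb < 0 || object@crossoverProb > 1)
    return("crossoverProb must be in [0, 1]")
  if (object@mutationProb < 0 || object@mutationProb > 1)
    return("mutationProb must be in [0, 1]")
  if (object@tabuLength < 1L) return("tabuLength must be >= 1")
  if (object@maxIterations < 0L) return("maxIterations must be >= 0")
  if (object@stagnationK < 1L) return("stagnationK must be >= 1")
  if (object@topN < 1L) return("topN must be >= 1")
  if (!(object@kLoci %in% 2:3)) return("kLoci must be 2 or 3")
  if (object@maxRetries < 1L) return("maxRetries must be >= 1")
  TRUE
})

#' @describeIn GAConfig constructor with published defaults
#' @param populationSize,crossoverProb,mutationProb,tabuLength,maxIterations,stagnationK,fitnessThreshold,topN,kLoci,logBase,maxRetries,forbidClassOut,seed see slots.
#' @export
gaConfig <- function(populationSize = 50L, crossoverProb = 0.7,
                     mutationProb = 0.002, tabuLength = 30L,
                     maxIterations = 60L, stagnationK = 3L,
                     fitnessThreshold = NA_real_, topN = 1L,
                     kLoci = 2L, logBase = exp(1), maxRetries = 10L,
                     forbidClassOut = FALSE, seed = 1L) {
  new("GAConfig", populationSize = as.integer(populationSize),
      crossoverProb = crossoverProb, mutationProb = mutationProb,
      tabuLength = as.integer(tabuLength),
      maxIterations = as.integer(maxIterations),
      stagnationK = as.integer(stagnationK),
      fitnessThreshold = as.numeric(fitnessThreshold),
      topN = as.integer(topN), kLoci = as.integer(kLoci),
      logBase = logBase, maxRetries = as.integer(maxRetries),
      forbidClassOut = forbidClassOut, seed = as.integer(seed))
}

setMethod("show", "GAConfig", function(object) {
  cat(sprintf(paste0("GAConfig: pop %d, pc %.3g, pm %.3g, tabu %d, ",
                     "maxIter %d, stagnation %d, topN %d, k %d, seed %d\n"),
              object@populationSize, object@crossoverProb,
              object@mutationProb, object@tabuLength,
              object@maxIterations, object@stagnationK, object@topN,
              object@kLoci, object@seed))
})

# ---- tabu list --------------------------------------------------------------

#' Bounded FIFO tabu list of network fingerprints
#'
#' Membership is exact adjacency-matrix equality, implemented by
#' fingerprinting the 0/1 bit pattern.  Insertions beyond capacity evict
#' the oldest entry.  The list is a reference object (environment) so the
#' search operators can share it.
#'
#' @param capacity maximum number of remembered individuals.
#' @return A tabu list object.
#' @export
tabuList <- function(capacity) {
  stopifnot(capacity >= 1)
  e <- new.env(parent = emptyenv())
  e$keys <- character(0)
  e$capacity <- as.integer(capacity)
  class(e) <- "tabuList"
  e
}

.tabuKey <- function(amat) paste(amat, collapse = "")

#' @rdname tabuList
#' @param tabu a tabu list.
#' @param ind a [DagIndividual-class], adjacency matrix, or fingerprint.
#' @export
tabuContains <- function(tabu, ind) {
  key <- if (is.character(ind)) ind
         else .tabuKey(if (is(ind, "DagIndividual")) ind@amat else ind)
  key %in% tabu$keys
}

#' @rdname tabuList
#' @export
tabuInsert <- function(tabu, ind) {
  key <- if (is.character(ind)) ind
         else .tabuKey(if (is(ind, "DagIndividual")) ind@amat else ind)
  tabu$keys <- c(tabu$keys, key)
  if (length(tabu$keys) > tabu$capacity)
    tabu$keys <- tabu$keys[-seq_len(length(tabu$keys) - tabu$capacity)]
  invisible(tabu)
}

#' @rdname tabuList
#' @export
tabuSize <- function(tabu) length(tabu$keys)

# ---- initial network and population ----------------------------------------

#' Build the seed network from a mutual-information ranking
#'
#' Takes the top-N locus combinations of a [rankPairs()] ranking; loci
#' not covered by the top-N are covered by the first combination in the
#' remainder in which they appear.  Every top-N combination contributes
#' an edge from each involved SNP to the phenotype node plus chain edges
#' between the combination's SNPs oriented from lower to higher index
#' (which keeps the construction acyclic); coverage combinations
#' contribute a single SNP-SNP edge oriented toward the uncovered node,
#' so the phenotype node's parent family stays small enough to score
#' (`q = 3^(2N)` grows steeply with N, and every uninformative SNP
#' seeded into that family hands the search a reason to prune it
#' wholesale; hence the default `topN = 1` when a single interaction is
#' sought) and no node accumulates a large parent family before the
#' search starts.
#'
#' @param ranked data.frame from [rankPairs()].
#' @param topN number of leading combinations to seed with.
#' @param snps character vector of all SNP names (defines node order).
#' @return A [DagIndividual-class] seed network.
#' @export
buildInitialNetwork <- function(ranked, topN, snps) {
  stopifnot(nrow(ranked) >= 1, topN >= 1)
  idxCols <- grep("^snp", names(ranked))
  sel <- seq_len(min(topN, nrow(ranked)))
  covered <- unique(unlist(ranked[sel, idxCols]))
  rest <- setdiff(seq_len(nrow(ranked)), sel)
  dag <- emptyDag(snps)
  a <- dag@amat
  cls <- ncol(a)
  for (r in sel) {
    nodes <- sort(unlist(ranked[r, idxCols]))
    a[nodes, cls] <- 1L
    for (j in seq_len(length(nodes) - 1L)) a[nodes[j], nodes[j + 1L]] <- 1L
  }
  for (node in setdiff(seq_along(snps), covered)) {
    if (node %in% covered) next
    hit <- rest[which(apply(ranked[rest, idxCols, drop = FALSE] == node,
                            1L, any))[1L]]
    if (is.na(hit) || !length(hit)) next
    nodes <- unlist(ranked[hit, idxCols])
    partner <- setdiff(nodes, node)[1L]
    a[partner, node] <- 1L     # one parent for the fresh node; no cycle risk
    covered <- unique(c(covered, nodes))
    rest <- setdiff(rest, hit)
  }
  dagIndividual(a)
}

# one random legal single-edge edit of a plain adjacency matrix; the edit
# type is drawn uniformly from {add, drop, reverse} so perturbation does
# not drift toward denser graphs, then a random applicable edge is tried
.randomEditAmat <- function(a, forbidClassOut = FALSE, maxAttempts = 200L) {
  n <- nrow(a)
  for (t in seq_len(maxAttempts)) {
    op <- sample(c("add", "drop", "reverse"), 1L)
    if (op != "add") {
      e <- which(a == 1L)
      if (!length(e)) next
      pick <- if (length(e) == 1L) e else sample(e, 1L)
      from <- ((pick - 1L) %% n) + 1L
      to <- ((pick - 1L) %/% n) + 1L
      if (op == "drop") { a[from, to] <- 0L; return(a) }
      if (forbidClassOut && to == n) next
      a[from, to] <- 0L
      if (.wouldCycleAmat(a, to, from)) { a[from, to] <- 1L; next }
      a[to, from] <- 1L
      return(a)
    }
    from <- sample.int(n, 1L)
    to <- sample.int(n, 1L)
    if (from == to || a[from, to] == 1L) next
    if (forbidClassOut && from == n) next
    if (.wouldCycleAmat(a, from, to)) next
    a[from, to] <- 1L
    return(a)
  }
  # dense fallback: drop a random present edge
  e <- which(a == 1L)
  if (length(e)) a[sample(e, 1L)] <- 0L
  a
}

#' Generate the initial population by chained single-edge edits
#'
#' Starting from the seed network, each next individual is obtained from
#' its predecessor by one random legal edit (add, drop or reverse an
#' edge) that does not create a ring, until the population size is
#' reached.
#'
#' @param seedNetwork a [DagIndividual-class].
#' @param cfg a [GAConfig-class].
#' @return A list of [DagIndividual-class] objects of length
#'   `populationSize`, the seed first.
#' @export
generateInitialPopulation <- function(seedNetwork, cfg) {
  stopifnot(is(seedNetwork, "DagIndividual"), is(cfg, "GAConfig"))
  pop <- vector("list", cfg@populationSize)
  pop[[1L]] <- seedNetwork
  a <- seedNetwork@amat
  for (i in seq_len(cfg@populationSize)[-1L]) {
    a <- .randomEditAmat(a, cfg@forbidClassOut)
    pop[[i]] <- dagIndividual(a)
  }
  pop
}

# ---- selection --------------------------------------------------------------

#' Roulette-wheel selection
#'
#' Samples indices with probability proportional to fitness,
#' `P_i = f_i / sum(f)`.  Fitness values must be strictly positive; BIC
#' scores are first shifted by [shiftFitness()].
#'
#' @param fitness strictly positive fitness values.
#' @param n number of draws.
#' @return Integer indices of the selected individuals.
#' @export
rouletteSelect <- function(fitness, n = 1L) {
  if (any(fitness <= 0)) stop("fitness values must be strictly positive",
                              call. = FALSE)
  sample.int(length(fitness), n, replace = TRUE, prob = fitness)
}

#' Shift BIC scores to strictly positive roulette fitness
#'
#' `f_i = BIC_i - min(BIC) + delta`, preserving ranking while
#' guaranteeing positivity.  The default offset is half the population
#' score range, which caps the selection ratio between the best and the
#' worst individual at 3:1 — enough pressure to drive the search while
#' keeping diversity (a vanishing offset makes roulette selection
#' winner-takes-all whenever scores spread over many units, collapsing
#' the population into clones of the current best within a couple of
#' generations).  A population with all-equal scores yields uniform
#' selection.
#'
#' @param scores numeric BIC scores (typically negative).
#' @param delta positive offset; default `max(range/2, 1e-8)`.
#' @return Strictly positive fitness values.
#' @export
shiftFitness <- function(scores, delta = NULL) {
  if (is.null(delta))
    delta <- max((max(scores) - min(scores)) / 2, 1e-8)
  scores - min(scores) + delta
}

# ---- crossover --------------------------------------------------------------

# exchange the given columns (parent sets) row by row between two
# adjacency matrices, skipping any row whose exchange would put a ring
# or self-loop into either offspring-in-progress.
.crossoverAmat <- function(a1, a2, cols, forbidClassOut = FALSE) {
  n <- nrow(a1)
  for (f in cols) {
    for (r in seq_len(n)) {
      v1 <- a1[r, f]; v2 <- a2[r, f]
      if (v1 == v2) next
      if (r == f) next                       # never install a self-loop
      if (forbidClassOut && r == n) next
      if (v2 == 1L && .wouldCycleAmat(a1, r, f)) next
      if (v1 == 1L && .wouldCycleAmat(a2, r, f)) next
      a1[r, f] <- v2; a2[r, f] <- v1
    }
  }
  list(a1, a2)
}

#' Multi-column crossover with ring avoidance
#'
#' Randomly selects two columns of the adjacency matrix — i.e. the
#' parent sets of two nodes — and exchanges them between the two
#' individuals row by row; a row whose exchange would create a ring in
#' either offspring is skipped and the exchange continues with the next
#' row, so both offspring are guaranteed acyclic.
#'
#' @param parent1,parent2 [DagIndividual-class] parents over the same
#'   node set.
#' @param forbidClassOut disallow edges out of the phenotype node.
#' @return A list of two offspring [DagIndividual-class] objects.
#' @export
crossover <- function(parent1, parent2, forbidClassOut = FALSE) {
  stopifnot(is(parent1, "DagIndividual"), is(parent2, "DagIndividual"),
            identical(nodeNames(parent1), nodeNames(parent2)))
  n <- nrow(parent1@amat)
  cols <- sample.int(n, 2L)
  off <- .crossoverAmat(parent1@amat, parent2@amat, cols,
                        forbidClassOut)
  list(dagIndividual(off[[1L]]), dagIndividual(off[[2L]]))
}

#' Tabu crossover
#'
#' Repeats the ring-avoiding crossover with fresh random columns until
#' neither offspring is a member of the tabu list, up to `maxRetries`
#' attempts (the unbounded loop of the original formulation is bounded
#' to guarantee termination).  Accepted offspring are appended to the
#' tabu list, evicting the oldest entries beyond capacity.
#'
#' @inheritParams crossover
#' @param tabu a [tabuList()].
#' @param maxRetries retry bound; on exhaustion the last offspring are
#'   returned flagged as unaccepted.
#' @return A list with elements `offspring` (list of two
#'   [DagIndividual-class]), `accepted` (logical: offspring passed the
#'   tabu test) and `retries`.
#' @export
tabuCrossover <- function(parent1, parent2, tabu, maxRetries = 10L,
                          forbidClassOut = FALSE) {
  off <- NULL
  for (try in seq_len(maxRetries)) {
    off <- crossover(parent1, parent2, forbidClassOut)
    k1 <- .tabuKey(off[[1L]]@amat); k2 <- .tabuKey(off[[2L]]@amat)
    if (!tabuContains(tabu, k1) && !tabuContains(tabu, k2)) {
      tabuInsert(tabu, k1); tabuInsert(tabu, k2)
      return(list(offspring = off, accepted = TRUE, retries = try))
    }
  }
  # retry bound exhausted: return the last offspring flagged unaccepted
  list(offspring = off, accepted = FALSE, retries = maxRetries)
}

# ---- mutation ---------------------------------------------------------------

#' Point mutation of one network
#'
#' With probability `pm`, flips one uniformly chosen off-diagonal entry
#' of the adjacency matrix.  The mutant replaces the input only when it
#' is acyclic and strictly improves the fitness; otherwise the input is
#' returned unchanged.
#'
#' @param ind a scored [DagIndividual-class] (score slot set).
#' @param table the [GenotypeTable-class] used for scoring.
#' @param pm mutation probability.
#' @param base logarithm base of the BIC.
#' @param forbidClassOut disallow edges out of the phenotype node.
#' @return A [DagIndividual-class]: the accepted mutant (score updated)
#'   or the unchanged input.
#' @export
mutateIndividual <- function(ind, table, pm, base = exp(1),
                             forbidClassOut = FALSE) {
  stopifnot(is(ind, "DagIndividual"))
  if (runif(1) >= pm) return(ind)
  if (is.na(ind@score)) ind@score <- bicScore(ind, table, base = base)
  a <- .mutateFlip(ind@amat, forbidClassOut)
  if (is.null(a)) return(ind)
  sc <- bicScore(dagIndividual(a), table, base = base)
  if (sc > ind@score) dagIndividual(a, score = sc) else ind
}

# flip one random off-diagonal entry; NULL when the flip makes a ring
.mutateFlip <- function(a, forbidClassOut = FALSE) {
  n <- nrow(a)
  repeat {
    from <- sample.int(n, 1L)
    to <- sample.int(n, 1L)
    if (from != to) break
  }
  if (a[from, to] == 1L) { a[from, to] <- 0L; return(a) }
  if (forbidClassOut && from == n) return(NULL)
  if (.wouldCycleAmat(a, from, to)) return(NULL)
  a[from, to] <- 1L
  a
}

#' Tabu mutation over a population
#'
#' Considers every individual independently for mutation at rate `pm`.
#' A candidate mutant is accepted only when it is acyclic, strictly
#' fitness-improving and not a member of the tabu list; mutants rejected
#' for degrading the fitness are recorded in the tabu list so roundabout
#' revisits are blocked.
#'
#' @param pop list of [DagIndividual-class] with score slots set.
#' @param table the [GenotypeTable-class] used for scoring.
#' @param tabu a [tabuList()] (separate from the crossover list).
#' @param cfg a [GAConfig-class].
#' @param cache optional score cache environment passed to [bicScore()].
#' @return The population list, same length, with accepted mutants
#'   substituted.
#' @export
tabuMutate <- function(pop, table, tabu, cfg, cache = NULL) {
  nd <- .nodeData(table)
  for (i in seq_along(pop)) {
    if (runif(1) >= cfg@mutationProb) next
    a <- .mutateFlip(pop[[i]]@amat, cfg@forbidClassOut)
    if (is.null(a)) next
    key <- .tabuKey(a)
    if (tabuContains(tabu, key)) next
    sc <- .bicAmat(a, nd$data, nd$arity, base = cfg@logBase, cache = cache)
    if (sc > pop[[i]]@score) {
      pop[[i]] <- dagIndividual(a, score = sc)
    } else {
      tabuInsert(tabu, key)       # remember the inferior mutant
    }
  }
  pop
}

# ---- the search -------------------------------------------------------------

#' Genetic-tabu Bayesian network structure search
#'
#' Full search pipeline: encode the genotype table as bitstrings, rank
#' locus combinations by mutual information with the phenotype, build
#' the seed network from the top-N combinations, grow the initial
#' population by chained single-edge edits, then evolve it by roulette
#' selection, tabu crossover with ring avoidance and tabu mutation,
#' scoring every network by BIC.  The best individual ever seen is
#' tracked outside the population (elitism), so its fitness is
#' monotonically non-decreasing.  The loop stops at `maxIterations`, or
#' after `stagnationK` generations without improvement of the best
#' fitness, or when the optional `fitnessThreshold` is reached.
#'
#' @param table a [GenotypeTable-class].
#' @param cfg a [GAConfig-class]; `cfg@seed` seeds all randomness, so
#'   identical inputs reproduce identical histories.
#' @param ranked optional precomputed [rankPairs()] ranking (skips the
#'   screen, e.g. after thresholding).
#' @return A list with elements `best` (the best [DagIndividual-class],
#'   score slot set), `history` (data.frame of generation, bestScore,
#'   meanScore, tabuHits), `ranked` (the mutual-information ranking),
#'   `generations` (number run) and `config`.
#' @examples
#' \donttest{
#' sim <- simulateDataset(buildPenetrance(2, maf = 0.4, h2 = 0.4),
#'                        nNoiseSnps = 8, nCases = 200, nControls = 200)
#' fit <- epiSearch(sim$table, gaConfig(seed = 7))
#' fit$best
#' }
#' @export
epiSearch <- function(table, cfg = gaConfig(), ranked = NULL) {
  stopifnot(is(table, "GenotypeTable"), is(cfg, "GAConfig"))
  set.seed(cfg@seed)
  nd <- .nodeData(table)
  cache <- new.env(parent = emptyenv())
  if (is.null(ranked)) {
    bits <- encodeBits(table)
    ranked <- rankPairs(bits, k = cfg@kLoci, base = cfg@logBase)
  }
  seedNet <- buildInitialNetwork(ranked, cfg@topN, snpNames(table))
  pop <- generateInitialPopulation(seedNet, cfg)
  score1 <- function(ind) {
    if (is.na(ind@score))
      ind@score <- .bicAmat(ind@amat, nd$data, nd$arity,
                            base = cfg@logBase, cache = cache)
    ind
  }
  pop <- lapply(pop, score1)
  scores <- vapply(pop, slot, 1, "score")
  bestIdx <- which.max(scores)
  best <- pop[[bestIdx]]
  tabuX <- tabuList(cfg@tabuLength)
  tabuM <- tabuList(cfg@tabuLength)
  history <- data.frame(generation = 0L, bestScore = best@score,
                        meanScore = mean(scores), tabuHits = 0L)
  stagnant <- 0L
  bestMean <- mean(scores)
  gens <- 0L
  for (gen in seq_len(cfg@maxIterations)) {
    gens <- gen
    fitness <- shiftFitness(scores)
    tabuHits <- 0L
    nextPop <- vector("list", 0L)
    while (length(nextPop) < cfg@populationSize) {
      # parents drawn by roulette without replacement within the pair:
      # crossing an individual with itself cannot produce new offspring
      pair <- rouletteSelect(fitness, 2L)
      for (retry in seq_len(10L)) {
        if (pair[1L] != pair[2L] || length(fitness) == 1L) break
        pair[2L] <- rouletteSelect(fitness, 1L)
      }
      p1 <- pop[[pair[1L]]]; p2 <- pop[[pair[2L]]]
      if (runif(1) < cfg@crossoverProb) {
        xo <- tabuCrossover(p1, p2, tabuX, cfg@maxRetries,
                            cfg@forbidClassOut)
        if (!xo$accepted) tabuHits <- tabuHits + 1L
        kids <- xo$offspring
      } else {
        kids <- list(p1, p2)
      }
      nextPop <- c(nextPop, kids)
    }
    pop <- lapply(nextPop[seq_len(cfg@populationSize)], score1)
    pop <- tabuMutate(pop, table, tabuM, cfg, cache = cache)
    scores <- vapply(pop, slot, 1, "score")
    genBest <- max(scores)
    genMean <- mean(scores)
    improved <- genBest > best@score || genMean > bestMean
    if (genBest > best@score) best <- pop[[which.max(scores)]]
    if (genMean > bestMean) bestMean <- genMean
    # stop only when neither the optimal individual nor the population
    # fitness improves for stagnationK consecutive generations
    stagnant <- if (improved) 0L else stagnant + 1L
    history <- rbind(history,
                     data.frame(generation = gen,
                                bestScore = best@score,
                                meanScore = mean(scores),
                                tabuHits = tabuHits))
    if (!is.na(cfg@fitnessThreshold) &&
        best@score >= cfg@fitnessThreshold) break
    if (stagnant >= cfg@stagnationK) break
  }
  list(best = best, history = history, ranked = ranked,
       generations = gens, config = cfg)
}
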