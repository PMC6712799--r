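#' @rdname mutualInformation
#' @section Log base:
#' All entropies use the logarithm base given by `base` (default natural
#' log, i.e. nats).  Rankings of locus combinations are invariant to the
#' base; absolute thresholds on mutual information are not, so a threshold
#' must be interpreted in the same base it was derived in.
#' @export
entropyClass <- function(bits, base = exp(1)) {
  stopifnot(is(bits, "BitMatrix"))
  n <- bits@nSamples
  p <- c(.popcount(bits@classBits[[1L]]), .popcount(bits@classBits[[2L]])) / n
  -sum(ifelse(p > 0, p * log(p, base = base), 0))
}

#' Joint probability of a genotype assignment by bitwise AND + popcount
#'
#' Estimates the maximum-likelihood plug-in probability that a sample
#' simultaneously carries the given genotype value at each listed SNP
#' (and, optionally, the given class value) as
#' `popcount(AND of the selected bitstrings) / nSamples`.
#'
#' @param bits a [BitMatrix-class].
#' @param assignment list of `c(snpIndex, genotypeValue)` pairs; may be
#'   empty when `classValue` is given.
#' @param classValue optional class value 0/1 to intersect with.
#' @return The joint relative frequency, a number in `[0, 1]`.
#' @examples
#' g <- matrix(c(1L,1L,0L,1L, 1L,0L,0L,1L), ncol = 2,
#'             dimnames = list(NULL, c("SNPB", "SNPC")))
#' bits <- encodeBits(GenotypeTable(g, c(1, 0, 1, 0)))
#' jointProb(bits, list(c(1, 1), c(2, 1)))  # = 2/4
#' @export
jointProb <- function(bits, assignment = list(), classValue = NULL) {
  stopifnot(is(bits, "BitMatrix"))
  if (!length(assignment) && is.null(classValue))
    stop("give at least one SNP assignment or a class value", call. = FALSE)
  sel <- lapply(assignment, function(a) {
    s <- a[[1L]]; v <- a[[2L]]
    if (s < 1L || s > length(bits@snpBits))
      stop("SNP index ", s, " out of range", call. = FALSE)
    if (!(v %in% 0:2))
      stop("genotype value ", v, " is not 0/1/2", call. = FALSE)
    bits@snpBits[[s]][[v + 1L]]
  })
  if (!is.null(classValue)) {
    if (!(classValue %in% 0:1))
      stop("class value ", classValue, " is not 0/1", call. = FALSE)
    sel <- c(sel, list(bits@classBits[[classValue + 1L]]))
  }
  acc <- Reduce(`&`, sel)
  .popcount(acc) / bits@nSamples
}

#' Joint entropy of SNP loci, optionally with the phenotype
#'
#' Sums `-p log p` over all `3^k` genotype-value cells of the given loci
#' (times the two class values when `includeClass = TRUE`), with each cell
#' probability computed by bitwise AND + popcount and the convention
#' `0 log 0 = 0`.
#'
#' @inheritParams jointProb
#' @param snpIndices distinct SNP indices (1-based), at most `kMax` of them.
#' @param includeClass also condition cells on the phenotype value.
#' @param base logarithm base (default natural log).
#' @param kMax cap on the number of loci, guarding the `3^k` cell
#'   enumeration (default 3, the largest interaction order searched).
#' @return The joint entropy, a non-negative number.
#' @export
jointEntropy <- function(bits, snpIndices, includeClass = FALSE,
                         base = exp(1), kMax = 3L) {
  stopifnot(is(bits, "BitMatrix"))
  k <- length(snpIndices)
  if (k < 1L || k > kMax)
    stop("number of loci must be between 1 and ", kMax, call. = FALSE)
  if (anyDuplicated(snpIndices))
    stop("SNP indices must be distinct", call. = FALSE)
  cells <- expand.grid(rep(list(0:2), k))
  classVals <- if (includeClass) 0:1 else NA
  h <- 0
  for (cv in classVals) {
    for (r in seq_len(nrow(cells))) {
      asn <- lapply(seq_len(k), function(j) c(snpIndices[j], cells[r, j]))
      p <- jointProb(bits, asn, classValue = if (is.na(cv)) NULL else cv)
      if (p > 0) h <- h - p * log(p, base = base)
    }
  }
  h
}

#' Mutual information between loci and the case-control phenotype
#'
#' Computes `I(Class | SNP_1, ..., SNP_k) = H(Class) + H(SNP_1..SNP_k)
#' - H(Class, SNP_1..SNP_k)` from the one-hot bitstring encoding.
#' Tiny negative values from floating-point rounding (above `-1e-12`)
#' are clamped to zero; larger negatives signal an internal error.
#'
#' @inheritParams jointEntropy
#' @return The mutual information in the units of `base`, a non-negative
#'   number bounded by `H(Class)`.
#' @export
mutualInformation <- function(bits, snpIndices, base = exp(1), kMax = 3L) {
  mi <- entropyClass(bits, base = base) +
    jointEntropy(bits, snpIndices, includeClass = FALSE, base = base,
                 kMax = kMax) -
    jointEntropy(bits, snpIndices, includeClass = TRUE, base = base,
                 kMax = kMax)
  if (mi < 0) {
    if (mi < -1e-12)
      stop("internal error: mutual information ", mi, " below -1e-12",
           call. = FALSE)
    mi <- 0
  }
  mi
}

#' Rank all k-locus combinations by mutual information with the phenotype
#'
#' Scores every combination of `k` SNPs by `I(Class | SNPs)` and returns
#' them sorted in non-increasing order, ties broken by lexicographic index
#' order so the ranking is deterministic.
#'
#' @inheritParams jointEntropy
#' @param k interaction order, 2 or 3.
#' @param maxCombos budget on `choose(nSnps, k)`; exceeding it raises an
#'   error suggesting a prefilter (see [chisqPrefilter()]).
#' @return A data.frame with columns `snp1`, `snp2` (and `snp3` for
#'   `k = 3`) holding SNP indices in increasing order, matching name
#'   columns `name1`, `name2` (, `name3`), and `mi`.
#' @export
rankPairs <- function(bits, k = 2L, base = exp(1), maxCombos = 2e6) {
  stopifnot(is(bits, "BitMatrix"))
  if (!(k %in% 2:3)) stop("k must be 2 or 3", call. = FALSE)
  m <- length(bits@snpBits)
  if (choose(m, k) > maxCombos)
    stop("choose(", m, ", ", k, ") combinations exceed the budget of ",
         maxCombos, "; prefilter the loci first (see chisqPrefilter)",
         call. = FALSE)
  combos <- combn(m, k)
  mi <- .rankMiFast(bits, combos, base)
  out <- as.data.frame(t(combos))
  names(out) <- paste0("snp", seq_len(k))
  for (j in seq_len(k))
    out[[paste0("name", j)]] <- bits@snpNames[combos[j, ]]
  out$mi <- mi
  ord <- do.call(order, c(list(-out$mi), out[paste0("snp", seq_len(k))]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorised MI over many combinations: precomputes per-SNP x value x class
# raw strings once, then AND/popcount per cell.
.rankMiFast <- function(bits, combos, base) {
  n <- bits@nSamples
  hC <- entropyClass(bits, base = base)
  k <- nrow(combos)
  cells <- as.matrix(expand.grid(rep(list(1:3), k)))
  apply(combos, 2L, function(idx) {
    hS <- 0; hSC <- 0
    for (r in seq_len(nrow(cells))) {
      acc <- bits@snpBits[[idx[1L]]][[cells[r, 1L]]]
      for (j in seq_len(k)[-1L])
        acc <- acc & bits@snpBits[[idx[j]]][[cells[r, j]]]
      p <- .popcount(acc) / n
      if (p > 0) hS <- hS - p * log(p, base = base)
      for (cv in 1:2) {
        pc <- .popcount(acc & bits@classBits[[cv]]) / n
        if (pc > 0) hSC <- hSC - pc * log(pc, base = base)
      }
    }
    max(hC + hS - hSC, 0)
  })
}

#' Export ranked locus combinations as TSV
#'
#' Writes the `name*` and `mi` columns of a [rankPairs()] ranking in a
#' `SNP1 <tab> SNP2 [<tab> SNP3] <tab> MI` layout.
#'
#' @param ranked a data.frame from [rankPairs()] (or [extractPairs()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePairs <- function(ranked, path) {
  nameCols <- grep("^name", names(ranked), value = TRUE)
  out <- ranked[c(nameCols, "mi")]
  names(out) <- c(paste0("SNP", seq_along(nameCols)), "MI")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
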