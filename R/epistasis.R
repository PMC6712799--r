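#' Extract ranked epistatic pairs from a learned network
#'
#' Reads candidate epistatic SNP pairs off the best network found by the
#' search.  Under the `"adjacent"` rule a pair is reported when both
#' SNPs are adjacent to the phenotype node (an edge in either
#' direction); `"parents"` restricts to SNPs that are parents of the
#' phenotype node; `"snp-edge"` reports SNP-SNP edges with at least one
#' endpoint adjacent to the phenotype.  The default `"combined"` rule is
#' the union of `"adjacent"` and `"snp-edge"`: score-equivalent networks
#' can place an interaction either as two edges into the phenotype node
#' or as an SNP-SNP edge whose child also links to the phenotype, and
#' both placements describe the same dependence.  Every reported pair is
#' annotated
#' with its mutual information `I(Class | SNP1, SNP2)` and the report is
#' sorted by decreasing MI, ties broken by SNP names.
#'
#' @param best a [DagIndividual-class], typically `epiSearch(...)$best`.
#' @param bits the [BitMatrix-class] of the same genotype table.
#' @param rule extraction rule, see above.
#' @param base logarithm base for the MI annotation.
#' @return A data.frame with columns `name1`, `name2`, `snp1`, `snp2`
#'   and `mi` (possibly zero rows, with a warning, when no SNP is
#'   adjacent to the phenotype node).
#' @export
extractPairs <- function(best, bits, rule = c("combined", "adjacent",
                                              "parents", "snp-edge"),
                         base = exp(1)) {
  stopifnot(is(best, "DagIndividual"), is(bits, "BitMatrix"))
  rule <- match.arg(rule)
  a <- best@amat
  cls <- nrow(a)
  stopifnot(length(bits@snpBits) == cls - 1L)
  adj <- which(a[-cls, cls] == 1L | a[cls, -cls] == 1L)
  adjacentPairs <- function() {
    if (length(adj) >= 2L) t(combn(adj, 2L)) else matrix(integer(0), 0, 2)
  }
  snpEdgePairs <- function() {
    e <- which(a[-cls, -cls, drop = FALSE] == 1L, arr.ind = TRUE)
    keep <- e[, 1L] %in% adj | e[, 2L] %in% adj
    e <- e[keep, , drop = FALSE]
    cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  }
  pairs <- switch(rule,
    combined = rbind(adjacentPairs(), snpEdgePairs()),
    adjacent = adjacentPairs(),
    parents = {
      par <- which(a[-cls, cls] == 1L)
      if (length(par) >= 2L) t(combn(par, 2L))
      else matrix(integer(0), 0, 2)
    },
    `snp-edge` = snpEdgePairs())
  if (!nrow(pairs)) {
    warning("no SNP pair qualifies under rule '", rule,
            "'; returning an empty report")
    return(data.frame(name1 = character(0), name2 = character(0),
                      snp1 = integer(0), snp2 = integer(0),
                      mi = numeric(0)))
  }
  pairs <- unique(pairs)
  mi <- vapply(seq_len(nrow(pairs)), function(r)
    mutualInformation(bits, pairs[r, ], base = base), 1)
  out <- data.frame(name1 = bits@snpNames[pairs[, 1L]],
                    name2 = bits@snpNames[pairs[, 2L]],
                    snp1 = pairs[, 1L], snp2 = pairs[, 2L], mi = mi)
  out <- out[order(-out$mi, out$name1, out$name2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detection accuracy over a batch of datasets
#'
#' The published evaluation protocol: a dataset counts as recovered when
#' its full planted SNP set appears as one reported tuple within the top
#' `topM` entries of its report; accuracy is the recovered fraction.
#'
#' @param reports list of reports (data.frames from [extractPairs()]),
#'   one per dataset.
#' @param truths list of character vectors of planted SNP names, one per
#'   dataset.
#' @param topM how deep into each report to look (default unlimited).
#' @return A list with `nDatasets`, `numEdge` (datasets recovered) and
#'   `accuracy = numEdge / nDatasets`.
#' @export
detectionAccuracy <- function(reports, truths, topM = Inf) {
  if (length(reports) != length(truths))
    stop("need exactly one truth set per report", call. = FALSE)
  hit <- mapply(function(rep, truth) {
    if (!nrow(rep)) return(FALSE)
    nameCols <- grep("^name", names(rep), value = TRUE)
    top <- rep[seq_len(min(nrow(rep), topM)), nameCols, drop = FALSE]
    any(apply(top, 1L, function(tuple) setequal(tuple, truth)))
  }, reports, truths)
  list(nDatasets = length(reports), numEdge = sum(hit),
       accuracy = sum(hit) / length(reports))
}

#' Chi-square prefilter of SNP loci
#'
#' Per-SNP genotype-by-class contingency chi-square test (no continuity
#' correction); genotype values unobserved in the data drop out of the
#' table and its degrees of freedom.  By default SNPs with `p` below the
#' threshold are kept (the marginally associated loci); `keepBelow =
#' FALSE` inverts the direction.  SNPs with a constant genotype column
#' carry no test and are dropped.
#'
#' @param table a [GenotypeTable-class].
#' @param pThreshold significance threshold in (0, 1), default 0.01.
#' @param keepBelow keep SNPs with `p < pThreshold` (default) rather
#'   than the complement.
#' @return The reduced [GenotypeTable-class], sample order preserved.
#' @export
chisqPrefilter <- function(table, pThreshold = 0.01, keepBelow = TRUE) {
  stopifnot(is(table, "GenotypeTable"),
            pThreshold > 0, pThreshold < 1)
  g <- genoMatrix(table)
  ph <- phenotype(table)
  p <- vapply(seq_len(ncol(g)), function(j) {
    tab <- base::table(g[, j], ph)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }, 1)
  keep <- if (keepBelow) !is.na(p) & p < pThreshold
          else !is.na(p) & p >= pThreshold
  if (any(is.na(p)))
    message(sum(is.na(p)), " constant SNP column(s) dropped")
  if (sum(keep) < 2L)
    stop("fewer than two SNPs pass the chi-square prefilter", call. = FALSE)
  GenotypeTable(g[, keep, drop = FALSE], ph)
}
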