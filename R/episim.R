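#' PenetranceModel: a purely epistatic k-locus disease model
#'
#' A `3^k` penetrance table `P(case | genotype combination)` over `k`
#' interacting loci with genotype frequencies under Hardy-Weinberg
#' equilibrium at the given minor-allele frequency.  "Purely epistatic"
#' means every single-locus marginal penetrance (weighted by the HW
#' genotype frequencies of the other loci) equals the prevalence, so no
#' locus carries a main effect.  Heritability is the variance of the
#' penetrance around the prevalence scaled by `K (1 - K)`.
#'
#' @slot k number of interacting loci (2 or 3).
#' @slot maf per-locus minor-allele frequency.
#' @slot prevalence population case probability `K` of the table.
#' @slot h2 achieved heritability.
#' @slot targetH2 requested heritability.
#' @slot table numeric array of dimension `rep(3, k)` with penetrance
#'   values in `[0, 1]`; dimension *d* indexes locus *d*'s genotype
#'   0/1/2.
#' @export
setClass("PenetranceModel",
  representation(k = "integer", maf = "numeric", prevalence = "numeric",
                 h2 = "numeric", targetH2 = "numeric", table = "array"))

setValidity("PenetranceModel", function(object) {
  if (!(object@k %in% 2:3)) return("k must be 2 or 3")
  if (any(object@table < 0 | object@table > 1))
    return("penetrance values must lie in [0, 1]")
  if (!identical(dim(object@table), rep(3L, object@k)))
    return("penetrance table must have dimension rep(3, k)")
  w <- .hwFreq(object@maf)
  for (d in seq_len(object@k)) {
    marg <- apply(object@table, d, function(slice)
      sum(slice * .jointWeight(object@maf, object@k - 1L)))
    if (max(abs(marg - object@prevalence)) > 1e-6)
      return(sprintf("locus %d carries a main effect (marginal deviates by %.2g)",
                     d, max(abs(marg - object@prevalence))))
  }
  if (abs(object@h2 - .h2Of(object@table, object@maf,
                            object@prevalence)) > 1e-8)
    return("stored h2 does not match the table")
  TRUE
})

.hwFreq <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# joint HW weight vector over `k` loci (flattened array order)
.jointWeight <- function(maf, k) {
  w <- 1
  for (d in seq_len(k)) w <- outer(w, .hwFreq(maf))
  as.vector(w)
}

.h2Of <- function(tab, maf, K) {
  f <- array(.jointWeight(maf, length(dim(tab))), dim = dim(tab))
  sum(f * (tab - K)^2) / (K * (1 - K))
}

setMethod("show", "PenetranceModel", function(object) {
  cat(sprintf(paste0("PenetranceModel: %d loci, MAF %.3g, ",
                     "prevalence %.4g, h2 %.4g (target %.4g)\n"),
              object@k, object@maf, object@prevalence, object@h2,
              object@targetH2))
})

#' @describeIn PenetranceModel the achieved heritability, recomputable
#'   from the table
#' @param model a `PenetranceModel`
#' @export
penetranceH2 <- function(model) .h2Of(model@table, model@maf,
                                      model@prevalence)

#' @describeIn PenetranceModel marginal penetrance of one locus by
#'   genotype value (all equal the prevalence for a purely epistatic
#'   model)
#' @param locus locus index in `1..k`
#' @export
marginalPenetrance <- function(model, locus) {
  apply(model@table, locus, function(slice)
    sum(slice * .jointWeight(model@maf, model@k - 1L)))
}

# HW-weighted marginal mean of a deviation table over one locus
.locusMargin <- function(d, w, dd, k) {
  if (k == 2L) {
    if (dd == 1L) as.vector(d %*% w) else as.vector(w %*% d)
  } else {
    wo <- as.vector(outer(w, w))
    dm <- matrix(as.vector(aperm(d, c(dd, setdiff(1:3, dd)))), 3L)
    as.vector(dm %*% wo)
  }
}

# remove per-locus weighted marginal deviations (alternating projection
# onto the no-main-effect constraint set under the HW inner product)
.projectNoMain <- function(d, maf, k) {
  w <- .hwFreq(maf)
  for (sweep in 1:3) {
    for (dd in seq_len(k)) {
      d <- sweep(d, dd, .locusMargin(d, w, dd, k), `-`)
    }
  }
  d
}

#' Construct a purely epistatic penetrance model
#'
#' Random-search construction: sample a candidate deviation table,
#' project it onto the no-main-effect constraint (every locus's
#' HW-weighted marginal penetrance equals the prevalence), rescale the
#' deviations to hit the target heritability, clip into `[0, 1]` and
#' iterate; retry from a fresh candidate until the marginal constraint
#' holds to `1e-6` and the achieved heritability is within 5% of the
#' target.  When `prevalence` is `NULL` (the default) it is treated as
#' a free parameter, GAMETES-style: each attempt draws a prevalence at
#' which the target heritability is geometrically feasible and the
#' realised value is reported in the model.
#'
#' @param k number of interacting loci (2 or 3).
#' @param maf minor-allele frequency in (0, 0.5].
#' @param h2 target heritability in (0, 1).
#' @param prevalence fixed population case probability, or `NULL` to
#'   leave it free.
#' @param maxTries attempts before declaring the parameter combination
#'   infeasible.
#' @return A [PenetranceModel-class].
#' @examples
#' set.seed(1)
#' m <- buildPenetrance(2, maf = 0.4, h2 = 0.1, prevalence = 0.2)
#' penetranceH2(m)
#' marginalPenetrance(m, 1)
#' @export
buildPenetrance <- function(k = 2L, maf, h2, prevalence = NULL,
                            maxTries = 500L) {
  stopifnot(k %in% 2:3, maf > 0, maf <= 0.5, h2 > 0, h2 < 1)
  if (!is.null(prevalence))
    stopifnot(prevalence > 0, prevalence < 1)
  freeK <- is.null(prevalence)
  f <- array(.jointWeight(maf, k), dim = rep(3L, k))
  for (try in seq_len(maxTries)) {
    K <- if (freeK) runif(1, 0.15, 0.6) else prevalence
    target <- h2 * K * (1 - K)
    d <- array(rnorm(3^k), dim = rep(3L, k))
    w <- .hwFreq(maf)
    for (it in 1:500) {
      d <- .projectNoMain(d, maf, k)
      v <- sum(f * d^2)
      if (v < 1e-12) break
      d <- d * sqrt(target / v)
      d <- pmin(pmax(d, -K), 1 - K)
      if (it %% 20L == 0L) {     # early exit once the loop has settled
        mdev <- max(vapply(seq_len(k), function(dd)
          max(abs(.locusMargin(d, w, dd, k))), 1))
        if (mdev <= 1e-8 && abs(sum(f * d^2) - target) / target <= 1e-6)
          break
      }
    }
    tab <- K + d
    margOk <- all(vapply(seq_len(k), function(dd)
      max(abs(.locusMargin(d, w, dd, k))) <= 1e-6, TRUE))
    h2a <- .h2Of(tab, maf, K)
    if (margOk && abs(h2a - h2) / h2 <= 0.05)
      return(new("PenetranceModel", k = as.integer(k), maf = maf,
                 prevalence = K, h2 = h2a, targetH2 = h2,
                 table = tab))
  }
  stop("no purely epistatic penetrance table with h2 = ", h2,
       ", MAF = ", maf,
       if (!freeK) paste0(", prevalence = ", prevalence) else "",
       " found in ", maxTries,
       " attempts: parameter combination appears infeasible",
       call. = FALSE)
}

#' Simulate one case-control dataset with a planted interaction
#'
#' Draws functional genotypes under Hardy-Weinberg equilibrium at the
#' model MAF, assigns disease status from the penetrance table, and
#' rejection-samples individuals until the case and control quotas are
#' reached.  Noise SNPs are drawn independently of status with MAFs
#' uniform in `noiseMafRange`.  The planted loci are placed at random
#' positions among the noise SNPs; their names are returned as the
#' truth set.
#'
#' @param model a [PenetranceModel-class].
#' @param nNoiseSnps number of noise SNPs (total SNPs = `k + nNoiseSnps`).
#' @param nCases,nControls sample quotas.
#' @param noiseMafRange range the noise-SNP MAFs are drawn from.
#' @param maxAttempts budget of simulated individuals per quota unit
#'   before giving up (guards extreme prevalence).
#' @return A list with `table` (a [GenotypeTable-class], planted SNPs
#'   named `P1..Pk`, noise SNPs `N1..`), `truth` (planted SNP names)
#'   and `model`.
#' @export
simulateDataset <- function(model, nNoiseSnps, nCases, nControls,
                            noiseMafRange = c(0.05, 0.5),
                            maxAttempts = 500L) {
  stopifnot(is(model, "PenetranceModel"), nNoiseSnps >= 1,
            nCases >= 1, nControls >= 1)
  k <- model@k
  n <- nCases + nControls
  hw <- .hwFreq(model@maf)
  caseG <- matrix(0L, 0L, k)
  ctrlG <- matrix(0L, 0L, k)
  for (attempt in seq_len(maxAttempts)) {
    chunk <- n
    g <- vapply(seq_len(k), function(d)
      sample(0:2, chunk, replace = TRUE, prob = hw), integer(chunk))
    pen <- model@table[g + 1L]   # matrix-indexing: one row per individual
    status <- rbinom(chunk, 1L, pen)
    caseG <- rbind(caseG, g[status == 1L, , drop = FALSE])
    ctrlG <- rbind(ctrlG, g[status == 0L, , drop = FALSE])
    if (nrow(caseG) >= nCases && nrow(ctrlG) >= nControls) break
  }
  if (nrow(caseG) < nCases || nrow(ctrlG) < nControls)
    stop("case/control quota unreachable within the attempt budget; ",
         "prevalence too extreme", call. = FALSE)
  funcG <- rbind(caseG[seq_len(nCases), , drop = FALSE],
                 ctrlG[seq_len(nControls), , drop = FALSE])
  ph <- c(rep(1L, nCases), rep(0L, nControls))
  # shuffle sample order so case/control blocks are interleaved
  ord <- sample.int(n)
  funcG <- funcG[ord, , drop = FALSE]
  ph <- ph[ord]
  noise <- vapply(seq_len(nNoiseSnps), function(j) {
    m <- runif(1, noiseMafRange[1L], noiseMafRange[2L])
    sample(0:2, n, replace = TRUE, prob = .hwFreq(m))
  }, integer(n))
  nTot <- k + nNoiseSnps
  pos <- sample.int(nTot, k)           # planted positions
  g <- matrix(0L, n, nTot)
  g[, pos] <- funcG
  g[, -pos] <- noise
  nm <- character(nTot)
  nm[pos] <- paste0("P", seq_len(k))
  nm[-pos] <- paste0("N", seq_len(nNoiseSnps))
  colnames(g) <- nm
  list(table = GenotypeTable(g, ph), truth = paste0("P", seq_len(k)),
       model = model)
}

#' Simulate a batch of dataset files with a truth manifest
#'
#' Writes `nFiles` GAMETES-dialect files, each generated with the
#' deterministic per-file seed `baseSeed + i - 1` (model construction
#' included), plus a JSON manifest mapping each file to its planted SNP
#' names and model parameters.
#'
#' @param outDir output directory (created if needed).
#' @param nFiles number of dataset files.
#' @param baseSeed base RNG seed.
#' @param k,maf,h2,prevalence passed to [buildPenetrance()].
#' @param nNoiseSnps,nCases,nControls,noiseMafRange passed to
#'   [simulateDataset()].
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json` in `outDir`).
#' @export
simulateBatch <- function(outDir, nFiles, baseSeed = 1L, k = 2L,
                          maf = 0.4, h2 = 0.4, prevalence = NULL,
                          nNoiseSnps = 18L, nCases = 400L,
                          nControls = 400L,
                          noiseMafRange = c(0.05, 0.5)) {
  stopifnot(nFiles >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", nFiles)
  for (i in seq_len(nFiles)) {
    set.seed(baseSeed + i - 1L)
    model <- buildPenetrance(k, maf = maf, h2 = h2,
                             prevalence = prevalence)
    sim <- simulateDataset(model, nNoiseSnps, nCases, nControls,
                           noiseMafRange)
    fname <- sprintf("sim_%03d.txt", i)
    writeGenotypes(sim$table, file.path(outDir, fname))
    entries[[i]] <- list(file = fname, truth = sim$truth,
                         seed = baseSeed + i - 1L,
                         k = k, maf = maf, h2Target = h2,
                         h2Achieved = model@h2,
                         prevalence = model@prevalence,
                         nCases = nCases, nControls = nControls,
                         nSnps = k + nNoiseSnps)
  }
  manifest <- list(baseSeed = baseSeed, nFiles = nFiles,
                   datasets = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
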