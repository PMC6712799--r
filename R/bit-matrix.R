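#' BitMatrix: bitwise Boolean encoding of a genotype table
#'
#' Per-SNP one-hot indicator bitstrings enabling probability estimation
#' by bitwise AND plus popcount (Hamming weight).  For each SNP there are
#' three bitstrings, one per genotype value 0/1/2, with bit *i* set when
#' sample *i* carries that value; the phenotype contributes two bitstrings
#' (control, case).  Bit position follows sample order, sample 1 first.
#'
#' Bitstrings are stored as `raw` vectors padded with zero bits to a whole
#' number of bytes; padding never affects counts because the one-hot
#' encoding leaves pad bits unset in every string.
#'
#' @slot snpBits list (one element per SNP) of lists of three raw vectors,
#'   indexed `[[value + 1]]` for genotype value 0/1/2.
#' @slot classBits list of two raw vectors, indexed `[[value + 1]]` for
#'   class value 0 (control) / 1 (case).
#' @slot nSamples integer, number of samples (= used bits per string).
#' @slot snpNames character, SNP identifiers aligned with `snpBits`.
#'
#' @seealso [encodeBits()], [jointProb()], [mutualInformation()]
#' @export
setClass("BitMatrix",
  representation(snpBits = "list", classBits = "list",
                 nSamples = "integer", snpNames = "character"))

setValidity("BitMatrix", function(object) {
  n <- object@nSamples
  if (length(object@snpBits) != length(object@snpNames))
    return("snpBits and snpNames lengths differ")
  for (s in seq_along(object@snpBits)) {
    b <- object@snpBits[[s]]
    if (length(b) != 3L) return("each SNP needs three value bitstrings")
    if (sum(vapply(b, .popcount, 1L)) != n)
      return(sprintf("SNP '%s' bitstrings do not partition the samples",
                     object@snpNames[s]))
  }
  if (length(object@classBits) != 2L) return("class needs two bitstrings")
  if (.popcount(object@classBits[[1L]]) + .popcount(object@classBits[[2L]]) != n)
    return("class bitstrings do not partition the samples")
  TRUE
})

# popcount of a raw vector via the byte lookup table
.popcount <- function(r) sum(.POP8[as.integer(r) + 1L])

.packIndicator <- function(logical01, n) {
  pad <- (-n) %% 8L
  packBits(c(logical01, rep(FALSE, pad)), type = "raw")
}

#' Encode a genotype table as one-hot bitstrings
#'
#' Converts genotype data to the binary Boolean format used for fast
#' bitwise mutual-information computation: bit *i* of the value-*v*
#' string of SNP *s* is set iff sample *i* has genotype *v* at *s*.
#'
#' @param table a [GenotypeTable-class].
#' @return A [BitMatrix-class].
#' @examples
#' g <- matrix(c(1L,1L,0L,1L, 1L,0L,0L,1L), ncol = 2,
#'             dimnames = list(NULL, c("SNPB", "SNPC")))
#' bits <- encodeBits(GenotypeTable(g, c(1, 0, 1, 0)))
#' jointProb(bits, list(c(1, 1), c(2, 1)))  # p(SNPB=1, SNPC=1) = 0.5
#' @export
encodeBits <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  g <- genoMatrix(table)
  n <- nrow(g)
  snpBits <- lapply(seq_len(ncol(g)), function(s) {
    col <- g[, s]
    lapply(0:2, function(v) .packIndicator(col == v, n))
  })
  ph <- phenotype(table)
  classBits <- lapply(0:1, function(v) .packIndicator(ph == v, n))
  new("BitMatrix", snpBits = snpBits, classBits = classBits,
      nSamples = n, snpNames = snpNames(table))
}

#' Decode a BitMatrix back to genotype and phenotype codes
#'
#' Inverse of [encodeBits()]; mainly for verifying that the encoding is
#' lossless.
#'
#' @param bits a [BitMatrix-class].
#' @return A [GenotypeTable-class] with the reconstructed codes.
#' @export
decodeBits <- function(bits) {
  stopifnot(is(bits, "BitMatrix"))
  n <- bits@nSamples
  unpack <- function(r) as.logical(rawToBits(r))[seq_len(n)]
  g <- vapply(bits@snpBits, function(b) {
    v <- integer(n)
    v[unpack(b[[2L]])] <- 1L
    v[unpack(b[[3L]])] <- 2L
    v
  }, integer(n))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  colnames(g) <- bits@snpNames
  ph <- integer(n)
  ph[unpack(bits@classBits[[2L]])] <- 1L
  GenotypeTable(g, ph)
}

setMethod("show", "BitMatrix", function(object) {
  cat(sprintf("BitMatrix: %d SNPs x %d samples (%d cases / %d controls)\n",
              length(object@snpBits), object@nSamples,
              .popcount(object@classBits[[2L]]),
              .popcount(object@classBits[[1L]])))
})
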