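#' GenotypeTable: a case-control genotype matrix
#'
#' Samples-by-SNPs matrix of genotype codes together with a binary
#' phenotype.  Genotypes are coded 0 (common homozygote), 1 (heterozygote),
#' 2 (rare homozygote); the phenotype is 1 for cases and 0 for controls.
#' Row order of the source file is preserved as sample order and defines
#' the bit positions used by [encodeBits()].
#'
#' @slot genotypes integer matrix, samples x SNPs, values in \{0,1,2\};
#'   column names are the SNP identifiers.
#' @slot phenotype integer vector of 0/1 disease status, one per sample.
#'
#' @seealso [readGenotypes()], [encodeBits()]
#' @export
setClass("GenotypeTable",
  representation(genotypes = "matrix", phenotype = "integer"))

setValidity("GenotypeTable", function(object) {
  g <- object@genotypes
  ph <- object@phenotype
  if (!is.numeric(g)) return("genotypes must be a numeric matrix")
  if (nrow(g) < 1L) return("at least one sample is required")
  if (ncol(g) < 2L) return("at least two SNPs are required")
  if (length(ph) != nrow(g))
    return("phenotype length must equal the number of samples")
  if (is.null(colnames(g))) return("SNP columns must be named")
  if (anyDuplicated(colnames(g))) return("SNP names must be unique")
  if ("Class" %in% colnames(g))
    return("'Class' is reserved for the phenotype column")
  bad <- which(!(g %in% 0:2))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(g)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(g)) + 1L
    return(sprintf("genotype value %s at row %d, SNP '%s' is not 0/1/2",
                   format(g[bad[1L]]), i, colnames(g)[j]))
  }
  if (!all(ph %in% 0:1)) {
    i <- which(!(ph %in% 0:1))[1L]
    return(sprintf("phenotype value %s at row %d is not 0/1",
                   format(ph[i]), i))
  }
  TRUE
})

#' Construct a GenotypeTable
#'
#' @param genotypes numeric matrix (samples x SNPs) of 0/1/2 codes with
#'   column names; a data.frame is accepted and coerced.
#' @param phenotype numeric vector of 0/1 case-control status.
#' @return A validated [GenotypeTable-class] object.
#' @examples
#' g <- matrix(c(0L,1L,2L,1L, 1L,1L,0L,2L), ncol = 2,
#'             dimnames = list(NULL, c("SNP1", "SNP2")))
#' gt <- GenotypeTable(g, c(1, 0, 1, 0))
#' nSamples(gt)
#' @export
GenotypeTable <- function(genotypes, phenotype) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  new("GenotypeTable", genotypes = genotypes,
      phenotype = as.integer(phenotype))
}

#' @describeIn GenotypeTable number of samples (rows)
#' @param x,object a `GenotypeTable`
#' @export
nSamples <- function(x) nrow(x@genotypes)

#' @describeIn GenotypeTable number of SNP loci (columns)
#' @export
nSnps <- function(x) ncol(x@genotypes)

#' @describeIn GenotypeTable SNP identifiers
#' @export
snpNames <- function(x) colnames(x@genotypes)

#' @describeIn GenotypeTable the samples x SNPs integer matrix
#' @export
genoMatrix <- function(x) x@genotypes

#' @describeIn GenotypeTable the 0/1 phenotype vector
#' @export
phenotype <- function(x) x@phenotype

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d samples x %d SNPs (%d cases / %d controls)\n",
              nSamples(object), nSnps(object),
              sum(object@phenotype == 1L), sum(object@phenotype == 0L)))
  nm <- snpNames(object)
  cat("  SNPs: ", paste(utils::head(nm, 6), collapse = ", "),
      if (length(nm) > 6) ", ..." else "", "\n", sep = "")
})

.sniffDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("file '", path, "' is empty", call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a GAMETES-dialect genotype table
#'
#' Reads a delimited text file with a header of SNP names plus a
#' case-control class column, one sample per row, genotype codes 0/1/2
#' and class codes 0/1.  The delimiter is auto-detected between tab and
#' comma unless given.
#'
#' @param path path to the file.
#' @param delimiter field separator; `NULL` (default) auto-detects tab
#'   versus comma from the header line.
#' @param classColumn name of the phenotype column (default `"Class"`).
#'   If absent, the last column is used with a warning.
#' @return A [GenotypeTable-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, delimiter = NULL, classColumn = "Class") {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is.null(delimiter)) delimiter <- .sniffDelim(path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = delimiter, check.names = FALSE,
               colClasses = "integer", comment.char = ""),
    error = function(e)
      stop("malformed genotype file '", path, "': ", conditionMessage(e),
           call. = FALSE))
  if (!ncol(df)) stop("no columns parsed from '", path, "'", call. = FALSE)
  ci <- match(classColumn, colnames(df))
  if (is.na(ci)) {
    warning("class column '", classColumn, "' not found in '", path,
            "'; using last column '", colnames(df)[ncol(df)], "'")
    ci <- ncol(df)
  }
  ph <- df[[ci]]
  g <- as.matrix(df[, -ci, drop = FALSE])
  GenotypeTable(g, ph)
}

#' Write a genotype table in GAMETES dialect
#'
#' Emits a header of SNP names plus a final `Class` column, one sample
#' per row, preserving sample order.
#'
#' @param table a [GenotypeTable-class].
#' @param path output file path.
#' @param delimiter field separator (default tab, as emitted by GAMETES).
#' @return Invisibly, `path`.
#' @export
writeGenotypes <- function(table, path, delimiter = "\t") {
  stopifnot(is(table, "GenotypeTable"))
  validObject(table)
  df <- as.data.frame(genoMatrix(table), check.names = FALSE)
  df[["Class"]] <- phenotype(table)
  ok <- tryCatch({
    write.table(df, path, sep = delimiter, quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write genotype table to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}
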