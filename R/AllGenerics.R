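#' Per-sample library sizes
#'
#' Column sums of the raw count assay.
#'
#' @param x a \linkS4class{MirCounts} object.
#' @return named numeric vector of per-sample total read counts.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @describeIn librarySizes column sums of the `counts` assay.
#' @export
setMethod("librarySizes", "MirCounts", function(x) {
  colSums(SummarizedExperiment::assay(x, "counts"))
})

#' Signature table accessor
#'
#' @param x a \linkS4class{HaemolysisSignature}.
#' @return the underlying data frame (one row per signature miRNA).
#' @export
setGeneric("signatureTable", function(x) standardGeneric("signatureTable"))

#' @describeIn signatureTable underlying data frame.
#' @export
setMethod("signatureTable", "HaemolysisSignature", function(x) x@table)

#' @rdname signatureTable
#' @export
signatureMirnas <- function(x) signatureTable(x)$mirna

#' @rdname signatureTable
#' @param x a \linkS4class{HaemolysisSignature}.
#' @return `conditionAssociated`: names of the signature miRNAs flagged as
#'   associated with the study condition (to be excluded via
#'   [partitionSignature()] in that context).
#' @export
conditionAssociated <- function(x) {
  tab <- signatureTable(x)
  tab$mirna[tab$condition_associated]
}

#' Partition accessors
#'
#' @param x a \linkS4class{SignaturePartition}.
#' @return character vector of miRNA names.
#' @export
setGeneric("signatureIds", function(x) standardGeneric("signatureIds"))

#' @describeIn signatureIds signature-set miRNAs (size p1).
#' @export
setMethod("signatureIds", "SignaturePartition", function(x) x@signatureIds)

#' @rdname signatureIds
#' @export
setGeneric("backgroundIds", function(x) standardGeneric("backgroundIds"))

#' @describeIn signatureIds background-set miRNAs (size p2).
#' @export
setMethod("backgroundIds", "SignaturePartition", function(x) x@backgroundIds)

#' @rdname signatureIds
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

#' @describeIn signatureIds miRNAs excluded from both sets.
#' @export
setMethod("excludedIds", "SignaturePartition", function(x) x@excludedIds)

#' Report table accessor
#'
#' @param x a \linkS4class{HaemolysisReport}.
#' @return data frame with one row per sample.
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @describeIn reportTable underlying per-sample data frame.
#' @export
setMethod("reportTable", "HaemolysisReport", function(x) x@table)

#' DE result accessors
#'
#' @param x a \linkS4class{DEResult}.
#' @return `deTable`: per-miRNA data frame; `priorDf`/`priorVar`: the
#'   empirical-Bayes hyper-parameters (`NA` before [ebayesModerate()]).
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @describeIn deTable per-miRNA statistics.
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @rdname deTable
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))

#' @describeIn deTable prior degrees of freedom.
#' @export
setMethod("priorDf", "DEResult", function(x) x@priorDf)

#' @rdname deTable
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))

#' @describeIn deTable prior variance.
#' @export
setMethod("priorVar", "DEResult", function(x) x@priorVar)

setMethod("show", "MirCounts", function(object) {
  cts <- SummarizedExperiment::assay(object, "counts")
  cat(sprintf("MirCounts: %d miRNAs x %d samples\n", nrow(cts), ncol(cts)))
  ls <- librarySizes(object)
  cat(sprintf("library sizes: %s - %s reads (median %s)\n",
              format(min(ls), big.mark = ","), format(max(ls), big.mark = ","),
              format(round(stats::median(ls)), big.mark = ",")))
})

setMethod("show", "MirNormalized", function(object) {
  cat(sprintf("MirNormalized: %d miRNAs x %d samples (TMM log2 CPM)\n",
              nrow(object), ncol(object)))
})

setMethod("show", "HaemolysisSignature", function(object) {
  tab <- object@table
  cat(sprintf("HaemolysisSignature: %d miRNAs (%d condition-associated)\n",
              nrow(tab), sum(tab$condition_associated)))
})

setMethod("show", "SignaturePartition", function(object) {
  cat(sprintf("SignaturePartition: p1 = %d signature, p2 = %d background, %d excluded\n",
              length(object@signatureIds), length(object@backgroundIds),
              length(object@excludedIds)))
})

setMethod("show", "HaemolysisReport", function(object) {
  tab <- object@table
  cat(sprintf("HaemolysisReport: %d samples (threshold %.2f)\n",
              nrow(tab), object@threshold))
  cat(sprintf("  Caution: %d  Clear: %d  undefined: %d\n",
              sum(tab$classification == "Caution", na.rm = TRUE),
              sum(tab$classification == "Clear", na.rm = TRUE),
              sum(is.na(tab$classification))))
})

setMethod("show", "DEResult", function(object) {
  cat(sprintf("DEResult: %d miRNAs, residual df %.1f%s\n",
              nrow(object@table), object@dfResidual,
              if (is.na(object@priorDf)) " (unmoderated)"
              else sprintf(", prior df %.2f", object@priorDf)))
})
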