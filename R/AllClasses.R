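#' @import methods
#' @importFrom stats p.adjust pt pnorm quantile rnorm rnbinom rpois rlnorm
#'   runif median model.matrix cor var setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

.is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

#' MirCounts: raw miRNA-by-sample count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' `counts`: non-negative integer read counts with miRNA identifiers
#' (canonicalized, see [canonicalizeMirna()]) as row names and sample
#' identifiers as column names.
#'
#' @seealso [MirCounts()], [readCountMatrix()]
#' @exportClass MirCounts
setClass("MirCounts", contains = "SummarizedExperiment")

setValidity("MirCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(cts)) || is.null(colnames(cts)))
      msg <- c(msg, "counts must carry miRNA row names and sample column names")
    else {
      if (anyDuplicated(rownames(cts)))
        msg <- c(msg, "miRNA identifiers must be unique")
      if (anyDuplicated(colnames(cts)))
        msg <- c(msg, "sample identifiers must be unique")
    }
    if (!.is_whole(cts))
      msg <- c(msg, "counts must be finite whole numbers")
    else if (any(cts < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' MirNormalized: TMM-adjusted log2 CPM matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays `log2cpm`
#' (log2 counts-per-million on TMM-adjusted effective library sizes) and
#' `detected` (logical; `TRUE` where the source count was positive).
#' Per-sample `lib_size`, `tmm_factor` and `eff_lib_size` live in
#' `colData`.
#'
#' @seealso [log2Cpm()]
#' @exportClass MirNormalized
setClass("MirNormalized", contains = "SummarizedExperiment")

setValidity("MirNormalized", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("log2cpm", "detected") %in% an))
    msg <- c(msg, "assays 'log2cpm' and 'detected' are required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("lib_size", "tmm_factor", "eff_lib_size")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, sprintf("colData must contain %s", paste(need, collapse = ", ")))
  else {
    f <- cd$tmm_factor
    if (any(f <= 0)) msg <- c(msg, "tmm_factor must be positive")
    else if (abs(mean(log(f))) > 1e-6)
      msg <- c(msg, "tmm_factor must have geometric mean 1")
  }
  if (is.null(msg) && all(c("log2cpm", "detected") %in% an)) {
    z <- SummarizedExperiment::assay(object, "log2cpm")
    d <- SummarizedExperiment::assay(object, "detected")
    if (any(!is.finite(z[d])))
      msg <- c(msg, "log2cpm must be finite wherever detected")
  }
  if (is.null(msg)) TRUE else msg
})

#' HaemolysisSignature: signature miRNA table
#'
#' Wraps a data frame with one row per signature miRNA and columns
#' `mirna`, `log2fc` (haemolysed vs non-haemolysed), `avg_expr`
#' (log2 CPM), `adj_p` (BH-adjusted p) and `condition_associated`
#' (logical flag marking miRNAs also differentially abundant between
#' study conditions, e.g. pregnancy, which should be excluded from
#' metric calculations in that context).
#'
#' @seealso [bundledSignature()], [readSignatureTable()]
#' @exportClass HaemolysisSignature
setClass("HaemolysisSignature", representation(table = "data.frame"))

setValidity("HaemolysisSignature", function(object) {
  tab <- object@table
  msg <- NULL
  need <- c("mirna", "log2fc", "avg_expr", "adj_p", "condition_associated")
  if (!all(need %in% colnames(tab)))
    return(sprintf("signature table needs columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$mirna)) msg <- c(msg, "signature miRNA names must be unique")
  if (nrow(tab) && (any(tab$adj_p < 0, na.rm = TRUE) || any(tab$adj_p > 1, na.rm = TRUE)))
    msg <- c(msg, "adj_p must lie in [0, 1]")
  if (!is.logical(tab$condition_associated))
    msg <- c(msg, "condition_associated must be logical")
  if (is.null(msg)) TRUE else msg
})

#' SignaturePartition: signature / background split of a matrix
#'
#' Records which miRNAs of a normalized matrix act as the (possibly
#' reduced) haemolysis signature set, which form the background set, and
#' which were excluded from both.
#'
#' @slot signatureIds character, signature miRNAs present in the matrix.
#' @slot backgroundIds character, background miRNAs.
#' @slot excludedIds character, miRNAs removed from both sets.
#' @seealso [partitionSignature()]
#' @exportClass SignaturePartition
setClass("SignaturePartition", representation(
  signatureIds = "character",
  backgroundIds = "character",
  excludedIds = "character"
))

setValidity("SignaturePartition", function(object) {
  msg <- NULL
  if (length(intersect(object@signatureIds, object@backgroundIds)))
    msg <- c(msg, "signature and background sets must be disjoint")
  if (length(intersect(object@excludedIds,
                       c(object@signatureIds, object@backgroundIds))))
    msg <- c(msg, "excluded miRNAs must not appear in either set")
  if (length(object@backgroundIds) < 1)
    msg <- c(msg, "background set must contain at least one miRNA")
  if (is.null(msg)) TRUE else msg
})

#' HaemolysisReport: per-sample haemolysis assessment
#'
#' One row per sample: `sample_id`, `haemolysis_metric` (difference of
#' geometric means of signature vs background log2 CPM),
#' `classification` (`"Caution"` when the metric reaches the threshold,
#' else `"Clear"`), `proxy_delta_cq` (log2 CPM miR-451a minus
#' miR-23a-3p, `NA` when a marker is undetected), effective set sizes
#' actually used per sample, raw `library_size` and `n_detected_mirnas`
#' (miRNAs with positive floored counts).
#'
#' @slot table data.frame as above.
#' @slot threshold numeric classification threshold.
#' @slot p1,p2 integer sizes of the (reduced) signature and background sets.
#' @seealso [assessHaemolysis()], [writeReport()]
#' @exportClass HaemolysisReport
setClass("HaemolysisReport", representation(
  table = "data.frame", threshold = "numeric",
  p1 = "integer", p2 = "integer"
))

setValidity("HaemolysisReport", function(object) {
  tab <- object@table
  need <- c("sample_id", "haemolysis_metric", "classification",
            "proxy_delta_cq", "n_signature_used", "n_background_used",
            "library_size", "n_detected_mirnas")
  if (!all(need %in% colnames(tab)))
    return(sprintf("report needs columns %s", paste(need, collapse = ", ")))
  msg <- NULL
  ok <- is.finite(tab$haemolysis_metric)
  if (any(ok)) {
    want <- ifelse(tab$haemolysis_metric[ok] >= object@threshold,
                   "Caution", "Clear")
    if (!identical(as.character(tab$classification[ok]), want))
      msg <- c(msg, "classification must equal Caution iff metric >= threshold")
  }
  if (any(tab$n_signature_used > object@p1, na.rm = TRUE) ||
      any(tab$n_background_used > object@p2, na.rm = TRUE))
    msg <- c(msg, "effective set sizes cannot exceed partition sizes")
  if (is.null(msg)) TRUE else msg
})

#' DEResult: per-miRNA differential-abundance fit
#'
#' Per-miRNA ordinary least squares of log2 CPM on a group indicator
#' (plus optional batch dummies), optionally with empirical-Bayes
#' moderated t-statistics. `table` holds `mirna`, `log2fc`, `avg_expr`,
#' `t_stat`, `p_value` and, once moderated, `moderated_t` and `adj_p`.
#'
#' @slot table data.frame as above.
#' @slot dfResidual numeric residual degrees of freedom (shared).
#' @slot sigma2 numeric per-miRNA residual variances.
#' @slot stdevUnscaled numeric unscaled standard deviation of the group
#'   coefficient (shared design leverage term).
#' @slot priorDf,priorVar numeric empirical-Bayes hyper-parameters
#'   (`NA` before moderation; `priorDf` may be `Inf`).
#' @seealso [fitGroupModel()], [ebayesModerate()]
#' @exportClass DEResult
setClass("DEResult", representation(
  table = "data.frame", dfResidual = "numeric", sigma2 = "numeric",
  stdevUnscaled = "numeric", priorDf = "numeric", priorVar = "numeric"
))

setValidity("DEResult", function(object) {
  need <- c("mirna", "log2fc", "avg_expr", "t_stat", "p_value")
  if (!all(need %in% colnames(object@table)))
    return(sprintf("DE table needs columns %s", paste(need, collapse = ", ")))
  if (length(object@dfResidual) != 1 || object@dfResidual <= 0)
    return("dfResidual must be a single positive number")
  TRUE
})
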