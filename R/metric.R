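#' Geometric mean
#'
#' `(prod(values))^(1/n)` computed in log space for numerical stability.
#' Callers must have removed non-positive values (undetected cells) first.
#'
#' @param values non-empty vector of positive finite numbers.
#' @return the geometric mean.
#' @examples
#' geometricMean(c(2, 8)) # 4
#' @export
geometricMean <- function(values) {
  if (length(values) == 0) stop("geometric mean of an empty vector is undefined")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("geometric mean requires positive finite values")
  exp(mean(log(values)))
}

#' Split a matrix into signature and background sets
#'
#' The signature set holds the signature miRNAs present in the matrix;
#' the background set holds every other miRNA. In a case-control study
#' any miRNA known to be differentially abundant between the study
#' groups should be passed as `exclude`: by default it is removed from
#' BOTH sets, so the metric cannot be confounded by the condition of
#' interest. `exclude_from = "signature"` restricts removal to the
#' signature set instead.
#'
#' @param norm a \linkS4class{MirNormalized}.
#' @param sig a \linkS4class{HaemolysisSignature}.
#' @param exclude character vector of miRNA names to exclude
#'   (canonicalized internally), e.g. `conditionAssociated(sig)`.
#' @param min_signature minimum usable signature size (default 5); fewer
#'   usable signature miRNAs is an error, as the geometric mean becomes
#'   too volatile for a meaningful score.
#' @param exclude_from `"both"` (default) or `"signature"`.
#' @return a \linkS4class{SignaturePartition}.
#' @export
partitionSignature <- function(norm, sig, exclude = character(),
                               min_signature = 5,
                               exclude_from = c("both", "signature")) {
  stopifnot(is(norm, "MirNormalized"), is(sig, "HaemolysisSignature"),
            min_signature >= 2)
  exclude_from <- match.arg(exclude_from)
  ids <- rownames(norm)
  if (length(ids) == 0) stop("normalized matrix has no miRNAs")
  exclude <- if (length(exclude)) unique(canonicalizeMirna(exclude)) else character()
  sig_names <- signatureMirnas(sig)
  absent <- setdiff(sig_names, ids)
  if (length(absent))
    warning(sprintf("%d signature miRNA(s) absent from the matrix: %s",
                    length(absent), paste(absent, collapse = ", ")))
  sig_ids <- setdiff(intersect(sig_names, ids), exclude)
  bg_excl <- if (exclude_from == "both") exclude else character()
  bg_ids <- setdiff(ids, c(sig_names, bg_excl))
  if (length(sig_ids) < min_signature)
    stop(sprintf(
      "signature coverage too low: %d usable signature miRNA(s), need >= %d",
      length(sig_ids), min_signature))
  new("SignaturePartition",
      signatureIds = sig_ids, backgroundIds = bg_ids,
      excludedIds = intersect(if (exclude_from == "both") exclude
                              else intersect(exclude, sig_names), ids))
}

# Per-sample geometric means over a miRNA set, using only cells that are
# detected and have positive log2 CPM (the geometric mean is undefined
# otherwise). Returns list(value =, n_used =).
.set_geomean <- function(z, det, set_ids, sample) {
  v <- z[set_ids, sample]
  usable <- det[set_ids, sample] & is.finite(v) & v > 0
  if (!any(usable)) return(list(value = NA_real_, n_used = 0L))
  list(value = geometricMean(v[usable]), n_used = sum(usable))
}

#' Per-sample haemolysis metric
#'
#' For sample i the metric is the geometric mean of the sample's log2
#' CPM values over the signature set minus the geometric mean over the
#' background set, using only detected cells with positive log2 CPM.
#' Large values indicate that RBC-associated miRNAs are collectively
#' elevated, the hallmark of haemolysis.
#'
#' @param norm a \linkS4class{MirNormalized}.
#' @param part a \linkS4class{SignaturePartition} for `norm`.
#' @param samples sample ids (default: all).
#' @return named numeric vector of metrics (`NA` where no signature
#'   miRNA is usable in a sample), with attribute `effective_sizes`, a
#'   data frame of per-sample `n_signature_used` / `n_background_used`.
#' @export
haemolysisMetric <- function(norm, part, samples = colnames(norm)) {
  stopifnot(is(norm, "MirNormalized"), is(part, "SignaturePartition"))
  bad <- setdiff(c(signatureIds(part), backgroundIds(part)), rownames(norm))
  if (length(bad))
    stop(sprintf("partition miRNA(s) not in matrix: %s", paste(bad, collapse = ", ")))
  missing <- setdiff(samples, colnames(norm))
  if (length(missing))
    stop(sprintf("unknown sample(s): %s", paste(missing, collapse = ", ")))
  z <- SummarizedExperiment::assay(norm, "log2cpm")
  det <- SummarizedExperiment::assay(norm, "detected")
  n_sig <- n_bg <- integer(length(samples))
  metric <- numeric(length(samples))
  for (k in seq_along(samples)) {
    gs <- .set_geomean(z, det, signatureIds(part), samples[k])
    gb <- .set_geomean(z, det, backgroundIds(part), samples[k])
    n_sig[k] <- gs$n_used; n_bg[k] <- gb$n_used
    metric[k] <- if (is.na(gs$value) || is.na(gb$value)) NA_real_
                 else gs$value - gb$value
  }
  structure(setNames(metric, samples),
            effective_sizes = data.frame(sample_id = samples,
                                         n_signature_used = n_sig,
                                         n_background_used = n_bg))
}

#' Classify a haemolysis metric
#'
#' `"Caution"` (haemolysis evidence; consider removing the sample or
#' interpreting with care) iff the metric reaches the threshold, else
#' `"Clear"`.
#'
#' @param metric numeric vector of haemolysis metrics.
#' @param threshold classification threshold (default 1.9).
#' @return character vector of `"Clear"` / `"Caution"` (`NA` in, `NA` out).
#' @examples
#' classifyMetric(c(1.89, 1.9)) # "Clear" "Caution"
#' @export
classifyMetric <- function(metric, threshold = 1.9) {
  stopifnot(is.numeric(metric), is.finite(threshold))
  ifelse(is.na(metric), NA_character_,
         ifelse(metric >= threshold, "Caution", "Clear"))
}

#' Sequencing proxy for the RT-qPCR delta-Cq haemolysis assay
#'
#' `log2 CPM(miR-451a) - log2 CPM(miR-23a-3p)` per sample, oriented so
#' that larger values indicate more haemolysis, matching the direction
#' of the RT-qPCR `Cq(miR-23a-3p) - Cq(miR-451a)` scale. `NA` where
#' either marker is absent from the matrix or undetected in the sample
#' (never silently zero).
#'
#' @param norm a \linkS4class{MirNormalized}.
#' @param samples sample ids (default: all).
#' @return named numeric vector.
#' @export
proxyDeltaCq <- function(norm, samples = colnames(norm)) {
  stopifnot(is(norm, "MirNormalized"))
  markers <- c("miR-451a", "miR-23a-3p")
  present <- markers %in% rownames(norm)
  if (!all(present)) {
    warning(sprintf("marker(s) absent from matrix: %s; proxy delta Cq unavailable",
                    paste(markers[!present], collapse = ", ")))
    return(setNames(rep(NA_real_, length(samples)), samples))
  }
  z <- SummarizedExperiment::assay(norm, "log2cpm")
  det <- SummarizedExperiment::assay(norm, "detected")
  ok <- det["miR-451a", samples] & det["miR-23a-3p", samples]
  out <- ifelse(ok, z["miR-451a", samples] - z["miR-23a-3p", samples], NA_real_)
  setNames(out, samples)
}

#' Assess haemolysis in a plasma miRNA count matrix
#'
#' The full per-sample pipeline: floor low counts, filter to abundant
#' miRNAs (mean CPM over all samples, assessment mode), TMM factors,
#' log2 CPM, signature/background partition, then per sample the
#' haemolysis metric, Clear/Caution classification and proxy delta Cq.
#' Per-sample failures (no usable signature miRNA) yield `NA` rows
#' rather than aborting the batch.
#'
#' @param x a \linkS4class{MirCounts}.
#' @param signature a \linkS4class{HaemolysisSignature}
#'   (default [bundledSignature()]).
#' @param exclude miRNAs to exclude from both sets (e.g.
#'   `conditionAssociated(signature)` for a pregnancy cohort, or any
#'   miRNA known to be associated with the study condition).
#' @param threshold Caution threshold on the metric (default 1.9).
#' @param min_count flooring threshold (default 5).
#' @param min_cpm abundance filter threshold (default 40).
#' @param prior prior count for log2 CPM (default 0.5).
#' @param min_signature minimum usable signature size (default 5).
#' @param exclude_from `"both"` (default) or `"signature"`; see
#'   [partitionSignature()].
#' @return a \linkS4class{HaemolysisReport}.
#' @examples
#' sim <- simulateCounts(simConfig(n_samples = 8, seed = 7))
#' rep <- assessHaemolysis(sim$counts)
#' head(reportTable(rep))
#' @export
assessHaemolysis <- function(x, signature = bundledSignature(),
                             exclude = character(), threshold = 1.9,
                             min_count = 5, min_cpm = 40, prior = 0.5,
                             min_signature = 5,
                             exclude_from = c("both", "signature")) {
  stopifnot(is(x, "MirCounts"))
  exclude_from <- match.arg(exclude_from)
  raw_ls <- librarySizes(x)
  floored <- floorLowCounts(x, min_count = min_count)
  n_det <- colSums(SummarizedExperiment::assay(floored, "counts") > 0)
  filt <- abundanceFilter(floored, min_cpm = min_cpm)
  norm <- log2Cpm(filt, factors = tmmFactors(filt), prior = prior)
  part <- partitionSignature(norm, signature, exclude = exclude,
                             min_signature = min_signature,
                             exclude_from = exclude_from)
  metric <- haemolysisMetric(norm, part)
  sizes <- attr(metric, "effective_sizes")
  tab <- data.frame(
    sample_id = colnames(norm),
    haemolysis_metric = as.numeric(metric),
    classification = classifyMetric(as.numeric(metric), threshold),
    proxy_delta_cq = as.numeric(suppressWarnings(proxyDeltaCq(norm))),
    n_signature_used = sizes$n_signature_used,
    n_background_used = sizes$n_background_used,
    library_size = as.numeric(raw_ls),
    n_detected_mirnas = as.integer(n_det),
    stringsAsFactors = FALSE, row.names = NULL)
  new("HaemolysisReport", table = tab, threshold = threshold,
      p1 = length(signatureIds(part)), p2 = length(backgroundIds(part)))
}
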