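#' Floor low counts to zero
#'
#' Mature miRNAs with fewer than `min_count` reads in a sample are
#' considered sequencing noise and reduced to zero, independently per
#' sample, before abundance filtering and normalization.
#'
#' @param x a \linkS4class{MirCounts}.
#' @param min_count integer; cells with count `< min_count` become 0
#'   (default 5).
#' @return a \linkS4class{MirCounts} with floored counts (library sizes,
#'   being column sums, reflect the flooring).
#' @export
floorLowCounts <- function(x, min_count = 5) {
  stopifnot(is(x, "MirCounts"), min_count >= 0)
  cts <- SummarizedExperiment::assay(x, "counts")
  cts[cts < min_count] <- 0
  MirCounts(cts)
}

.cpm_raw <- function(cts) {
  ls <- colSums(cts)
  if (any(ls == 0)) stop("sample(s) with zero library size")
  sweep(cts, 2, ls, "/") * 1e6
}

#' Filter miRNAs by abundance
#'
#' Retains a miRNA iff its mean CPM over `group_samples` (or over all
#' samples when `NULL`) is at least `min_cpm`; miRNAs below that are
#' unlikely to be present in most samples. "Fewer than 40 CPM" is the
#' removal rule, so exactly 40 is retained.
#'
#' @param x a \linkS4class{MirCounts} (typically already floored).
#' @param min_cpm minimum mean CPM to retain (default 40).
#' @param group_samples optional character vector of sample ids over
#'   which the mean CPM is evaluated (e.g. the haemolysed group during
#'   signature discovery).
#' @return the row-filtered \linkS4class{MirCounts}.
#' @export
abundanceFilter <- function(x, min_cpm = 40, group_samples = NULL) {
  stopifnot(is(x, "MirCounts"))
  cts <- SummarizedExperiment::assay(x, "counts")
  if (is.null(group_samples)) {
    group_samples <- colnames(cts)
  } else {
    if (length(group_samples) == 0)
      stop("'group_samples' must be a non-empty subset of sample ids")
    missing <- setdiff(group_samples, colnames(cts))
    if (length(missing))
      stop(sprintf("unknown sample(s) in 'group_samples': %s",
                   paste(missing, collapse = ", ")))
  }
  cpm <- .cpm_raw(cts)[, group_samples, drop = FALSE]
  keep <- rowMeans(cpm) >= min_cpm
  if (!any(keep))
    stop(sprintf(
      "no miRNA reaches %g mean CPM; consider lowering 'min_cpm'", min_cpm))
  MirCounts(cts[keep, , drop = FALSE])
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scale factors correcting for composition
#' differences between libraries: reference sample chosen by the 75th
#' percentile of relative counts closest to the mean; per-sample
#' M-values (log2 CPM ratio to the reference) doubly trimmed (30% on M,
#' 5% on A) over miRNAs nonzero in both; factor = 2^(precision-weighted
#' mean of retained M-values), weights from the asymptotic binomial
#' variance; factors rescaled to geometric mean 1. Computed with
#' `edgeR::calcNormFactors`, the method's reference implementation.
#'
#' @param x a \linkS4class{MirCounts} with at least 2 samples, each with
#'   a positive library size.
#' @return named numeric vector of positive factors (geometric mean 1).
#' @export
tmmFactors <- function(x) {
  stopifnot(is(x, "MirCounts"))
  cts <- SummarizedExperiment::assay(x, "counts")
  if (ncol(cts) < 2) stop("TMM requires at least 2 samples")
  if (any(colSums(cts) == 0)) stop("sample(s) with zero library size")
  f <- edgeR::calcNormFactors(cts, method = "TMM")
  if (any(!is.finite(f) | f <= 0)) {
    warning("sample(s) with no usable overlap with the reference; factor set to 1")
    f[!is.finite(f) | f <= 0] <- 1
    f <- f / exp(mean(log(f)))
  }
  setNames(f, colnames(cts))
}

#' TMM-adjusted log2 CPM
#'
#' Effective library size N' = library size x TMM factor; the
#' transformed value is `log2((count + prior) / (N' + 2 * prior) * 1e6)`.
#' The prior keeps zero counts finite and reduces to plain log2 CPM when
#' `prior = 0`.
#'
#' @param x a \linkS4class{MirCounts}.
#' @param factors per-sample positive factors aligned to samples
#'   (defaults to [tmmFactors()]).
#' @param prior prior count (default 0.5).
#' @return a \linkS4class{MirNormalized} with assays `log2cpm` and
#'   `detected` (count > 0).
#' @export
log2Cpm <- function(x, factors = tmmFactors(x), prior = 0.5) {
  stopifnot(is(x, "MirCounts"), prior >= 0)
  cts <- SummarizedExperiment::assay(x, "counts")
  if (length(factors) != ncol(cts))
    stop("'factors' must align with samples")
  if (!is.null(names(factors)) && !identical(names(factors), colnames(cts)))
    factors <- factors[colnames(cts)]
  if (any(!is.finite(factors) | factors <= 0))
    stop("'factors' must be positive")
  ls <- colSums(cts)
  if (any(ls == 0)) stop("sample(s) with zero library size")
  eff <- ls * factors
  z <- log2(sweep(cts + prior, 2, eff + 2 * prior, "/") * 1e6)
  new("MirNormalized", SummarizedExperiment::SummarizedExperiment(
    assays = list(log2cpm = z, detected = cts > 0),
    colData = S4Vectors::DataFrame(lib_size = ls, tmm_factor = factors,
                                   eff_lib_size = eff,
                                   row.names = colnames(cts))))
}
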