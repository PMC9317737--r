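#' Discovery pipeline configuration
#'
#' Defaults mirror the signature-discovery procedure: floor counts below
#' 5, keep miRNAs with mean CPM >= 40 in the haemolysed group, intersect
#' the top 60 miRNAs by abundance and by smallest adjusted p with the
#' strict log2FC > 0.9 criterion, flag condition association at
#' FDR < 0.05. `top_percent`, when set, replaces `top_k` by
#' `ceiling(n * top_percent / 100)` (the percentile reading of the
#' rank cut).
#'
#' @param min_count flooring threshold.
#' @param min_cpm abundance threshold over the haemolysed group.
#' @param top_k rank cut for the abundance and adjusted-p criteria.
#' @param top_percent optional percentage rank cut overriding `top_k`.
#' @param lfc_cut strict lower bound on log2 fold change.
#' @param fdr_cut FDR threshold for condition-association flagging.
#' @param include_batch include a batch covariate when labels carry one.
#' @param include_borderline include borderline samples in the
#'   haemolysed group (default: borderline samples are excluded from
#'   discovery).
#' @param prior prior count for log2 CPM.
#' @return a list of class `discovery_config`.
#' @export
discoveryConfig <- function(min_count = 5, min_cpm = 40, top_k = 60,
                            top_percent = NULL, lfc_cut = 0.9,
                            fdr_cut = 0.05, include_batch = TRUE,
                            include_borderline = FALSE, prior = 0.5) {
  stopifnot(top_k >= 1, lfc_cut >= 0, fdr_cut > 0, fdr_cut < 1,
            min_count >= 0, min_cpm >= 0, prior >= 0)
  if (!is.null(top_percent))
    stopifnot(top_percent > 0, top_percent <= 100)
  structure(list(min_count = min_count, min_cpm = min_cpm, top_k = top_k,
                 top_percent = top_percent, lfc_cut = lfc_cut,
                 fdr_cut = fdr_cut, include_batch = include_batch,
                 include_borderline = include_borderline, prior = prior),
            class = "discovery_config")
}

# design matrix for ~ group (+ batch); errors on rank deficiency naming
# the offending columns
.build_design <- function(group, batch = NULL) {
  df <- data.frame(group = factor(group, levels = c("non_haemolysed", "haemolysed")))
  form <- ~group
  if (!is.null(batch) && length(unique(batch)) > 1) {
    df$batch <- factor(batch)
    form <- ~ group + batch
  }
  X <- model.matrix(form, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; confounded column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  X
}

#' Per-miRNA group model fit (ordinary least squares)
#'
#' Regresses each miRNA's log2 CPM on a haemolysed/non-haemolysed group
#' indicator, plus batch dummies when available. The group coefficient
#' is the log2 fold change (haemolysed minus non-haemolysed); ordinary
#' t-statistics use the per-miRNA residual variance.
#'
#' @param norm a \linkS4class{MirNormalized}.
#' @param labels a label data frame as returned by [readSampleLabels()];
#'   only samples labelled `haemolysed` / `non_haemolysed` are used and
#'   both groups need at least 2 samples.
#' @param include_batch use the `batch` column when present.
#' @return an unmoderated \linkS4class{DEResult}.
#' @export
fitGroupModel <- function(norm, labels, include_batch = TRUE) {
  stopifnot(is(norm, "MirNormalized"))
  labels <- labels[labels$sample_id %in% colnames(norm), , drop = FALSE]
  use <- labels$haemolysis_label %in% c("haemolysed", "non_haemolysed")
  labels <- labels[use, , drop = FALSE]
  n_h <- sum(labels$haemolysis_label == "haemolysed")
  n_c <- sum(labels$haemolysis_label == "non_haemolysed")
  if (n_h < 2 || n_c < 2)
    stop(sprintf(
      "need >= 2 samples per haemolysis group, got %d haemolysed and %d non-haemolysed",
      n_h, n_c))
  batch <- if (include_batch && "batch" %in% colnames(labels)) labels$batch else NULL
  X <- .build_design(labels$haemolysis_label, batch)
  Y <- SummarizedExperiment::assay(norm, "log2cpm")[, labels$sample_id, drop = FALSE]
  n <- ncol(Y); p <- ncol(X)
  df <- n - p
  if (df < 1) stop("no residual degrees of freedom: more coefficients than samples")
  qrX <- qr(X)
  beta <- t(qr.coef(qrX, t(Y)))           # genes x coefficients
  fitted <- beta %*% t(X)
  res <- Y - fitted
  s2 <- rowSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  u <- sqrt(xtx_inv[2, 2])                # leverage of the group coefficient
  lfc <- beta[, 2]
  # exact-fit rows: clear round-off so constant rows give lfc = 0, t = 0
  scale2 <- rowMeans(Y^2) + 1
  zero_var <- s2 < scale2 * 1e-24
  s2[zero_var] <- 0
  zero_fc <- zero_var & abs(lfc) < sqrt(scale2) * 1e-12
  lfc[zero_fc] <- 0
  tt <- lfc / (sqrt(s2) * u)              # 0/0 handled below, x/0 -> +-Inf
  tt[zero_fc] <- 0
  pv <- 2 * pt(-abs(tt), df = df)
  tab <- data.frame(mirna = rownames(Y), log2fc = as.numeric(lfc),
                    avg_expr = rowMeans(Y), t_stat = as.numeric(tt),
                    p_value = as.numeric(pv),
                    moderated_t = NA_real_, adj_p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("DEResult", table = tab, dfResidual = df, sigma2 = as.numeric(s2),
      stdevUnscaled = u, priorDf = NA_real_, priorVar = NA_real_)
}

# Newton inversion of the trigamma function (decreasing and convex on
# (0, Inf), so convergence is monotone from the starting value).
.trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Moment-matching estimate of the scaled inverse chi-square prior on the
# residual variances: E[log s^2] and Var[log s^2] of a scaled F link to
# digamma/trigamma of the degrees of freedom.
.estimate_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Empirical-Bayes moderation of the group-model t-statistics
#'
#' Shrinks per-miRNA residual variances toward a common prior estimated
#' by moment matching on the log residual variances (digamma/trigamma
#' moment equations, trigamma inverted numerically). Posterior variance
#' `(d0*s0^2 + d*s^2) / (d0 + d)`; the moderated t uses the posterior
#' variance with `d + d0` degrees of freedom and p-values are
#' recomputed, then BH-adjusted. When all variances are identical the
#' prior degrees of freedom are infinite and every posterior variance
#' equals the common value.
#'
#' @param de an unmoderated \linkS4class{DEResult} with >= 2 miRNAs.
#' @param prior_df optional override of the prior degrees of freedom
#'   (`0` recovers the ordinary t exactly; `Inf` pools all variances).
#' @param prior_var optional override of the prior variance (required
#'   with a finite nonzero `prior_df` override).
#' @return a moderated \linkS4class{DEResult}.
#' @export
ebayesModerate <- function(de, prior_df = NULL, prior_var = NULL) {
  stopifnot(is(de, "DEResult"))
  s2 <- de@sigma2
  if (length(s2) < 2) stop("moderation needs >= 2 miRNAs")
  df <- de@dfResidual
  if (is.null(prior_df)) {
    est <- .estimate_prior(s2, df)
    d0 <- est$df_prior; s02 <- est$var_prior
  } else {
    d0 <- prior_df
    s02 <- if (!is.null(prior_var)) prior_var
           else if (d0 == 0) 0
           else if (is.infinite(d0)) .estimate_prior(s2, df)$var_prior
           else stop("'prior_var' required with a finite nonzero 'prior_df'")
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  df_total <- min(df + d0, length(s2) * df)
  tab <- de@table
  tt <- tab$log2fc / (sqrt(s2_post) * de@stdevUnscaled)
  tt[s2_post == 0 & tab$log2fc == 0] <- 0
  pv <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt))
        else 2 * pt(-abs(tt), df = df_total)
  tab$moderated_t <- as.numeric(tt)
  tab$p_value <- as.numeric(pv)
  tab$adj_p <- bhAdjust(tab$p_value)
  new("DEResult", table = tab, dfResidual = df, sigma2 = s2,
      stdevUnscaled = de@stdevUnscaled, priorDf = d0, priorVar = s02)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (capped at 1, order-preserving), via
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Rank-intersection signature selection
#'
#' Selects the miRNAs lying in (top-k by average expression) AND
#' (top-k by smallest adjusted p) AND (log2FC strictly above `lfc_cut`,
#' i.e. higher in haemolysed samples). Rank cuts are closed sets: ties
#' at the k-th position are all included, making selection
#' deterministic and monotone in k.
#'
#' @param de a moderated \linkS4class{DEResult} (needs `adj_p`).
#' @param config a [discoveryConfig()].
#' @return a \linkS4class{HaemolysisSignature} (possibly empty, with a
#'   warning), `condition_associated` initialized to `FALSE`.
#' @export
selectSignature <- function(de, config = discoveryConfig()) {
  stopifnot(is(de, "DEResult"))
  tab <- deTable(de)
  if (nrow(tab) == 0 || all(is.na(tab$adj_p)))
    stop("selectSignature needs a moderated, adjusted DEResult")
  k <- if (!is.null(config$top_percent))
    ceiling(nrow(tab) * config$top_percent / 100) else config$top_k
  k <- min(k, nrow(tab))
  expr_cut <- sort(tab$avg_expr, decreasing = TRUE)[k]
  p_cut <- sort(tab$adj_p)[k]
  keep <- tab$avg_expr >= expr_cut & tab$adj_p <= p_cut &
    tab$log2fc > config$lfc_cut
  if (!any(keep))
    warning("no miRNA satisfies all selection criteria; empty signature")
  out <- tab[keep, c("mirna", "log2fc", "avg_expr", "adj_p"), drop = FALSE]
  out <- out[order(out$adj_p, -out$avg_expr, out$mirna), , drop = FALSE]
  out$condition_associated <- logical(nrow(out))
  HaemolysisSignature(out)
}

#' Flag condition-associated signature miRNAs
#'
#' Marks signature entries that are differentially abundant with respect
#' to the study condition (e.g. pregnancy), from a DE fit computed on
#' non-haemolysed samples only. Entries are flagged, never deleted:
#' removal happens at partition time via the exclusion set.
#'
#' @param de_condition a moderated \linkS4class{DEResult} of condition
#'   groups on non-haemolysed samples.
#' @param sig a \linkS4class{HaemolysisSignature}.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return the signature with updated `condition_associated` flags.
#' @export
flagConditionAssociation <- function(de_condition, sig, fdr_cut = 0.05) {
  stopifnot(is(de_condition, "DEResult"), is(sig, "HaemolysisSignature"))
  tab <- signatureTable(sig)
  de <- deTable(de_condition)
  hit <- de$mirna[!is.na(de$adj_p) & de$adj_p < fdr_cut]
  absent <- setdiff(tab$mirna, de$mirna)
  if (length(absent))
    warning(sprintf("signature miRNA(s) missing from condition DE (flags left FALSE): %s",
                    paste(absent, collapse = ", ")))
  tab$condition_associated <- tab$mirna %in% hit
  HaemolysisSignature(tab)
}

#' Discover a haemolysis signature from a labelled count matrix
#'
#' Full pipeline: floor low counts, abundance-filter over the haemolysed
#' samples, TMM, log2 CPM, per-miRNA group model (+ batch), empirical
#' Bayes moderation, BH adjustment, rank-intersection selection; when
#' the labels carry a `condition` column the signature is additionally
#' flagged for condition association using the non-haemolysed samples.
#' Borderline-labelled samples are excluded from both groups unless
#' `config$include_borderline` is set.
#'
#' @param x a \linkS4class{MirCounts}.
#' @param labels label data frame (see [readSampleLabels()]) covering
#'   >= 2 haemolysed and >= 2 non-haemolysed samples.
#' @param config a [discoveryConfig()].
#' @return a \linkS4class{HaemolysisSignature}.
#' @export
discoverSignature <- function(x, labels, config = discoveryConfig()) {
  stopifnot(is(x, "MirCounts"), inherits(config, "discovery_config"))
  labels <- readSampleLabels(labels)
  labels <- labels[labels$sample_id %in% colnames(x), , drop = FALSE]
  if (config$include_borderline)
    labels$haemolysis_label[labels$haemolysis_label == "borderline"] <- "haemolysed"
  haem <- labels$sample_id[labels$haemolysis_label == "haemolysed"]
  clear <- labels$sample_id[labels$haemolysis_label == "non_haemolysed"]
  if (length(haem) < 2 || length(clear) < 2)
    stop(sprintf(
      "need >= 2 samples per haemolysis group, got %d haemolysed and %d non-haemolysed",
      length(haem), length(clear)))
  floored <- floorLowCounts(x, min_count = config$min_count)
  filt <- abundanceFilter(floored, min_cpm = config$min_cpm, group_samples = haem)
  norm <- log2Cpm(filt, factors = tmmFactors(filt), prior = config$prior)
  de <- fitGroupModel(norm, labels, include_batch = config$include_batch)
  de <- ebayesModerate(de)
  sig <- selectSignature(de, config)
  if ("condition" %in% colnames(labels) && nrow(signatureTable(sig)) > 0) {
    cl <- labels[labels$sample_id %in% clear, , drop = FALSE]
    cond_groups <- table(cl$condition)
    if (length(cond_groups) == 2 && all(cond_groups >= 2)) {
      de_cond <- .fit_condition_model(norm, cl, include_batch = config$include_batch)
      de_cond <- ebayesModerate(de_cond)
      sig <- flagConditionAssociation(de_cond, sig, fdr_cut = config$fdr_cut)
    } else {
      warning("condition labels present but groups unusable; flags left FALSE")
    }
  }
  sig
}

# condition DE on non-haemolysed samples: same machinery with the
# condition factor standing in for the group indicator
.fit_condition_model <- function(norm, labels, include_batch = TRUE) {
  lv <- sort(unique(as.character(labels$condition)))
  fake <- ifelse(labels$condition == lv[2], "haemolysed", "non_haemolysed")
  lab2 <- data.frame(sample_id = labels$sample_id, haemolysis_label = fake,
                     stringsAsFactors = FALSE)
  if ("batch" %in% colnames(labels)) lab2$batch <- labels$batch
  fitGroupModel(norm, lab2, include_batch = include_batch)
}
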