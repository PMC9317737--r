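make_labels <- function(samples, groups, batch = NULL, condition = NULL) {
  out <- data.frame(sample_id = samples, haemolysis_label = groups,
                    stringsAsFactors = FALSE)
  if (!is.null(batch)) out$batch <- batch
  if (!is.null(condition)) out$condition <- condition
  out
}

test_that("group model recovers mean differences and matches the normal-equations oracle", {
  set.seed(101)
  n <- 8
  samples <- sprintf("S%02d", 1:n)
  groups <- rep(c("haemolysed", "non_haemolysed"), each = 4)
  batch <- rep(c("b1", "b2"), times = 4)
  Y <- matrix(rnorm(10 * n, mean = 8), 10, n,
              dimnames = list(sprintf("miR-%02d", 1:10), samples))
  Y[1, ] <- 8                                  # identical group means
  Y[2, ] <- ifelse(groups == "haemolysed", 9, 8)  # clean +1 shift
  de <- fitGroupModel(norm_from_matrix(Y), make_labels(samples, groups, batch))
  tab <- deTable(de)
  expect_equal(tab$log2fc[1], 0)
  expect_equal(tab$t_stat[1], 0)
  expect_equal(tab$log2fc[2], 1, tolerance = 1e-12)
  # independent oracle: explicit normal equations per miRNA
  X <- cbind(1, groups == "haemolysed", batch == "b2")
  xtx_inv <- solve(t(X) %*% X)
  for (g in 3:10) {   # rows 1-2 are exact fits (zero residual variance)
    beta <- xtx_inv %*% t(X) %*% Y[g, ]
    expect_equal(tab$log2fc[g], beta[2], tolerance = 1e-9)
    rss <- sum((Y[g, ] - X %*% beta)^2)
    s2 <- rss / (n - 3)
    t_or <- beta[2] / sqrt(s2 * xtx_inv[2, 2])
    if (s2 > 0) expect_equal(tab$t_stat[g], t_or, tolerance = 1e-9)
  }
  expect_equal(de@dfResidual, n - 3)
})

test_that("group model rejects tiny groups and confounded designs", {
  samples <- sprintf("S%02d", 1:6)
  Y <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("m", 1:5), samples))
  expect_error(
    fitGroupModel(norm_from_matrix(Y),
                  make_labels(samples, c("haemolysed", rep("non_haemolysed", 5)))),
    ">= 2 samples per haemolysis group")
  # batch perfectly confounded with group
  expect_error(
    fitGroupModel(norm_from_matrix(Y),
                  make_labels(samples, rep(c("haemolysed", "non_haemolysed"), each = 3),
                              batch = rep(c("b1", "b2"), each = 3))),
    "rank deficient")
})

test_that("empirical Bayes moderation matches degenerate and limiting cases", {
  set.seed(7)
  samples <- sprintf("S%02d", 1:10)
  groups <- rep(c("haemolysed", "non_haemolysed"), each = 5)
  Y <- matrix(rnorm(50 * 10, sd = rep(sqrt(c(0.5, 1, 2)), length.out = 50)),
              50, 10, dimnames = list(paste0("m", 1:50), samples))
  de <- fitGroupModel(norm_from_matrix(Y), make_labels(samples, groups))
  # prior_df = 0 recovers the ordinary t exactly
  de0 <- ebayesModerate(de, prior_df = 0)
  expect_equal(deTable(de0)$moderated_t, deTable(de)$t_stat, tolerance = 1e-12)
  # prior_df = Inf pools every variance to the prior
  deInf <- ebayesModerate(de, prior_df = Inf)
  tInf <- deTable(deInf)$moderated_t
  expect_equal(tInf * sqrt(priorVar(deInf)),
               deTable(de)$log2fc / de@stdevUnscaled, tolerance = 1e-9)
  # identical residual variances: infinite prior df, posterior = common value
  Yc <- matrix(rep(rnorm(10), each = 50), 50, 10, byrow = FALSE,
               dimnames = dimnames(Y))
  Yc <- Yc + outer(seq_len(50), rep(0, 10))  # distinct rows, same residuals
  dec <- fitGroupModel(norm_from_matrix(Yc), make_labels(samples, groups))
  mec <- ebayesModerate(dec)
  expect_equal(priorDf(mec), Inf)
})

test_that("moderated statistics agree with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(13)
  samples <- sprintf("S%02d", 1:12)
  groups <- rep(c("haemolysed", "non_haemolysed"), each = 6)
  Y <- matrix(rnorm(300 * 12, mean = 8, sd = sqrt(rchisq(300, 4) / 4 + 0.2)),
              300, 12, dimnames = list(paste0("m", 1:300), samples))
  de <- ebayesModerate(fitGroupModel(norm_from_matrix(Y), make_labels(samples, groups)))
  design <- stats::model.matrix(~ factor(groups, levels = c("non_haemolysed", "haemolysed")))
  fit <- limma::eBayes(limma::lmFit(Y, design))
  expect_equal(priorDf(de), fit$df.prior, tolerance = 1e-6)
  expect_equal(priorVar(de), fit$s2.prior, tolerance = 1e-6)
  expect_equal(deTable(de)$moderated_t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(deTable(de)$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated t holds its nominal type-I error on null data", {
  set.seed(2024)
  samples <- sprintf("S%02d", 1:12)
  groups <- rep(c("haemolysed", "non_haemolysed"), each = 6)
  Y <- matrix(rnorm(2000 * 12, mean = 8, sd = sqrt(rchisq(2000, 4) / 4 + 0.3)),
              2000, 12, dimnames = list(paste0("m", 1:2000), samples))
  de <- ebayesModerate(fitGroupModel(norm_from_matrix(Y), make_labels(samples, groups)))
  expect_equal(mean(deTable(de)$p_value < 0.05), 0.05, tolerance = 0.01 / 0.05)
})

test_that("BH adjustment matches hand-computed step-up values and is order-invariant", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand step-up: sorted p * n / rank, cumulative minimum from the top
  expect_equal(bhAdjust(c(0.005, 0.011, 0.02, 0.8)),
               c(0.02, 0.022, 0.8 / 30, 0.8))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("signature selection is the exact three-way rank intersection", {
  set.seed(77)
  n <- 100
  tab <- data.frame(
    mirna = sprintf("sim-miR-%03d", 1:n),
    log2fc = round(runif(n, -1, 2), 3),
    avg_expr = round(runif(n, 4, 14), 3),
    t_stat = 0, p_value = runif(n), moderated_t = 0,
    adj_p = round(runif(n), 4), stringsAsFactors = FALSE)
  tab$log2fc[5] <- 0.9  # exactly at the strict cut -> excluded
  de <- new("DEResult", table = tab, dfResidual = 10,
            sigma2 = rep(1, n), stdevUnscaled = 0.5,
            priorDf = 5, priorVar = 1)
  cfg <- discoveryConfig(top_k = 30, lfc_cut = 0.9)
  got <- sort(signatureMirnas(selectSignature(de, cfg)))
  # exhaustive independent check of the selection rule
  expr_cut <- sort(tab$avg_expr, decreasing = TRUE)[30]
  p_cut <- sort(tab$adj_p)[30]
  want <- sort(tab$mirna[tab$avg_expr >= expr_cut & tab$adj_p <= p_cut &
                           tab$log2fc > 0.9])
  expect_identical(got, want)
  expect_false(tab$mirna[5] %in% got)
  # monotone in top_k: selection at k1 <= k2 is nested
  prev <- character(0)
  for (k in c(10, 25, 50, 80, 100)) {
    cur <- signatureMirnas(selectSignature(de, discoveryConfig(top_k = k)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # percent mode replaces the absolute rank cut
  got60pct <- signatureMirnas(selectSignature(de, discoveryConfig(top_percent = 60)))
  expect_identical(sort(got60pct),
                   sort(signatureMirnas(selectSignature(de, discoveryConfig(top_k = 60)))))
  empty <- tab; empty$log2fc <- -1
  de_empty <- new("DEResult", table = empty, dfResidual = 10,
                  sigma2 = rep(1, n), stdevUnscaled = 0.5,
                  priorDf = 5, priorVar = 1)
  expect_warning(sig0 <- selectSignature(de_empty, cfg), "empty")
  expect_equal(nrow(signatureTable(sig0)), 0)
})

test_that("condition-association flagging marks significant entries without deleting", {
  sig <- bundledSignature()
  tab <- signatureTable(sig)
  tab$condition_associated <- FALSE
  sig0 <- HaemolysisSignature(tab)
  de_tab <- data.frame(
    mirna = c("miR-451a", "miR-25-3p", "miR-140-3p"),
    log2fc = c(2, 1, 0.1), avg_expr = 10, t_stat = 1,
    p_value = c(1e-5, 1e-4, 0.9), moderated_t = 1,
    adj_p = c(3e-5, 2e-4, 0.9), stringsAsFactors = FALSE)
  de <- new("DEResult", table = de_tab, dfResidual = 10, sigma2 = rep(1, 3),
            stdevUnscaled = 0.5, priorDf = 5, priorVar = 1)
  expect_warning(flagged <- flagConditionAssociation(de, sig0), "missing")
  ftab <- signatureTable(flagged)
  expect_equal(nrow(ftab), 20)   # nothing deleted
  expect_setequal(ftab$mirna[ftab$condition_associated],
                  c("miR-451a", "miR-25-3p"))
})

test_that("discovery recovers a planted enriched set and respects labels", {
  sc <- default_recovery_scenario(seed = 1)
  sig <- discoverSignature(sc$sim$counts, sc$labels)
  tab <- signatureTable(sig)
  expect_gte(sum(sc$planted %in% tab$mirna) / 20, 0.9)
  expect_equal(sum(!tab$mirna %in% sc$planted), 0)   # no false positives
  # shuffled labels: (near-)empty signature
  set.seed(99)
  shuffled <- sc$labels
  shuffled$haemolysis_label <- sample(shuffled$haemolysis_label)
  sig_null <- suppressWarnings(discoverSignature(sc$sim$counts, shuffled))
  expect_lte(nrow(signatureTable(sig_null)), 2)
  # borderline samples are excluded from the groups
  borderline <- sc$labels
  borderline$haemolysis_label[borderline$haemolysis_label == "haemolysed"] <- "borderline"
  expect_error(discoverSignature(sc$sim$counts, borderline),
               ">= 2 samples per haemolysis group")
})

test_that("discovery flags condition-associated miRNAs via the clear samples", {
  sc <- default_recovery_scenario(seed = 3)
  # plant a condition (pregnancy) effect on five signature miRNAs, split
  # evenly over both haemolysis groups so the haemolysis fold change is
  # untouched while the condition DE on clear samples sees a 3-fold shift
  m <- SummarizedExperiment::assay(sc$sim$counts, "counts")
  haem <- sc$labels$sample_id[sc$labels$haemolysis_label == "haemolysed"]
  clear <- sc$labels$sample_id[sc$labels$haemolysis_label == "non_haemolysed"]
  pregnant <- c(haem[1:6], clear[1:15])
  bump <- sc$planted[1:5]
  m[bump, pregnant] <- round(m[bump, pregnant] * 3)
  labels <- sc$labels
  labels$condition <- ifelse(labels$sample_id %in% pregnant,
                             "pregnant", "non_pregnant")
  sig <- discoverSignature(MirCounts(m), labels)
  tab <- signatureTable(sig)
  in_sig <- intersect(bump, tab$mirna)
  expect_gte(length(in_sig), 4)
  flagged <- tab$mirna[tab$condition_associated]
  expect_true(all(in_sig %in% flagged))   # condition-DE members are flagged
  expect_true(all(flagged %in% bump))     # and nothing else is
})
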