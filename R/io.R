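#' Canonicalize mature miRNA names
#'
#' Plasma miRNA count tables mix spellings such as `"hsa-miR-451a"`,
#' `"miR-451a"` and `"MIR-451A"`. Canonicalization trims whitespace,
#' strips a leading species prefix (`"hsa-"`) and normalizes case to the
#' miRBase `"miR-"` / `"let-"` convention. The operation is idempotent.
#'
#' @param name character vector of miRNA names.
#' @return character vector of canonical names.
#' @examples
#' canonicalizeMirna(c("hsa-miR-451a", "MIR-425-5P"))
#' @export
canonicalizeMirna <- function(name) {
  if (!is.character(name) || length(name) == 0)
    stop("'name' must be a non-empty character vector")
  out <- trimws(name)
  if (any(!nzchar(out)))
    stop("invalid miRNA name: empty string")
  out <- sub("^hsa-", "", out, ignore.case = TRUE)
  # case normalization only applies to miRBase-style names; other
  # identifiers pass through untouched
  mirbase <- grepl("^(mir|let)-", out, ignore.case = TRUE)
  out[mirbase] <- sub("^mir-", "miR-", tolower(out[mirbase]))
  out
}

#' Construct a MirCounts object
#'
#' Row names are canonicalized; rows that collapse to the same canonical
#' name are summed (prefix variants of one mature miRNA) with a warning.
#'
#' @param counts numeric matrix of non-negative whole-number read counts,
#'   miRNAs in rows (named) and samples in columns (named).
#' @return a \linkS4class{MirCounts}.
#' @export
MirCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have miRNA row names and sample column names")
  if (ncol(counts) < 1) stop("count matrix has no samples")
  if (!.is_whole(counts))
    stop("counts must be finite whole numbers (fractional counts are rejected)")
  if (any(counts < 0)) stop("counts must be non-negative")
  ids <- canonicalizeMirna(rownames(counts))
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warning(sprintf("summing %d duplicate miRNA row(s) after canonicalization: %s",
                    length(dups), paste(dups, collapse = ", ")))
    counts <- rowsum(counts, group = ids, reorder = FALSE)
  } else {
    rownames(counts) <- ids
  }
  storage.mode(counts) <- "double"
  new("MirCounts", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts)))
}

.read_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "")
}

#' Read a miRNA count matrix
#'
#' Expects a TSV (or CSV, by file extension) with miRNA identifiers in
#' the first column and one integer count column per sample. Duplicate
#' miRNA rows after canonicalization are summed with a warning;
#' negative or fractional cells are rejected.
#'
#' @param path path to the table.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return a \linkS4class{MirCounts}.
#' @export
readCountMatrix <- function(path, sep = NULL) {
  tab <- .read_table(path, sep)
  if (ncol(tab) < 2)
    stop(sprintf("malformed count table '%s': no sample columns", path))
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat))
    stop(sprintf("malformed count table '%s': non-numeric or missing cells", path))
  if (any(mat < 0))
    stop(sprintf("malformed count table '%s': negative counts", path))
  if (all(mat == 0))
    stop(sprintf("count table '%s' is all zero", path))
  rownames(mat) <- ids
  MirCounts(mat)
}

#' Write a miRNA count matrix
#'
#' @param x a \linkS4class{MirCounts}.
#' @param path destination; TSV with a `mirna` identifier column.
#' @return invisibly, `path`.
#' @export
writeCountMatrix <- function(x, path) {
  stopifnot(is(x, "MirCounts"))
  cts <- SummarizedExperiment::assay(x, "counts")
  out <- data.frame(mirna = rownames(cts), cts, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a HaemolysisSignature
#'
#' @param table data frame with columns `mirna`, `log2fc`, `avg_expr`,
#'   `adj_p`, `condition_associated`.
#' @return a \linkS4class{HaemolysisSignature}.
#' @export
HaemolysisSignature <- function(table) {
  if (nrow(table) > 0)
    table$mirna <- canonicalizeMirna(as.character(table$mirna))
  else table$mirna <- as.character(table$mirna)
  table$condition_associated <- as.logical(table$condition_associated)
  rownames(table) <- NULL
  new("HaemolysisSignature", table = table)
}

#' Read / write signature tables
#'
#' TSV with columns `mirna`, `log2fc`, `avg_expr`, `adj_p`,
#' `condition_associated` (`true`/`false`).
#'
#' @param path file path.
#' @return [readSignatureTable()]: a \linkS4class{HaemolysisSignature}.
#' @export
readSignatureTable <- function(path) {
  tab <- .read_table(path)
  need <- c("mirna", "log2fc", "avg_expr", "adj_p", "condition_associated")
  if (!all(need %in% colnames(tab)))
    stop(sprintf("signature table '%s' must have columns %s",
                 path, paste(need, collapse = ", ")))
  ca <- tab$condition_associated
  if (is.character(ca)) ca <- tolower(trimws(ca)) %in% c("true", "t", "yes", "1")
  tab$condition_associated <- as.logical(ca)
  HaemolysisSignature(tab[, need])
}

#' @rdname readSignatureTable
#' @param x a \linkS4class{HaemolysisSignature}.
#' @return [writeSignatureTable()]: invisibly, `path`.
#' @export
writeSignatureTable <- function(x, path) {
  stopifnot(is(x, "HaemolysisSignature"))
  tab <- signatureTable(x)
  tab$condition_associated <- ifelse(tab$condition_associated, "true", "false")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled 20-miRNA plasma haemolysis signature
#'
#' The general-use plasma haemolysis signature: 20 mature miRNAs with
#' significantly higher abundance in haemolysed plasma, of which 10 are
#' flagged as pregnancy-associated (`condition_associated = TRUE`) and
#' should be excluded from both signature and background when scoring
#' pregnancy cohorts. Fields carry the discovery statistics (log2 fold
#' change haemolysed vs non-haemolysed, average log2 CPM, BH-adjusted p).
#'
#' @return a \linkS4class{HaemolysisSignature} with 20 entries.
#' @examples
#' sig <- bundledSignature()
#' nrow(signatureTable(sig))
#' conditionAssociated(sig)
#' @export
bundledSignature <- function() {
  path <- system.file("extdata", "haemolysis_signature.tsv",
                      package = "hemoSig", mustWork = TRUE)
  readSignatureTable(path)
}

#' Read a sample label table
#'
#' TSV with a `sample_id` column and any of: `haemolysis_label`
#' (`haemolysed`, `non_haemolysed`, `borderline`, `unknown`),
#' `delta_cq` (RT-qPCR delta Cq), `condition`, `batch`. When
#' `haemolysis_label` is absent but `delta_cq` is present, labels are
#' derived with the RT-qPCR rule: < 7 clear (`non_haemolysed`),
#' exactly 7 `borderline`, > 7 `haemolysed`. `delta_cq_orientation`
#' states which subtraction the column holds; `"451a-minus-23a"` values
#' are negated to the canonical `Cq(miR-23a-3p) - Cq(miR-451a)` scale
#' before thresholding.
#'
#' @param x path to a TSV, or a data frame.
#' @param delta_cq_orientation `"23a-minus-451a"` (canonical) or
#'   `"451a-minus-23a"`.
#' @return data frame with columns `sample_id`, `haemolysis_label` and,
#'   when available, `delta_cq` (canonical orientation), `condition`,
#'   `batch`.
#' @export
readSampleLabels <- function(x, delta_cq_orientation = c("23a-minus-451a",
                                                         "451a-minus-23a")) {
  delta_cq_orientation <- match.arg(delta_cq_orientation)
  tab <- if (is.character(x)) .read_table(x) else as.data.frame(x)
  if (!"sample_id" %in% colnames(tab))
    stop("label table must have a 'sample_id' column")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in label table")
  if ("delta_cq" %in% colnames(tab)) {
    tab$delta_cq <- as.numeric(tab$delta_cq)
    if (delta_cq_orientation == "451a-minus-23a") tab$delta_cq <- -tab$delta_cq
  }
  if (!"haemolysis_label" %in% colnames(tab)) {
    if (!"delta_cq" %in% colnames(tab))
      stop("label table needs 'haemolysis_label' or 'delta_cq'")
    dc <- tab$delta_cq
    tab$haemolysis_label <- ifelse(is.na(dc), "unknown",
                            ifelse(dc < 7, "non_haemolysed",
                            ifelse(dc > 7, "haemolysed", "borderline")))
  }
  vocab <- c("haemolysed", "non_haemolysed", "borderline", "unknown")
  tab$haemolysis_label <- as.character(tab$haemolysis_label)
  bad <- setdiff(unique(tab$haemolysis_label), vocab)
  if (length(bad))
    stop(sprintf("haemolysis_label outside {%s}: %s",
                 paste(vocab, collapse = ", "), paste(bad, collapse = ", ")))
  tab
}

#' Write / read a haemolysis report
#'
#' TSV with one row per sample; round-trips losslessly (to numeric
#' precision) through [readReport()].
#'
#' @param report a \linkS4class{HaemolysisReport}.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "HaemolysisReport"))
  tab <- reportTable(report)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeReport
#' @param threshold classification threshold recorded in the restored
#'   object (default 1.9).
#' @return [readReport()]: a \linkS4class{HaemolysisReport}.
#' @export
readReport <- function(path, threshold = 1.9) {
  tab <- .read_table(path)
  tab$sample_id <- as.character(tab$sample_id)
  tab$classification <- as.character(tab$classification)
  new("HaemolysisReport", table = tab, threshold = threshold,
      p1 = as.integer(max(0, tab$n_signature_used, na.rm = TRUE)),
      p2 = as.integer(max(0, tab$n_background_used, na.rm = TRUE)))
}
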