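# Readers/writers for the tabular formats the pipeline touches, unit
# conversion, and small format validators. All TSVs are tab-delimited UTF-8
# with a header row; expression is genes x samples.

.EXPR_UNITS <- c("FPKM", "TPM", "LOG2_TPM")

#' Construct an expression matrix
#'
#' A lightweight container: a numeric genes x samples matrix with unique,
#' non-empty dimnames and a declared unit (`FPKM`, `TPM` or `LOG2_TPM`).
#' Values must be finite and non-negative (all three units are >= 0).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param unit one of `"FPKM"`, `"TPM"`, `"LOG2_TPM"`.
#' @return an `expr_matrix` object (classed matrix with a `unit` attribute).
#' @export
expr_matrix <- function(values, unit) {
  unit <- match.arg(unit, .EXPR_UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("expression values must be a numeric matrix")
  if (nrow(values) < 1 || ncol(values) < 1)
    .stopf("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate gene symbols: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .stopf("duplicate sample ids")
  if (any(!is.finite(values)))
    .stopf("expression matrix contains non-finite values")
  if (any(values < 0))
    .stopf("expression values must be non-negative")
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit of an expression matrix
#' @param x an `expr_matrix` (plain matrices return `NULL`).
#' @return the unit string or `NULL`.
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

# Accept either an expr_matrix or a plain genes x samples numeric matrix.
.as_expr_values <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) .stopf("expected a numeric genes x samples matrix")
  x
}

#' Read an expression TSV
#'
#' First column = gene symbol, remaining columns = samples. Duplicate gene
#' symbols are collapsed by keeping the row with the highest mean expression
#' (the usual TCGA convention). Any non-numeric / missing cell is a parse
#' error naming the offending gene and sample.
#'
#' @param path TSV path.
#' @param unit declared unit of the values.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, unit = c("TPM", "FPKM", "LOG2_TPM")) {
  unit <- match.arg(unit)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) .stopf("expression TSV needs a gene column plus >= 2 sample columns")
  genes <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    .stopf("non-numeric or missing value at gene '%s', sample '%s'",
           genes[bad[1]], colnames(vals)[bad[2]])
  }
  rownames(vals) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(ix) ix[which.max(means[ix])]))
    vals <- vals[sort(keep), , drop = FALSE]
  }
  expr_matrix(vals, unit)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: gene column named `gene`, one column per
#' sample. Values are written at full precision so finite decimals
#' round-trip exactly.
#'
#' @param x an `expr_matrix` or genes x samples matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression <- function(x, path) {
  m <- .as_expr_values(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample s: `TPM(g, s) = FPKM(g, s) / sum_g' FPKM(g', s) * 1e6`, so
#' every column sums to 1e6. Applying it to an already column-normalized
#' matrix is a no-op (idempotent up to floating point).
#'
#' @param m an `expr_matrix` with unit `FPKM` (or a plain non-negative matrix).
#' @return an `expr_matrix` with unit `TPM`.
#' @export
fpkm_to_tpm <- function(m) {
  vals <- .as_expr_values(m)
  if (!is.null(expr_unit(m)) && expr_unit(m) != "FPKM")
    .stopf("fpkm_to_tpm: input unit is %s, expected FPKM", expr_unit(m))
  cs <- colSums(vals)
  if (any(cs <= 0)) .stopf("fpkm_to_tpm: all-zero sample column(s): %s",
                           paste(colnames(vals)[cs <= 0], collapse = ", "))
  out <- sweep(vals, 2, cs, "/") * 1e6
  expr_matrix(out, "TPM")
}

#' Log2-transform a TPM matrix
#'
#' `log2(TPM + 1)`; the scale all rank-free analyses in this package run on.
#'
#' @param m an `expr_matrix` with unit `TPM`.
#' @return an `expr_matrix` with unit `LOG2_TPM`.
#' @export
log2_tpm <- function(m) {
  vals <- .as_expr_values(m)
  if (!is.null(expr_unit(m)) && expr_unit(m) == "LOG2_TPM") return(m)
  expr_matrix(log2(vals + 1), "LOG2_TPM")
}

#' Read a clinical table
#'
#' Mandatory columns: `sample_id`, `os_time` (days, > 0), `os_event`
#' (0 censored / 1 dead). Optional covariates (`age`, `gender`, `grade`,
#' `stage`) are kept as-is; missing values are allowed there and flagged in
#' the `n_missing` attribute.
#'
#' @param path TSV path.
#' @return a data.frame, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate a clinical data.frame
#' @param df data.frame with at least sample_id, os_time, os_event.
#' @return the validated data.frame (invisible attributes: `n_missing`).
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) .stopf("duplicate sample_id in clinical table")
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0))
    .stopf("os_time must be finite and > 0")
  if (!all(df$os_event %in% c(0, 1))) .stopf("os_event must be 0 or 1")
  covars <- intersect(c("age", "gender", "grade", "stage"), names(df))
  attr(df, "n_missing") <- vapply(df[covars], function(x) sum(is.na(x)), integer(1))
  df
}

#' The curated m6A regulator registry
#'
#' The 22 writer/reader/eraser genes whose expression defines the m6A
#' modification pattern: 7 writers (WTAP, METTL16, VIRMA, RBM15B, METTL3,
#' RBM15, ZC3H13), 13 readers (YTHDC1, YTHDF1, YTHDC2, YTHDF3, IGF2BP2,
#' LRPPRC, YTHDF2, HNRNPA2B1, HNRNPC, RBMX, EIF3A, G3BP1, FXR1) and
#' 2 erasers (ALKBH5, FTO).
#'
#' @return a data.frame with columns `symbol` and `role`.
#' @export
load_regulator_registry <- function() {
  reg <- data.frame(
    symbol = c("WTAP", "METTL16", "VIRMA", "RBM15B", "METTL3", "RBM15", "ZC3H13",
               "YTHDC1", "YTHDF1", "YTHDC2", "YTHDF3", "IGF2BP2", "LRPPRC",
               "YTHDF2", "HNRNPA2B1", "HNRNPC", "RBMX", "EIF3A", "G3BP1", "FXR1",
               "ALKBH5", "FTO"),
    role = c(rep("writer", 7), rep("reader", 13), rep("eraser", 2)),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(reg) == 22, !anyDuplicated(reg$symbol))
  reg
}

#' MAF variant classes counted as non-silent
#'
#' The conventional protein-altering classes used for mutation frequency and
#' tumor mutation burden; the complement (Silent, intronic, UTR, ...) is
#' ignored.
#'
#' @return character vector of Variant_Classification values.
#' @export
maf_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Read a MAF-style mutation table
#'
#' Requires the standard columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification` (and keeps `Variant_Type` when present); one row
#' per variant call.
#'
#' @param path tab-delimited MAF path (comment lines starting with `#` skipped).
#' @return a data.frame of variant records.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("MAF missing column(s): %s", paste(miss, collapse = ", "))
  df
}

#' Fraction of samples carrying a non-silent mutation in a gene list
#'
#' Counts samples with at least one non-silent variant in any of the listed
#' genes (a sample mutated in several listed genes counts once), over a
#' stated denominator `n_samples` (the assayed cohort, which may exceed the
#' samples present in the table).
#'
#' @param muts MAF-style data.frame (see [read_maf()]).
#' @param genes character vector of gene symbols.
#' @param n_samples denominator, >= 1.
#' @param non_silent variant classes counted; default [maf_nonsilent_classes()].
#' @return list with `count` and `fraction`.
#' @export
mutation_frequency <- function(muts, genes, n_samples,
                               non_silent = maf_nonsilent_classes()) {
  if (!length(genes)) .stopf("gene list is empty")
  if (length(n_samples) != 1 || n_samples < 1) .stopf("n_samples must be >= 1")
  hit <- muts$Hugo_Symbol %in% genes & muts$Variant_Classification %in% non_silent
  count <- length(unique(muts$Tumor_Sample_Barcode[hit]))
  list(count = count, fraction = count / n_samples)
}

#' Discretize copy-number values into loss/neutral/gain calls
#'
#' GISTIC-style soft thresholds on gene x sample segment means: gain at
#' `>= gain_threshold` (+0.3), loss at `<= loss_threshold` (-0.3). A
#' character matrix already in \{loss, neutral, gain\} passes through.
#'
#' @param x numeric gene x sample matrix of segment means, or a character
#'   call matrix.
#' @param gain_threshold,loss_threshold numeric thresholds (recorded in the
#'   `thresholds` attribute).
#' @return character gene x sample matrix of calls.
#' @export
cnv_calls <- function(x, gain_threshold = 0.3, loss_threshold = -0.3) {
  if (is.character(x)) {
    bad <- setdiff(unique(as.vector(x)), c("loss", "neutral", "gain"))
    if (length(bad)) .stopf("unknown CNV call value(s): %s", paste(bad, collapse = ", "))
    return(structure(x, thresholds = NULL))
  }
  stopifnot(is.matrix(x), is.numeric(x))
  calls <- matrix("neutral", nrow(x), ncol(x), dimnames = dimnames(x))
  calls[x >= gain_threshold] <- "gain"
  calls[x <= loss_threshold] <- "loss"
  structure(calls, thresholds = c(gain = gain_threshold, loss = loss_threshold))
}

#' Per-gene CNV gain/loss frequency
#'
#' @param cnv character gene x sample call matrix from [cnv_calls()].
#' @param genes genes to summarize; all must be present.
#' @return data.frame with `gene`, `gain_freq`, `loss_freq` (fractions of samples).
#' @export
cnv_frequency <- function(cnv, genes) {
  miss <- setdiff(genes, rownames(cnv))
  if (length(miss)) .stopf("CNV calls missing for gene(s): %s", paste(miss, collapse = ", "))
  sub <- cnv[genes, , drop = FALSE]
  data.frame(
    gene = genes,
    gain_freq = rowMeans(sub == "gain"),
    loss_freq = rowMeans(sub == "loss"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Members are deduplicated within a set; set names must be
#' unique; a line with fewer than 3 fields is an error naming the line.
#'
#' @param path GMT path.
#' @return named list of character vectors (class `gene_sets`), with the
#'   descriptions in the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) .stopf("GMT line %d has %d field(s); need >= 3", which(nf < 3)[1], nf[nf < 3][1])
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) .stopf("duplicate set name(s): %s",
                                paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0)) .stopf("empty gene set(s) in GMT")
  structure(sets, description = stats::setNames(vapply(parts, `[[`, character(1), 2), nm),
            class = "gene_sets")
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (defaults to the name).
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(length(names(sets)) == length(sets))
  desc <- description %||% attr(sets, "description") %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
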