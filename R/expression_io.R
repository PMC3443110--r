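#' Construct an expression matrix with detection calls
#'
#' Bundles a genes-by-samples matrix of linear-scale signal intensities with a
#' same-shaped matrix of detection calls (`"P"`resent, `"M"`arginal,
#' `"A"`bsent), the per-array summary produced by classic GeneChip software.
#' Signals must be finite and non-negative; gene and sample identifiers must
#' be unique.
#'
#' @param signals numeric matrix (genes x samples) of non-negative
#'   linear-scale intensities. Row names are gene identifiers, column names
#'   sample identifiers.
#' @param calls character matrix of the same shape with entries in
#'   `"P"`, `"M"`, `"A"`. Lower-case and full-word forms
#'   (`"present"` etc.) are normalized.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `gene_ids`, `sample_ids`, `signals`, `calls`.
#' @examples
#' s <- matrix(c(150, 10, 75, 20), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' k <- matrix(c("P", "A", "P", "M"), 2, 2, dimnames = dimnames(s))
#' expression_matrix(s, k)
#' @export
expression_matrix <- function(signals, calls) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("'signals' must be a numeric matrix")
  if (!is.matrix(calls) || !identical(dim(calls), dim(signals)))
    stop("'calls' must be a character matrix with the same shape as 'signals'")
  gene_ids <- rownames(signals)
  sample_ids <- colnames(signals)
  if (is.null(gene_ids) && nrow(signals) == 0L) gene_ids <- character(0)
  if (is.null(sample_ids) && ncol(signals) == 0L) sample_ids <- character(0)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'signals' must carry gene row names and sample column names")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyNA(signals) || any(!is.finite(signals)))
    stop("signals must be finite (no NA/NaN/Inf)")
  if (any(signals < 0))
    stop("signals must be non-negative")
  calls <- normalize_calls(calls)
  dimnames(calls) <- dimnames(signals)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 signals = signals, calls = calls),
            class = "ExpressionMatrix")
}

normalize_calls <- function(calls) {
  x <- toupper(trimws(as.character(calls)))
  x[x == "PRESENT"] <- "P"
  x[x == "MARGINAL"] <- "M"
  x[x == "ABSENT"] <- "A"
  bad <- which(!(x %in% c("P", "M", "A")))
  if (length(bad)) {
    i <- bad[1L]
    nr <- nrow(calls)
    stop(sprintf("invalid detection call '%s' at row %d, column %d",
                 as.character(calls)[i],
                 ((i - 1L) %% nr) + 1L, ((i - 1L) %/% nr) + 1L))
  }
  matrix(x, nrow(calls), ncol(calls))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat("samples:", paste(utils::head(x$sample_ids, 8L), collapse = ", "),
      if (length(x$sample_ids) > 8L) "..." else "", "\n")
  pct_p <- if (length(x$calls)) 100 * mean(x$calls == "P") else NA_real_
  cat(sprintf("detection: %.1f%% Present\n", pct_p))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signals)

#' Read an expression pivot table
#'
#' Reads a tab-delimited pivot export with one row per gene: a `gene_id`
#' column followed, for each sample, by `<sample>.Signal` and
#' `<sample>.Detection` columns. Every declared sample must have both
#' columns; signals must parse as non-negative numbers.
#'
#' @param path path to a tab-delimited pivot file.
#' @return An [expression_matrix()] with rows in file order.
#' @seealso [write_pivot()]
#' @export
read_pivot <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("pivot format error: no 'gene_id' column")
  sig_cols <- grep("\\.Signal$", names(df), value = TRUE)
  det_cols <- grep("\\.Detection$", names(df), value = TRUE)
  samples <- sub("\\.Signal$", "", sig_cols)
  det_samples <- sub("\\.Detection$", "", det_cols)
  missing_det <- setdiff(samples, det_samples)
  if (length(missing_det))
    stop("pivot format error: missing Detection column for sample '",
         missing_det[1L], "'")
  missing_sig <- setdiff(det_samples, samples)
  if (length(missing_sig))
    stop("pivot format error: missing Signal column for sample '",
         missing_sig[1L], "'")
  if (!length(samples)) stop("pivot format error: no sample columns declared")
  gene_ids <- df$gene_id
  n <- nrow(df)
  signals <- matrix(NA_real_, n, length(samples),
                    dimnames = list(gene_ids, samples))
  calls <- matrix(NA_character_, n, length(samples))
  for (j in seq_along(samples)) {
    raw <- df[[paste0(samples[j], ".Signal")]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric signal '%s' at row %d, sample '%s'",
                   raw[bad[1L]], bad[1L], samples[j]))
    if (any(v < 0))
      stop(sprintf("negative signal at row %d, sample '%s'",
                   which(v < 0)[1L], samples[j]))
    signals[, j] <- v
    calls[, j] <- df[[paste0(samples[j], ".Detection")]]
  }
  expression_matrix(signals, calls)
}

#' Write an expression pivot table
#'
#' Inverse of [read_pivot()]. By default signals are rendered at full
#' precision (17 significant digits) so that a write/read round trip
#' reproduces the matrix bit for bit.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @param digits significant digits for signal rendering; `NA` (default)
#'   means full round-trip precision.
#' @return `path`, invisibly.
#' @export
write_pivot <- function(x, path, digits = NA) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  fmt <- function(v) {
    if (is.na(digits)) sprintf("%.17g", v) else
      formatC(v, digits = digits, format = "g")
  }
  out <- data.frame(gene_id = x$gene_ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in x$sample_ids) {
    out[[paste0(s, ".Signal")]] <- vapply(x$signals[, s], fmt, character(1L))
    out[[paste0(s, ".Detection")]] <- x$calls[, s]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write pivot file: ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-delimited table with columns `sample_id`, `genotype` (`WT` or `KO`),
#' `age` (`PN11` or `PN56`) and `replicate` (positive integer). The
#' genotype/age vocabulary is enforced and sample ids must be unique.
#'
#' @param path path to the sample sheet.
#' @return data.frame with the four validated columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  req <- c("sample_id", "genotype", "age", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  bad_g <- setdiff(unique(df$genotype), c("WT", "KO"))
  if (length(bad_g)) stop("unknown genotype token: ", bad_g[1L])
  bad_a <- setdiff(unique(df$age), c("PN11", "PN56"))
  if (length(bad_a)) stop("unknown age token: ", bad_a[1L])
  rep_n <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_n) || any(rep_n < 1L))
    stop("replicate must be a positive integer")
  df$replicate <- rep_n
  df[req]
}

#' Read a gene annotation table
#'
#' Tab-delimited table with columns `gene_id`, `symbol`, `description`,
#' `go_bp_text` (the Gene Ontology Biological Process text scanned by
#' [keyword_tally()]; may be empty).
#'
#' @param path path to the annotation table.
#' @return data.frame with the four columns; `gene_id` unique.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  req <- c("gene_id", "symbol", "description", "go_bp_text")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in annotations: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  df[req]
}

#' Split a sample sheet into contrast groups
#'
#' Convenience used to form the sample-id groups of a two-group contrast.
#'
#' @param sheet a sample-sheet data.frame.
#' @param genotype,age vocabulary values to select.
#' @return character vector of sample ids.
#' @export
samples_for <- function(sheet, genotype, age) {
  sheet$sample_id[sheet$genotype == genotype & sheet$age == age]
}
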