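#' Construct an expression matrix
#'
#' The pipeline's core container: a numeric matrix of log2 expression
#' values with genes (or probes) as rows and samples as columns, both
#' axes carrying unique identifiers.
#'
#' @param values Numeric matrix (genes x samples), all values finite.
#' @param gene_ids Character vector of unique row identifiers.
#' @param sample_ids Character vector of unique column identifiers.
#' @return An `ExpressionMatrix`: a numeric matrix with dimnames and class
#'   attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stopf("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stopf("dimension mismatch between values and identifiers")
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1])
  if (!all(is.finite(values)))
    stopf("expression values must all be finite")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  value range: [%.3f, %.3f] (log2 scale)\n", min(x), max(x)))
  invisible(x)
}

#' Read an expression matrix
#'
#' Supports a plain TSV dialect (first column gene ids, header row sample
#' ids) and the value block of the GEO series-matrix text format (the
#' lines between the begin/end table sentinels).
#'
#' @param path File path.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to raw-scale input.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "series_matrix"),
                            log2_transform = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    lines <- readLines(path)
    first_line <- 1L
  } else {
    all_lines <- readLines(path)
    begin <- grep("^!series_matrix_table_begin", all_lines)
    end <- grep("^!series_matrix_table_end", all_lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
      stopf("series-matrix table sentinels not found or empty in %s", path)
    lines <- all_lines[(begin + 1):(end - 1)]
    first_line <- begin + 1L
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2)
    stopf("line %d: malformed header (need id column plus >=1 sample)",
          first_line)
  sample_ids <- gsub('^"|"$', "", header[-1])
  if (anyDuplicated(sample_ids))
    stopf("line %d: duplicate sample id: %s", first_line,
          sample_ids[duplicated(sample_ids)][1])
  body <- fields[-1]
  ncol_expect <- length(header)
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    ln <- first_line + i
    row <- body[[i]]
    if (length(row) != ncol_expect)
      stopf("line %d: expected %d fields, found %d", ln, ncol_expect,
            length(row))
    gene_ids[i] <- gsub('^"|"$', "", row[1])
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v))
      stopf("line %d: non-numeric value '%s'", ln, row[-1][which(is.na(v))[1]])
    values[i, ] <- v
  }
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene id '%s' (collapse probes explicitly with collapse_probes())",
          gene_ids[duplicated(gene_ids)][1])
  if (log2_transform) values <- log2(values + 1)
  expression_matrix(values, gene_ids, sample_ids)
}

#' Write an expression matrix as TSV
#'
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @param digits Decimal places written (default 6; the documented
#'   round-trip precision).
#' @export
write_expression <- function(mat, path, digits = 6) {
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "f", digits = digits)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' A per-sample clinical table with columns `sample_id`, `outcome`
#' (`"complicated"`/`"uncomplicated"`), `batch`, and optionally
#' `severity_score`, `mortality`, `age`, `sex`, `pathogen`.
#'
#' @param path CSV file path.
#' @return A `data.frame` with unique `sample_id`s.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ph <- read.csv(path, stringsAsFactors = FALSE)
  validate_phenotype(ph)
}

#' @rdname read_phenotype
#' @param pheno Phenotype `data.frame`.
#' @export
write_phenotype <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_phenotype <- function(ph) {
  if (!all(c("sample_id", "outcome") %in% names(ph)))
    stopf("phenotype table needs at least sample_id and outcome columns")
  if (anyDuplicated(ph$sample_id))
    stopf("duplicate sample_id: %s", ph$sample_id[duplicated(ph$sample_id)][1])
  bad <- setdiff(unique(ph$outcome), c("complicated", "uncomplicated"))
  if (length(bad))
    stopf("unknown outcome level '%s'", bad[1])
  ph
}

#' Summarize a cohort
#'
#' Counts and percentages describing a phenotype table: size, outcome
#' split, sex composition overall and per outcome, mortality within the
#' complicated group, and per-pathogen frequencies when a `pathogen`
#' column is present.  Percentages use round-half-away-from-zero at the
#' requested precision.
#'
#' @param pheno Phenotype table (already filtered to the analysis set;
#'   exclusions are the caller's explicit step).
#' @param digits Decimal places for percentages (default 1). May be a
#'   named list to override per field, e.g.
#'   `list(default = 1, pct_male = 0)`.
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(pheno, digits = 1) {
  if (nrow(pheno) == 0) stopf("empty phenotype table")
  dig <- function(field) {
    if (is.list(digits)) digits[[field]] %||% (digits$default %||% 1)
    else digits
  }
  pct <- function(num, den, field) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, dig(field))
  }
  n <- nrow(pheno)
  comp <- pheno$outcome == "complicated"
  out <- list(
    n_total = n,
    n_complicated = sum(comp),
    n_uncomplicated = sum(!comp),
    pct_complicated = pct(sum(comp), n, "pct_complicated")
  )
  if (!is.null(pheno$sex)) {
    male <- pheno$sex == "male"
    out$n_male <- sum(male)
    out$pct_male <- pct(sum(male), n, "pct_male")
    out$pct_male_complicated <- pct(sum(male & comp), sum(comp),
                                    "pct_male_complicated")
    out$pct_male_uncomplicated <- pct(sum(male & !comp), sum(!comp),
                                      "pct_male_uncomplicated")
  }
  if (!is.null(pheno$mortality)) {
    died <- isTRUE_vec(pheno$mortality)
    out$n_died_complicated <- sum(died & comp)
    out$pct_mortality_complicated <- pct(sum(died & comp), sum(comp),
                                         "pct_mortality_complicated")
  }
  if (!is.null(pheno$pathogen)) {
    tab <- table(pheno$pathogen[!is.na(pheno$pathogen) & pheno$pathogen != ""])
    out$pathogen_pct <- setNames(
      vapply(names(tab), function(p) pct(tab[[p]], n, "pathogen_pct"),
             numeric(1)),
      names(tab))
    out$pathogen_n <- setNames(as.integer(tab), names(tab))
  }
  class(out) <- "cohort_summary"
  out
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) x & !is.na(x)
  else x %in% c("TRUE", "true", "1", "yes")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d samples (%d complicated, %d uncomplicated)\n",
              x$n_total, x$n_complicated, x$n_uncomplicated))
  if (!is.null(x$pct_male))
    cat(sprintf("  male: %d (%s%%)\n", x$n_male, x$pct_male))
  if (!is.null(x$pct_mortality_complicated))
    cat(sprintf("  mortality within complicated: %d (%s%%)\n",
                x$n_died_complicated, x$pct_mortality_complicated))
  invisible(x)
}
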