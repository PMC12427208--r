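#' Read gene sets from a GMT file
#'
#' Tab-separated dialect: set name, description, then one gene per field.
#' Duplicate set names and lines without any gene are errors; duplicated
#' genes within a set are deduplicated with a warning.
#'
#' @param path Path to a GMT file (gzip transparently supported).
#' @return Named list of character gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stopf("GMT line with no genes (name: %s)",
            if (length(fields)) fields[1] else "<blank>")
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stopf("duplicate gene-set name: %s", nm)
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warnf("set %s contains duplicated gene(s); deduplicating", nm)
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional description per set (defaults to the set
#'   name).
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stopf("sets must be uniquely named")
  }
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Expected layout: genes in rows, a header of sample ids, the first
#' column holding gene ids.
#'
#' @param path Path to the TSV (gzip transparently supported).
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m)
}

#' Write a count matrix to TSV
#'
#' @param counts A [count_matrix()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  write_matrix_tsv(counts$values, path, id_col = "gene_id")
}

write_matrix_tsv <- function(m, path, id_col = "gene_id", digits = 10L) {
  df <- data.frame(rownames(m), fmt_signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a clinical table from CSV
#'
#' Requires a `sample_id` column; all other columns are covariates or
#' survival endpoints.
#'
#' @param path Path to the CSV.
#' @return Data frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stopf("clinical table must have a sample_id column")
  }
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in clinical table")
  df
}

write_table_csv <- function(df, path, digits = 10L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## sample-id consistency between an expression object and a clinical table:
## mismatches are an error naming the offenders, never a silent intersection
check_sample_match <- function(expr_ids, clinical_ids, where) {
  only_expr <- setdiff(expr_ids, clinical_ids)
  only_clin <- setdiff(clinical_ids, expr_ids)
  if (length(only_expr) || length(only_clin)) {
    stopf("sample id mismatch in %s: %s%s", where,
          if (length(only_expr))
            sprintf("expression-only: %s. ", paste(utils::head(only_expr, 5), collapse = ", "))
          else "",
          if (length(only_clin))
            sprintf("clinical-only: %s.", paste(utils::head(only_clin, 5), collapse = ", "))
          else "")
  }
  invisible(TRUE)
}
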