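# Plain-text table I/O shared by the pipeline stages and the CLI.
# Numeric columns are formatted with a fixed %.10g so that re-running a
# stage with identical inputs reproduces byte-identical files.

format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write a data.frame as a deterministic TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- format_num(out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read an expression matrix and cohort map
#'
#' The expression TSV has a first column of gene ids (header `gene`) and one
#' column per sample; the cohort TSV has columns `sample` and `cohort`
#' (values `tumor`/`normal`).
#'
#' @param expression_path,cohort_path TSV paths.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expression_path, cohort_path) {
  tbl <- utils::read.delim(expression_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!ncol(tbl) >= 2L)
    stop("expression TSV needs a gene column plus sample columns: ",
         expression_path)
  genes <- as.character(tbl[[1]])
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  co <- utils::read.delim(cohort_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "cohort") %in% names(co)))
    stop("cohort TSV needs 'sample' and 'cohort' columns: ", cohort_path)
  miss <- setdiff(colnames(mat), co$sample)
  if (length(miss))
    stop("cohort map lacks sample(s): ", paste(miss, collapse = ", "))
  cohort <- co$cohort[match(colnames(mat), co$sample)]
  expression_matrix(mat, cohort)
}

#' Write an expression matrix (and cohort map)
#'
#' @param E An [expression_matrix()].
#' @param expression_path,cohort_path Output TSV paths.
#' @return `expression_path`, invisibly.
#' @export
write_expression <- function(E, expression_path, cohort_path) {
  df <- data.frame(gene = E$gene_ids, E$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, expression_path)
  write_tsv(data.frame(sample = E$sample_ids, cohort = E$cohort,
                       stringsAsFactors = FALSE), cohort_path)
  invisible(expression_path)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `logFC`, `pvalue`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_differential <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "logFC", "pvalue") %in% names(tbl)))
    stop("differential table must have columns gene, logFC, pvalue: ", path)
  tbl
}

# flux table: reaction_id plus one column per test label
flux_table <- function(solutions) {
  stopifnot(length(solutions) >= 1L)
  rid <- solutions[[1]]$reaction_ids
  df <- data.frame(reaction_id = rid, stringsAsFactors = FALSE)
  for (s in solutions) df[[s$label]] <- s$v
  df
}
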