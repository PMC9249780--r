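# Expression processing: binarization against global/local thresholds,
# k-medoids clustering of binary sample signatures, silhouette-based model
# selection, and tumor-upregulation flagging.

#' Construct an expression matrix with cohort labels
#'
#' @param values Non-negative numeric matrix, genes x samples, with
#'   dimnames (normalized counts or equivalent).
#' @param cohort Character vector per sample, each `"tumor"` or `"normal"`.
#' @return Object of class `expression_matrix` (list with `values`,
#'   `gene_ids`, `sample_ids`, `cohort`).
#' @export
expression_matrix <- function(values, cohort) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression_matrix: values must carry gene and sample dimnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("expression_matrix: duplicate gene or sample ids")
  if (any(values < 0)) stop("expression_matrix: negative expression values")
  cohort <- as.character(cohort)
  if (length(cohort) != ncol(values))
    stop("expression_matrix: one cohort label per sample required")
  if (!all(cohort %in% c("tumor", "normal")))
    stop("expression_matrix: cohort labels must be 'tumor' or 'normal'")
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), cohort = cohort),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values), sum(x$cohort == "tumor"),
              sum(x$cohort == "normal")))
  invisible(x)
}

#' Binarize tumor expression into activity signatures
#'
#' Flags gene g in sample s as maybe-active (1) iff its value passes two
#' simultaneous thresholds, both inclusive: (i) global -- at least the
#' `cfg$global_quantile` quantile (Q1 by default) of all values across all
#' genes and tumor samples; (ii) local -- at least the gene's own mean
#' across tumor samples. Everything else is inactive (0). The quantile uses
#' the R type-7 (linear interpolation) convention by default
#' (`cfg$quantile_type`).
#'
#' @param E An [expression_matrix()]; only tumor samples are used.
#' @param cfg An [analysis_config()].
#' @return Integer 0/1 matrix, genes x tumor samples, with attributes
#'   `global_threshold` and `gene_means`.
#' @export
binarize <- function(E, cfg = analysis_config()) {
  stopifnot(inherits(E, "expression_matrix"))
  tum <- E$values[, E$cohort == "tumor", drop = FALSE]
  if (nrow(tum) < 2L || ncol(tum) < 2L)
    stop("binarize: need at least 2 genes and 2 tumor samples")
  q1 <- stats::quantile(as.numeric(tum), probs = cfg$global_quantile,
                        type = cfg$quantile_type, names = FALSE)
  gmean <- rowMeans(tum)
  states <- (tum >= q1) & (tum >= gmean)
  storage.mode(states) <- "integer"
  attr(states, "global_threshold") <- q1
  attr(states, "gene_means") <- gmean
  states
}

signature_dist <- function(signatures, method) {
  stats::dist(t(signatures), method = method)
}

#' Cluster binary signatures with PAM (k-medoids)
#'
#' Partitioning Around Medoids over the sample signatures under Manhattan
#' distance (the Hamming count on 0/1 vectors). Medoids are actual input
#' signatures; the clustering is deterministic for a fixed input.
#'
#' @param signatures 0/1 matrix, genes x samples (from [binarize()]).
#' @param k Number of clusters, `2 <= k < n samples`.
#' @param seed Integer seed (PAM itself is deterministic here; the seed is
#'   fixed for interface stability).
#' @param cfg An [analysis_config()] (`pam_distance`).
#' @return List with `assignments` (named integer vector), `medoids`
#'   (genes x k matrix, columns `medoid_1..k`), `medoid_samples` (the sample
#'   ids serving as medoids) and `objective` (sum of distances to assigned
#'   medoids).
#' @export
pam_cluster <- function(signatures, k, seed = 1L, cfg = analysis_config()) {
  n <- ncol(signatures)
  if (k >= n) stop("pam_cluster: k must be smaller than the number of samples")
  if (k < 2L) stop("pam_cluster: k must be >= 2")
  set.seed(seed)
  d <- signature_dist(signatures, cfg$pam_distance)
  fit <- cluster::pam(d, k = k, diss = TRUE)
  med_samples <- fit$medoids
  medoids <- signatures[, med_samples, drop = FALSE]
  colnames(medoids) <- paste0("medoid_", seq_len(k))
  dm <- as.matrix(d)
  obj <- sum(dm[cbind(colnames(signatures), med_samples[fit$clustering])])
  list(assignments = fit$clustering, medoids = medoids,
       medoid_samples = med_samples, objective = obj)
}

#' Select the number of clusters by mean silhouette width
#'
#' Runs PAM for each candidate k and returns the k maximizing the mean
#' silhouette width (ties broken by the smallest k). If all signatures are
#' identical the silhouette is undefined; the smallest candidate is
#' returned with a warning.
#'
#' @param signatures 0/1 matrix, genes x samples.
#' @param k_range Candidate cluster counts (subset of `2..n-1`).
#' @param seed Integer seed.
#' @param cfg An [analysis_config()].
#' @return Integer k; attribute `"widths"` holds the mean silhouette width
#'   per candidate.
#' @export
select_k_silhouette <- function(signatures, k_range = 2:5, seed = 1L,
                                cfg = analysis_config()) {
  n <- ncol(signatures)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("select_k_silhouette: k_range must lie within [2, n_samples - 1]")
  d <- signature_dist(signatures, cfg$pam_distance)
  if (max(d) == 0) {
    warning("select_k_silhouette: all signatures identical; ",
            "silhouette undefined, returning min(k_range)")
    return(structure(min(k_range), widths = stats::setNames(
      rep(NA_real_, length(k_range)), k_range)))
  }
  widths <- vapply(k_range, function(k) {
    set.seed(seed)
    fit <- cluster::pam(d, k = k, diss = TRUE)
    fit$silinfo$avg.width
  }, numeric(1))
  names(widths) <- k_range
  structure(k_range[which.max(widths)], widths = widths)
}

#' Flag tumor-upregulated genes
#'
#' Returns exactly the genes with `logFC >= cfg$logfc_min` and
#' `pvalue <= cfg$pvalue_max` (both inequalities inclusive; defaults 1.5 and
#' 1e-16).
#'
#' @param table data.frame with columns `gene`, `logFC`, `pvalue`.
#' @param cfg An [analysis_config()].
#' @return Sorted character vector of upregulated gene ids.
#' @export
flag_upregulated <- function(table, cfg = analysis_config()) {
  req <- c("gene", "logFC", "pvalue")
  if (!all(req %in% names(table)))
    stop("flag_upregulated: table must have columns ",
         paste(req, collapse = ", "))
  if (!nrow(table)) stop("flag_upregulated: empty differential table")
  if (any(table$pvalue < 0 | table$pvalue > 1, na.rm = TRUE))
    stop("flag_upregulated: p-values outside [0, 1]")
  keep <- table$logFC >= cfg$logfc_min & table$pvalue <= cfg$pvalue_max
  sort(unique(as.character(table$gene[keep & !is.na(keep)])))
}

#' Convenience log fold change table (synthetic use only)
#'
#' A deliberately simple stand-in for a differential-expression pipeline,
#' intended for synthetic fixtures: `logFC = log2((mean tumor + eps) /
#' (mean normal + eps))` with `eps = 1`, and a per-gene two-sided Welch
#' t-test p-value. This is NOT a substitute for a proper count-based
#' differential analysis on real data.
#'
#' @param E An [expression_matrix()] containing both cohorts.
#' @param eps Pseudocount.
#' @return data.frame with columns `gene`, `logFC`, `pvalue`.
#' @export
logfc_table <- function(E, eps = 1) {
  stopifnot(inherits(E, "expression_matrix"))
  tum <- E$values[, E$cohort == "tumor", drop = FALSE]
  nor <- E$values[, E$cohort == "normal", drop = FALSE]
  if (!ncol(tum) || !ncol(nor))
    stop("logfc_table: both cohorts must be present")
  lfc <- log2((rowMeans(tum) + eps) / (rowMeans(nor) + eps))
  pv <- vapply(seq_len(nrow(tum)), function(i) {
    x <- tum[i, ]; y <- nor[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  data.frame(gene = rownames(tum), logFC = as.numeric(lfc),
             pvalue = pv, row.names = NULL, stringsAsFactors = FALSE)
}
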