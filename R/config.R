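#' Analysis configuration
#'
#' Collects every tunable threshold of the workflow in one validated object.
#' Defaults follow the published analysis design: the global binarization
#' threshold is the first quartile (Q1) of all expression values, upregulation
#' requires logFC >= 1.5 at p <= 1e-16, oxygen uptake is capped at
#' 2 mmol/gDW/h, a reaction is essential when its knockout drops the optimal
#' biomass flux by at least 5%, the objective-weight lattice is the simplex
#' lattice \{3,4\} (15 weight vectors), the occurrence criterion is "extended
#' choke point in at least half of the non-redundant optima", and the
#' centrality criterion is "top 10% by summed PageRank".
#'
#' @param global_quantile Fraction in (0,1]; global expression threshold
#'   quantile ("Q1" = 0.25).
#' @param logfc_min Minimum log2 fold change (tumor vs normal) for a gene to
#'   count as upregulated.
#' @param pvalue_max Maximum p-value for upregulation.
#' @param oxygen_ub Upper bound on the oxygen uptake rate (mmol/gDW/h).
#' @param essentiality_drop Fractional biomass reduction defining essentiality.
#' @param lattice_q,lattice_m Simplex lattice \{q,m\} parameters (number of
#'   objectives and lattice resolution).
#' @param occurrence_fraction Fraction of non-redundant optima in which a
#'   reaction must be an extended choke point to be occurrence-selected.
#' @param centrality_top_fraction Fraction of ranked reactions counted as
#'   topologically important (ties at the cutoff included).
#' @param damping PageRank damping factor.
#' @param flux_tol Absolute flux below which a reaction is considered inactive.
#' @param dedup_tol L-infinity tolerance under which two flux distributions are
#'   considered redundant.
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (type 7, linear interpolation, matches R defaults).
#' @param pam_distance Distance for PAM/silhouette on binary vectors
#'   ("manhattan", equal to the Hamming count on 0/1 data, or "euclidean").
#' @param missing_gene Policy when a GPR references a gene absent from the
#'   supplied activity states: "error" (strict) or "inactive" (treat as 0).
#' @param extended_rule Quantifier over the neighbors of a double choke point
#'   when testing the extended class: "all" (every producer/consumer neighbor
#'   must be a strict single choke point) or "exists" (at least one).
#' @param min_flux_anchor Anchor for the flux-sum minimization test:
#'   "biomass" (fix biomass at its single-objective optimum, the parsimonious
#'   FBA convention) or "none" (unanchored; returns the degenerate all-zero
#'   optimum and is flagged as such).
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$oxygen_ub
#' @export
analysis_config <- function(global_quantile = 0.25,
                            logfc_min = 1.5,
                            pvalue_max = 1e-16,
                            oxygen_ub = 2,
                            essentiality_drop = 0.05,
                            lattice_q = 3L,
                            lattice_m = 4L,
                            occurrence_fraction = 0.5,
                            centrality_top_fraction = 0.10,
                            damping = 0.85,
                            flux_tol = 1e-6,
                            dedup_tol = 1e-6,
                            quantile_type = 7L,
                            pam_distance = c("manhattan", "euclidean"),
                            missing_gene = c("error", "inactive"),
                            extended_rule = c("all", "exists"),
                            min_flux_anchor = c("biomass", "none")) {
  cfg <- list(
    global_quantile = global_quantile,
    logfc_min = logfc_min,
    pvalue_max = pvalue_max,
    oxygen_ub = oxygen_ub,
    essentiality_drop = essentiality_drop,
    lattice_q = as.integer(lattice_q),
    lattice_m = as.integer(lattice_m),
    occurrence_fraction = occurrence_fraction,
    centrality_top_fraction = centrality_top_fraction,
    damping = damping,
    flux_tol = flux_tol,
    dedup_tol = dedup_tol,
    quantile_type = as.integer(quantile_type),
    pam_distance = match.arg(pam_distance),
    missing_gene = match.arg(missing_gene),
    extended_rule = match.arg(extended_rule),
    min_flux_anchor = match.arg(min_flux_anchor)
  )
  for (f in c("global_quantile", "essentiality_drop", "occurrence_fraction",
              "centrality_top_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      stop("analysis_config: '", f, "' must be a fraction in (0, 1]")
  }
  for (f in c("flux_tol", "dedup_tol")) {
    if (!(cfg[[f]] >= 0)) stop("analysis_config: '", f, "' must be >= 0")
  }
  if (cfg$flux_tol <= 0) stop("analysis_config: 'flux_tol' must be > 0")
  if (cfg$damping <= 0 || cfg$damping >= 1)
    stop("analysis_config: 'damping' must be in (0, 1)")
  if (cfg$lattice_q < 2L) stop("analysis_config: 'lattice_q' must be >= 2")
  if (cfg$lattice_m < 1L) stop("analysis_config: 'lattice_m' must be >= 1")
  if (cfg$oxygen_ub < 0) stop("analysis_config: 'oxygen_ub' must be >= 0")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Merge a plain list of overrides (e.g. from a YAML config file) into defaults.
as_analysis_config <- function(x = list()) {
  if (inherits(x, "analysis_config")) return(x)
  stopifnot(is.list(x))
  known <- names(formals(analysis_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, x)
}
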