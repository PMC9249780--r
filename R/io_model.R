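# Model I/O: COBRA-style JSON and a minimal SBML Level 3 + FBC v2 subset.

#' Load a metabolic model from JSON or SBML
#'
#' Reads either a COBRA-style JSON model (fields `reactions[].id`,
#' `.metabolites`, `.lower_bound`, `.upper_bound`, `.gene_reaction_rule` --
#' the de facto interchange format for genome-scale models) or an SBML
#' Level 3 document using the FBC v2 flux-bounds and gene-product constructs.
#' Objective role tags (`biomass`, `atp`, `pi4p`, `oxygen_uptake`) are read
#' from a top-level `objective_tags` object in JSON (an extension this
#' package also writes) and may be overridden with the `objective_tags`
#' argument; SBML files carry no tags, so supply them here.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @param objective_tags Optional named character vector overriding/setting
#'   role tags.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml"),
                       objective_tags = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  m <- switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
  if (!is.null(objective_tags)) {
    m$objective_tags <- objective_tags
    validate_model(m)
  }
  m
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse failure in '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(doc$reactions) || !length(doc$reactions))
    stop("JSON model format error: missing or empty 'reactions' element")
  rxns <- doc$reactions
  rid <- vapply(rxns, function(r) {
    if (is.null(r$id)) stop("JSON model format error: reaction without 'id'")
    as.character(r$id)
  }, character(1))
  met_declared <- if (!is.null(doc$metabolites))
    vapply(doc$metabolites, function(x) as.character(x$id), character(1))
  else character(0)
  met_used <- unique(unlist(lapply(rxns, function(r) names(r$metabolites))))
  mids <- unique(c(met_declared, met_used))
  S <- matrix(0, nrow = length(mids), ncol = length(rid),
              dimnames = list(mids, rid))
  for (j in seq_along(rxns)) {
    mm <- rxns[[j]]$metabolites
    for (mid in names(mm)) S[mid, j] <- as.numeric(mm[[mid]])
  }
  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  lb <- vapply(rxns, function(r) num_or(r$lower_bound, -1000), numeric(1))
  ub <- vapply(rxns, function(r) num_or(r$upper_bound, 1000), numeric(1))
  gpr <- vapply(rxns, function(r) {
    if (is.null(r$gene_reaction_rule)) "" else as.character(r$gene_reaction_rule)
  }, character(1))
  genes <- if (!is.null(doc$genes))
    vapply(doc$genes, function(x) as.character(x$id), character(1))
  else NULL
  tags <- if (!is.null(doc$objective_tags))
    unlist(doc$objective_tags) else character(0)
  metabolic_model(
    metabolite_ids = mids, reaction_ids = rid, S = S,
    lower_bound = lb, upper_bound = ub, gpr = gpr, gene_ids = genes,
    objective_tags = tags,
    id = if (!is.null(doc$id)) as.character(doc$id) else "model"
  )
}

#' Write a model as COBRA-style JSON
#'
#' @param m A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  rxns <- lapply(seq_along(m$reaction_ids), function(j) {
    col <- m$S[, j]
    nz <- which(col != 0)
    mets <- as.list(as.numeric(col[nz]))
    names(mets) <- m$metabolite_ids[nz]
    list(
      id = m$reaction_ids[j],
      metabolites = mets,
      lower_bound = m$lower_bound[j],
      upper_bound = m$upper_bound[j],
      gene_reaction_rule = m$gpr[j]
    )
  })
  doc <- list(
    id = m$id,
    metabolites = lapply(m$metabolite_ids, function(x) list(id = x)),
    reactions = rxns,
    genes = lapply(m$gene_ids, function(x) list(id = x)),
    objective_tags = as.list(m$objective_tags)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML L3 + FBC v2 subset ------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a model as SBML Level 3 with FBC v2
#'
#' Emits the subset of SBML L3v1 + FBC v2 this package also reads: species,
#' bound parameters referenced by `fbc:lowerFluxBound`/`fbc:upperFluxBound`,
#' and nested `fbc:and`/`fbc:or`/`fbc:geneProductRef` gene associations.
#' Identifiers are written as given and must be valid SBML SIds.
#'
#' @param m A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(m, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  bounds <- sort(unique(c(m$lower_bound, m$upper_bound)))
  bnd_id <- function(v) sprintf("bnd_%d", match(v, bounds))
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(m$id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" compartment="c" constant="false" ',
                   'boundaryCondition="false" hasOnlySubstanceUnits="false"/>'),
            vapply(m$metabolite_ids, esc, character(1))),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            vapply(bounds, bnd_id, character(1)),
            vapply(bounds, num, character(1))),
    '    </listOfParameters>',
    '    <listOfReactions>'
  )
  render_gpr <- function(node, indent) {
    pad <- strrep(" ", indent)
    switch(node$type,
      "gene" = sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                       pad, esc(node$gene)),
      c(sprintf("%s<fbc:%s>", pad, node$type),
        unlist(lapply(node$args, render_gpr, indent = indent + 2L)),
        sprintf("%s</fbc:%s>", pad, node$type))
    )
  }
  for (j in seq_along(m$reaction_ids)) {
    col <- m$S[, j]
    reac <- which(col < 0)
    prod <- which(col > 0)
    L <- c(L, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(m$reaction_ids[j]),
      if (m$lower_bound[j] < 0) "true" else "false",
      bnd_id(m$lower_bound[j]), bnd_id(m$upper_bound[j])))
    if (length(reac)) {
      L <- c(L, "        <listOfReactants>",
             sprintf(paste0('          <speciesReference species="%s" ',
                            'stoichiometry="%s" constant="true"/>'),
                     vapply(m$metabolite_ids[reac], esc, character(1)),
                     vapply(-as.numeric(col[reac]), num, character(1))),
             "        </listOfReactants>")
    }
    if (length(prod)) {
      L <- c(L, "        <listOfProducts>",
             sprintf(paste0('          <speciesReference species="%s" ',
                            'stoichiometry="%s" constant="true"/>'),
                     vapply(m$metabolite_ids[prod], esc, character(1)),
                     vapply(as.numeric(col[prod]), num, character(1))),
             "        </listOfProducts>")
    }
    if (m$gpr_ast[[j]]$type != "true") {
      L <- c(L, "        <fbc:geneProductAssociation>",
             render_gpr(m$gpr_ast[[j]], 10L),
             "        </fbc:geneProductAssociation>")
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>")
  if (length(m$gene_ids)) {
    L <- c(L, "    <fbc:listOfGeneProducts>",
           sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                   vapply(m$gene_ids, esc, character(1)),
                   vapply(m$gene_ids, esc, character(1))),
           "    </fbc:listOfGeneProducts>")
  }
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing"))
    stop("SBML format error: no <model> element in SBML Level 3 namespace")
  species <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  mids <- xml2::xml_attr(species, "id")
  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- as.numeric(xml2::xml_attr(params, "value"))
  names(pval) <- xml2::xml_attr(params, "id")
  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("SBML format error: model has no reactions")
  rid <- xml2::xml_attr(rx, "id")
  S <- matrix(0, nrow = length(mids), ncol = length(rid),
              dimnames = list(mids, rid))
  lb <- numeric(length(rid)); ub <- numeric(length(rid))
  gpr <- character(length(rid))
  bound_of <- function(ref, rid_j, side) {
    if (is.na(ref))
      stop("SBML format error: reaction '", rid_j, "' lacks fbc:", side,
           "FluxBound")
    if (!ref %in% names(pval))
      stop("SBML format error: flux bound parameter '", ref, "' not defined")
    pval[[ref]]
  }
  gpr_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(xml2::xml_attr(node, "fbc:geneProduct", c(fbc = FBC_NS)))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_text, character(1))
    op <- if (nm == "and") " and " else if (nm == "or") " or " else
      stop("SBML format error: unexpected element <", nm,
           "> in gene association")
    paste0("(", paste(parts, collapse = op), ")")
  }
  for (j in seq_along(rid)) {
    r <- rx[[j]]
    lb[j] <- bound_of(xml2::xml_attr(r, "fbc:lowerFluxBound", ns), rid[j], "lower")
    ub[j] <- bound_of(xml2::xml_attr(r, "fbc:upperFluxBound", ns), rid[j], "upper")
    for (sr in xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference",
                                  ns)) {
      sp <- xml2::xml_attr(sr, "species")
      if (!sp %in% mids)
        stop("SBML format error: reaction '", rid[j],
             "' references unknown species '", sp, "'")
      S[sp, j] <- S[sp, j] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference",
                                  ns)) {
      sp <- xml2::xml_attr(sr, "species")
      if (!sp %in% mids)
        stop("SBML format error: reaction '", rid[j],
             "' references unknown species '", sp, "'")
      S[sp, j] <- S[sp, j] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    assoc <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", ns)
    if (!inherits(assoc, "xml_missing")) {
      root <- xml2::xml_children(assoc)
      if (length(root) != 1L)
        stop("SBML format error: reaction '", rid[j],
             "' has a malformed gene association")
      gpr[j] <- gpr_text(root[[1]])
    }
  }
  gp <- xml2::xml_find_all(model, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  genes <- xml2::xml_attr(gp, "fbc:id", ns)
  mid_attr <- xml2::xml_attr(model, "id")
  metabolic_model(
    metabolite_ids = mids, reaction_ids = rid, S = S,
    lower_bound = lb, upper_bound = ub, gpr = gpr,
    gene_ids = if (length(genes)) genes else NULL,
    id = if (is.na(mid_attr)) "model" else mid_attr
  )
}
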