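# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar:  expr := term ("or" term)*
#           term := factor ("and" factor)*
#           factor := "(" expr ")" | identifier
# Identifiers are maximal runs of non-space, non-parenthesis characters, which
# tolerates Ensembl, HGNC and arbitrary synthetic ids. Connectives are
# case-insensitive. The empty rule parses to an always-active sentinel.

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean rule such as `"(g1 and g2) or g3"` into an expression tree
#' with AND/OR nodes and gene leaves. AND encodes enzyme complexes (all
#' subunits required), OR encodes isozymes (any suffices). An empty or
#' whitespace-only rule returns an always-active sentinel, the convention for
#' reactions without gene annotation (e.g. spontaneous or exchange reactions).
#'
#' @param rule_text Character scalar; may be empty.
#' @return An object of class `gpr`: a nested list with `type` one of
#'   `"and"`, `"or"`, `"gene"` (with a `gene` field) or `"true"` (sentinel).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' parse_gpr("")
#' @seealso [evaluate_gpr()], [gpr_genes()]
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  if (is.na(rule_text) || !nzchar(trimws(rule_text)))
    return(structure(list(type = "true"), class = "gpr"))

  toks <- gpr_tokenize(rule_text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks))
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$at[st$pos], st$toks$text[st$pos]))
  structure(expr, class = "gpr")
}

gpr_tokenize <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  text <- character(0); type <- character(0); at <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      text <- c(text, ch); type <- c(type, ch); at <- c(at, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "ident")
    text <- c(text, word); at <- c(at, i)
    i <- j
  }
  data.frame(text = text, type = type, at = at, stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(type = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_factor(st))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_factor(st)))
  }
  if (length(args) == 1L) args[[1]] else list(type = "and", args = args)
}

gpr_parse_factor <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk))
    stop("GPR parse error: unexpected end of rule (unbalanced expression)")
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")")
      stop(sprintf("GPR parse error at position %d: unbalanced parenthesis",
                   tk$at))
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "ident") {
    st$pos <- st$pos + 1L
    return(list(type = "gene", gene = tk$text))
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               tk$at, tk$text))
}

#' Evaluate a GPR rule against binary gene states
#'
#' AND nodes take the minimum of their children, OR nodes the maximum; the
#' always-active sentinel evaluates to 1.
#'
#' @param expr A `gpr` object from [parse_gpr()].
#' @param gene_states Named vector (or list) mapping gene ids to 0/1.
#' @param missing Policy for leaf genes absent from `gene_states`: `"error"`
#'   (default, strict) or `"inactive"` (score the leaf 0).
#' @return Integer 0 or 1.
#' @examples
#' evaluate_gpr(parse_gpr("(g1 and g2) or g3"), c(g1 = 1, g2 = 0, g3 = 1))
#' @export
evaluate_gpr <- function(expr, gene_states, missing = c("error", "inactive")) {
  missing <- match.arg(missing)
  gene_states <- unlist(gene_states)
  eval_node <- function(node) {
    switch(node$type,
      "true" = 1L,
      "gene" = {
        if (!node$gene %in% names(gene_states)) {
          if (missing == "error")
            stop("evaluate_gpr: gene '", node$gene,
                 "' absent from gene_states")
          0L
        } else as.integer(gene_states[[node$gene]] != 0)
      },
      "and" = min(vapply(node$args, eval_node, integer(1))),
      "or"  = max(vapply(node$args, eval_node, integer(1))),
      stop("evaluate_gpr: malformed GPR node type '", node$type, "'")
    )
  }
  eval_node(expr)
}

#' Genes referenced by a GPR rule
#'
#' @param expr A `gpr` object.
#' @return Character vector of unique gene ids (empty for the sentinel).
#' @export
gpr_genes <- function(expr) {
  walk <- function(node) {
    switch(node$type,
      "true" = character(0),
      "gene" = node$gene,
      unlist(lapply(node$args, walk))
    )
  }
  unique(walk(expr))
}

#' Serialize a GPR tree back to rule text
#'
#' Produces a normalized, fully parenthesized form; `parse_gpr()` of the
#' output yields an equivalent tree.
#'
#' @param expr A `gpr` object.
#' @return Character scalar (empty string for the sentinel).
#' @export
gpr_to_string <- function(expr) {
  render <- function(node, top = FALSE) {
    switch(node$type,
      "true" = "",
      "gene" = node$gene,
      {
        inner <- paste(vapply(node$args, render, character(1)),
                       collapse = paste0(" ", node$type, " "))
        if (top) inner else paste0("(", inner, ")")
      }
    )
  }
  render(expr, top = TRUE)
}

#' @export
print.gpr <- function(x, ...) {
  s <- gpr_to_string(x)
  cat("<gpr> ", if (nzchar(s)) s else "(always active)", "\n", sep = "")
  invisible(x)
}
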