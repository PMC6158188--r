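# Gene-protein-reaction (GPR) boolean rules: a tiny recursive-descent
# parser for parenthesized AND/OR expressions over gene ids. Unknown
# syntax is an error, never silently ignored — a corrupted GPR is
# untestable downstream.

GPR_TOKEN_RE <- "^[A-Za-z0-9_.:-]+$"

tokenize_gpr <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR boolean expression
#'
#' Accepts gene ids combined with `and` / `or` (case-insensitive) and
#' parentheses; `or` binds more loosely than `and`. Anything else is a
#' parse error.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return A nested list tree: either `list(op = "gene", gene = id)` or
#'   `list(op = "and"/"or", args = list(...))`; `NULL` for an empty rule.
#' @export
parse_gpr <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- tokenize_gpr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[[pos - 1L]] }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tok <- peek()
    assert(!is.na(tok), "GPR parse error: unexpected end of expression in '", text, "'")
    if (tok == "(") {
      advance()
      node <- parse_or()
      assert(identical(peek(), ")"),
             "GPR parse error: missing ')' in '", text, "'")
      advance()
      return(node)
    }
    assert(tok != ")", "GPR parse error: unexpected ')' in '", text, "'")
    assert(!tolower(tok) %in% c("and", "or"),
           "GPR parse error: operator '", tok, "' where a gene was expected in '",
           text, "'")
    assert(grepl(GPR_TOKEN_RE, tok),
           "GPR parse error: invalid token '", tok, "' in '", text, "'")
    advance()
    list(op = "gene", gene = tok)
  }

  tree <- parse_or()
  assert(pos > length(toks),
         "GPR parse error: trailing tokens after position ", pos, " in '", text, "'")
  tree
}

#' Genes referenced by a GPR tree
#' @param tree Output of [parse_gpr()].
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Canonical string form of a GPR tree
#'
#' Deterministic serialization (single spaces, explicit parentheses around
#' nested sub-expressions) so round-tripped rules compare equal up to
#' whitespace.
#'
#' @param tree Output of [parse_gpr()].
#' @return A string; `""` for `NULL`.
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(node, parent_op) {
    if (node$op == "gene") return(node$gene)
    inner <- vapply(node$args, rec, "", node$op)
    s <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (!is.na(parent_op)) paste0("(", s, ")") else s
  }
  rec(tree, NA_character_)
}

canonical_gpr <- function(text) deparse_gpr(parse_gpr(text))
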