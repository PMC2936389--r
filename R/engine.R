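# Query execution: evaluate Boolean strategies against a local corpus with
# set semantics (OR = union, AND = intersection, NOT = difference).
#
# [tiab] matching is exact-token and unstemmed: a term matches iff it occurs
# as a whole token in the title or abstract; phrases must occur as a
# consecutive token run and never cross the title/abstract boundary. PubMed's
# automatic term mapping and spelling-variant expansion are deliberately not
# emulated — strategies are expected to spell out variants explicitly.

# ---- MeSH tree -----------------------------------------------------------

#' Read a MeSH tree table
#'
#' Two-column delimited text (tab or semicolon): tree number, descriptor.
#' A header line is skipped when its first field is not a tree number.
#' Tree numbers are dot-separated paths such as `N02.278.354`; descriptor
#' D2 is a descendant of D1 when one of D2's tree numbers extends one of
#' D1's with a `.` segment.
#'
#' @param file path or connection.
#' @return data.frame with columns `tree_number`, `descriptor`, of class
#'   `mesh_tree`.
#' @export
read_mesh_tree <- function(file) {
  lines <- read_input_lines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  parts <- strsplit(lines, "[\t;]")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop("line ", bad[1], ": expected 'tree_number<TAB>descriptor'")
  df <- data.frame(tree_number = trimws(vapply(parts, `[`, "", 1L)),
                   descriptor = trimws(vapply(parts, `[`, "", 2L)),
                   stringsAsFactors = FALSE)
  if (nrow(df) && !grepl("^[A-Za-z][0-9]", df$tree_number[1]))
    df <- df[-1L, , drop = FALSE]  # header
  structure(df, class = c("mesh_tree", "data.frame"))
}

#' @param tree_number,descriptor equal-length character vectors.
#' @rdname read_mesh_tree
#' @export
mesh_tree <- function(tree_number, descriptor) {
  stopifnot(length(tree_number) == length(descriptor))
  structure(data.frame(tree_number = as.character(tree_number),
                       descriptor = as.character(descriptor),
                       stringsAsFactors = FALSE),
            class = c("mesh_tree", "data.frame"))
}

# descriptor plus all tree descendants, as a lowercase character set
mesh_descendants <- function(tree, descriptor) {
  stopifnot(inherits(tree, "mesh_tree"))
  own <- tree$tree_number[tolower(tree$descriptor) == tolower(descriptor)]
  if (!length(own)) return(tolower(descriptor))
  hit <- rep(FALSE, nrow(tree))
  for (tn in own) hit <- hit | startsWith(tree$tree_number, paste0(tn, "."))
  unique(c(tolower(descriptor), tolower(tree$descriptor[hit])))
}

# ---- single-record matchers ---------------------------------------------

# does the token run 'phrase' occur consecutively in stream?
stream_has_phrase <- function(stream, phrase) {
  k <- length(phrase)
  n <- length(stream)
  if (k == 0L || n < k) return(FALSE)
  if (k == 1L) return(phrase %in% stream)
  starts <- which(stream == phrase[1])
  starts <- starts[starts + k - 1L <= n]
  for (s in starts) if (all(stream[s:(s + k - 1L)] == phrase)) return(TRUE)
  FALSE
}

#' Title/abstract term matching
#'
#' Case-insensitive, exact-token matching of a `[tiab]` term against one
#' record: a single term matches when it equals a token of the title or
#' abstract; a multi-word phrase matches when its token sequence occurs
#' consecutively within the title or within the abstract (never across the
#' boundary). No stemming, no substring matching: `staff` does not match
#' `staffing`.
#'
#' @param record a [medline_record()].
#' @param text term or phrase.
#' @return logical scalar.
#' @export
match_tiab <- function(record, text) {
  stopifnot(inherits(record, "medline_record"))
  phrase <- token_stream(text)
  if (!length(phrase)) return(FALSE)
  stream_has_phrase(token_stream(record$title), phrase) ||
    stream_has_phrase(token_stream(record$abstract), phrase)
}

#' MeSH heading matching
#'
#' Case-insensitive equality of the query descriptor against the record's
#' headings. When a subheading is given, the matching heading must also
#' carry that qualifier. With `explode = TRUE` and a [read_mesh_tree()]
#' table, descendants of the descriptor also match (on any of which the
#' subheading constraint, if present, applies).
#'
#' @param record a [medline_record()].
#' @param descriptor MeSH descriptor text.
#' @param subheading optional qualifier.
#' @param explode expand to tree descendants; requires `tree`.
#' @param tree a [mesh_tree()] table.
#' @return logical scalar.
#' @export
match_mesh <- function(record, descriptor, subheading = NULL,
                       explode = FALSE, tree = NULL) {
  stopifnot(inherits(record, "medline_record"))
  if (isTRUE(explode) && is.null(tree))
    stop("explode = TRUE requires a MeSH tree")
  targets <- if (isTRUE(explode)) mesh_descendants(tree, descriptor)
             else tolower(descriptor)
  for (h in record$mesh) {
    if (!(tolower(h$descriptor) %in% targets)) next
    if (is.null(subheading)) return(TRUE)
    if (tolower(subheading) %in% tolower(h$subheadings)) return(TRUE)
  }
  FALSE
}

# ---- corpus-level execution ---------------------------------------------

# pre-tokenized view of a corpus for repeated matching
corpus_index <- function(corpus) {
  streams <- function(field) {
    txt <- vapply(corpus$records, `[[`, character(1), field)
    lapply(strsplit(tolower(txt), "[^a-z0-9]+"), function(t) t[nzchar(t)])
  }
  list(
    pmid = pmids(corpus),
    title = streams("title"),
    abstract = streams("abstract"),
    records = corpus$records
  )
}

eval_term_mask <- function(node, idx, tree, explode_default) {
  n <- length(idx$pmid)
  if (node$field == "tiab") {
    phrase <- token_stream(node$text)
    if (!length(phrase)) return(rep(FALSE, n))
    if (length(phrase) == 1L) {
      t1 <- vapply(idx$title, function(s) phrase %in% s, logical(1))
      a1 <- vapply(idx$abstract, function(s) phrase %in% s, logical(1))
      return(t1 | a1)
    }
    t1 <- vapply(idx$title, stream_has_phrase, logical(1), phrase)
    a1 <- vapply(idx$abstract, stream_has_phrase, logical(1), phrase)
    return(t1 | a1)
  }
  explode <- if (is.na(node$explode)) explode_default else node$explode
  if (isTRUE(explode) && is.null(tree))
    stop("explosion of \"", node$text, "\"[mh] requested but no MeSH tree supplied")
  vapply(idx$records, match_mesh, logical(1),
         descriptor = node$text, subheading = node$subheading,
         explode = isTRUE(explode), tree = tree)
}

eval_expr_mask <- function(expr, idx, line_masks, tree, explode_default) {
  switch(expr$type,
    term = eval_term_mask(expr, idx, tree, explode_default),
    ref  = line_masks[[expr$n]],
    op   = {
      masks <- lapply(expr$operands, eval_expr_mask, idx = idx,
                      line_masks = line_masks, tree = tree,
                      explode_default = explode_default)
      switch(expr$op,
        OR  = Reduce(`|`, masks),
        AND = Reduce(`&`, masks),
        NOT = masks[[1]] & !masks[[2]])
    },
    stop("unknown expression type: ", expr$type))
}

#' Execute a strategy or query expression against a corpus
#'
#' Evaluates line by line with set semantics and returns the PMIDs retrieved
#' by the result line (for a `boolean_strategy`) or by the expression
#' itself. An optional year range is applied with [filter_by_year()] before
#' matching, mirroring a database date limit.
#'
#' @param x a `boolean_strategy` or `query_expr`.
#' @param corpus a [medline_corpus()].
#' @param tree optional [mesh_tree()] for explosion.
#' @param explode default explosion behaviour for `[mh]` terms that do not
#'   set their own flag; `FALSE` runs tree-free as plain descriptor
#'   matching (PubMed itself explodes by default, but that requires a tree).
#' @param year_range optional `c(start, end)` inclusive publication-year
#'   limit.
#' @return character vector of retrieved PMIDs, in corpus order.
#' @export
#' @examples
#' corp <- medline_corpus(list(
#'   medline_record("1", title = "Hospital nurse staffing and mortality"),
#'   medline_record("2", title = "Physician workload")))
#' execute_strategy(parse_query("staffing[tiab]"), corp)
execute_strategy <- function(x, corpus, tree = NULL, explode = FALSE,
                             year_range = NULL) {
  stopifnot(inherits(corpus, "medline_corpus"))
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2L)
    corpus <- filter_by_year(corpus, year_range[1], year_range[2])
  }
  if (!length(corpus)) return(character())
  idx <- corpus_index(corpus)
  if (inherits(x, "query_expr")) {
    mask <- eval_expr_mask(x, idx, list(), tree, explode)
    return(idx$pmid[mask])
  }
  stopifnot(inherits(x, "boolean_strategy"))
  line_masks <- vector("list", length(x$lines))
  for (k in seq_along(x$lines))
    line_masks[[k]] <- eval_expr_mask(x$lines[[k]], idx, line_masks, tree, explode)
  idx$pmid[line_masks[[x$result_line]]]
}
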