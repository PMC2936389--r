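# PubMed-style Boolean strategy representation, parser and serializer.
#
# Two dialects are supported:
#   * numbered-line: one expression per line, "N<space>expr", where later
#     lines reference earlier ones as #N and the last line is the result;
#   * single-line: one stand-alone expression.
# Terms carry a field tag: term[tiab] (title/abstract, exact token match) or
# "Descriptor/subheading"[mh] (MeSH heading). Operator precedence is
# NOT > AND > OR, left-associative; parentheses override. Operators and
# field tags are case-insensitive.

# ---- expression constructors --------------------------------------------

#' Query expression nodes
#'
#' Low-level constructors for the Boolean query tree. Most users parse text
#' with [parse_strategy()] or [parse_query()] instead.
#'
#' `term_node()` is a field-tagged term: a single token or phrase restricted
#' to title/abstract (`field = "tiab"`) or a MeSH descriptor with optional
#' subheading (`field = "mh"`). `op_node()` combines two or more operands
#' with `AND`/`OR`, or exactly two with `NOT` (set difference). `line_ref()`
#' refers to an earlier numbered line of a strategy.
#'
#' @param text term or phrase text ([tiab]) or MeSH descriptor ([mh]).
#' @param field `"tiab"` or `"mh"`.
#' @param subheading optional MeSH qualifier (only with `field = "mh"`).
#' @param explode `NA` (follow the run-level default), `TRUE` or `FALSE`:
#'   whether the descriptor is expanded to its MeSH-tree descendants.
#' @return an object of class `query_expr`.
#' @export
term_node <- function(text, field = c("tiab", "mh"), subheading = NULL, explode = NA) {
  field <- match.arg(field)
  text <- as.character(text)
  if (length(text) != 1L || !nzchar(trimws(text))) stop("empty term")
  if (field == "tiab" && !is.null(subheading)) stop("[tiab] terms take no subheading")
  structure(list(type = "term", text = text, field = field,
                 subheading = subheading, explode = explode),
            class = c("query_term", "query_expr"))
}

#' @param op `"AND"`, `"OR"` or `"NOT"`.
#' @param operands list of `query_expr` operands.
#' @rdname term_node
#' @export
op_node <- function(op, operands) {
  op <- toupper(op)
  stopifnot(op %in% c("AND", "OR", "NOT"), is.list(operands))
  if (length(operands) < 2L) stop("'", op, "' needs at least two operands")
  if (op == "NOT" && length(operands) != 2L) stop("'NOT' is binary (A NOT B)")
  if (!all(vapply(operands, inherits, logical(1), "query_expr")))
    stop("operands must be query expressions")
  structure(list(type = "op", op = op, operands = operands),
            class = c("query_op", "query_expr"))
}

#' @param n referenced line number.
#' @rdname term_node
#' @export
line_ref <- function(n) {
  stopifnot(is_count(n), n >= 1)
  structure(list(type = "ref", n = as.integer(n)),
            class = c("query_ref", "query_expr"))
}

#' @export
print.query_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- lexer ---------------------------------------------------------------

# token types: lparen rparen ref quoted tag word
lex_query <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "("); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")"); i <- i + 1L; next }
    if (ch == "#") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      if (j == i + 1L) stop("'#' not followed by a line number")
      push("ref", substr(text, i + 1L, j - 1L))
      i <- j; next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") j <- j + 1L
      if (j > n) stop("unbalanced quote")
      push("quoted", substr(text, i + 1L, j - 1L))
      i <- j + 1L; next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced field tag bracket")
      push("tag", tolower(trimws(substr(text, i + 1L, j - 1L))))
      i <- j + 1L; next
    }
    # bare word: up to whitespace or a structural character
    j <- i
    while (j <= n && !grepl("^[\\s()\\[\\]#\"]$", chars[j], perl = TRUE)) j <- j + 1L
    push("word", substr(text, i, j - 1L))
    i <- j
  }
  toks
}

# ---- recursive-descent parser -------------------------------------------

# max_ref: highest line number an embedded #N may refer to (line - 1);
# Inf for stand-alone expressions where refs are disallowed via max_ref = 0.
parse_expr_tokens <- function(toks, max_ref = 0L) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  is_operator <- function(t) !is.null(t) && t$type == "word" &&
    toupper(t$value) %in% c("AND", "OR", "NOT")

  parse_term <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of expression")
    if (t$type == "lparen") {
      advance()
      e <- parse_or()
      t2 <- peek()
      if (is.null(t2) || t2$type != "rparen") stop("unbalanced parenthesis")
      advance()
      return(e)
    }
    if (t$type == "ref") {
      advance()
      nref <- as.integer(t$value)
      if (nref > max_ref)
        stop("line reference #", nref, " to a non-earlier line")
      return(line_ref(nref))
    }
    if (t$type == "quoted") {
      advance()
      tagtok <- peek()
      if (is.null(tagtok) || tagtok$type != "tag")
        stop("quoted term \"", t$value, "\" lacks a field tag")
      advance()
      return(make_tagged_term(t$value, tagtok$value))
    }
    if (t$type == "word") {
      if (is_operator(t)) stop("unexpected operator '", t$value, "'")
      words <- character()
      while (!is.null(peek()) && peek()$type == "word" && !is_operator(peek()))
        words <- c(words, advance()$value)
      tagtok <- peek()
      if (is.null(tagtok) || tagtok$type != "tag")
        stop("term '", paste(words, collapse = " "), "' lacks a field tag")
      advance()
      return(make_tagged_term(paste(words, collapse = " "), tagtok$value))
    }
    stop("unexpected token '", t$value, "'")
  }

  parse_not <- function() {
    left <- parse_term()
    while (is_operator(peek()) && toupper(peek()$value) == "NOT") {
      advance()
      left <- op_node("NOT", list(left, parse_term()))
    }
    left
  }
  parse_and <- function() {
    operands <- list(parse_not())
    while (is_operator(peek()) && toupper(peek()$value) == "AND") {
      advance()
      operands <- c(operands, list(parse_not()))
    }
    if (length(operands) == 1L) operands[[1]] else op_node("AND", operands)
  }
  parse_or <- function() {
    operands <- list(parse_and())
    while (is_operator(peek()) && toupper(peek()$value) == "OR") {
      advance()
      operands <- c(operands, list(parse_and()))
    }
    if (length(operands) == 1L) operands[[1]] else op_node("OR", operands)
  }

  e <- parse_or()
  if (!is.null(peek()))
    stop("trailing input after expression: '", peek()$value, "'")
  e
}

make_tagged_term <- function(text, tag) {
  if (tag %in% c("tiab")) return(term_node(text, "tiab"))
  if (tag %in% c("mh", "mesh")) {
    parts <- trimws(strsplit(text, "/", fixed = TRUE)[[1]])
    if (length(parts) > 2L) stop("at most one subheading per MeSH term: ", text)
    return(term_node(parts[1], "mh",
                     subheading = if (length(parts) == 2L) parts[2]))
  }
  stop("unknown field tag [", tag, "]")
}

#' Parse a stand-alone (single-line) query expression
#'
#' @param text expression text, e.g.
#'   `'(nurse[tiab] OR nurses[tiab]) AND staffing[tiab]'`.
#' @return a `query_expr`.
#' @seealso [parse_strategy()] for the numbered-line dialect.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parse_expr_tokens(lex_query(text), max_ref = 0L)
}

# ---- numbered strategies -------------------------------------------------

#' Parse a numbered-line Boolean search strategy
#'
#' Each non-blank line must be `<number> <expression>`; numbers must run
#' consecutively from 1 and `#N` references may only point at earlier lines.
#' The highest-numbered line is the strategy's result. Parse errors report
#' the offending line number.
#'
#' @param text character scalar (lines separated by newlines) or character
#'   vector of lines.
#' @param name strategy label.
#' @return an object of class `boolean_strategy` with elements `name`,
#'   `lines` (list of `query_expr`) and `result_line`.
#' @export
#' @examples
#' s <- parse_strategy(c("1 nurse[tiab] OR nurses[tiab]",
#'                       "2 staffing[tiab]",
#'                       "3 #1 AND #2"), name = "demo")
#' s$result_line
parse_strategy <- function(text, name = "") {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  text <- text[!grepl("^\\s*$", text)]
  if (!length(text)) stop("empty strategy")
  m <- regmatches(text, regexec("^\\s*([0-9]+)[.)]?\\s+(.*\\S)\\s*$", text))
  bad <- which(vapply(m, length, integer(1)) == 0L)
  if (length(bad))
    stop("line ", bad[1], ": not a '<number> <expression>' line: ", text[bad[1]])
  nums <- as.integer(vapply(m, `[`, "", 2L))
  if (!identical(nums, seq_along(nums)))
    stop("line numbers must be consecutive from 1; got ",
         paste(nums, collapse = ", "))
  exprs <- vector("list", length(nums))
  for (k in seq_along(nums)) {
    exprs[[k]] <- tryCatch(
      parse_expr_tokens(lex_query(m[[k]][3]), max_ref = k - 1L),
      error = function(e) stop("line ", k, ": ", conditionMessage(e), call. = FALSE))
  }
  structure(list(name = as.character(name), lines = exprs,
                 result_line = length(exprs)),
            class = "boolean_strategy")
}

#' Read a strategy file
#'
#' Reads either dialect: if every non-blank line starts with a line number
#' the numbered-line dialect is parsed; otherwise the whole file is treated
#' as one single-line expression.
#'
#' @param file path or connection.
#' @param name strategy label; defaults to the file name without extension.
#' @return a `boolean_strategy`.
#' @export
read_strategy <- function(file, name = NULL) {
  lines <- read_input_lines(file)
  if (is.null(name))
    name <- if (is.character(file)) sub("\\.[^.]*$", "", basename(file)) else ""
  nonblank <- lines[!grepl("^\\s*$", lines)]
  if (!length(nonblank)) stop("empty strategy file")
  if (all(grepl("^\\s*[0-9]+[.)]?\\s", nonblank)))
    return(parse_strategy(nonblank, name = name))
  expr <- parse_query(paste(nonblank, collapse = " "))
  structure(list(name = as.character(name), lines = list(expr), result_line = 1L),
            class = "boolean_strategy")
}

#' @export
print.boolean_strategy <- function(x, ...) {
  if (nzchar(x$name)) cat(x$name, "\n")
  cat(format(x), sep = "\n")
  invisible(x)
}

# ---- serialization -------------------------------------------------------

needs_quotes <- function(text) {
  grepl('[()\\[\\]#"]', text, perl = TRUE) ||
    any(toupper(strsplit(text, " ", fixed = TRUE)[[1]]) %in% c("AND", "OR", "NOT")) ||
    grepl(",", text, fixed = TRUE)
}

#' @export
format.query_expr <- function(x, ...) {
  if (x$type == "ref") return(paste0("#", x$n))
  if (x$type == "term") {
    if (x$field == "mh") {
      body <- paste0(x$text, if (!is.null(x$subheading)) paste0("/", x$subheading))
      return(paste0("\"", body, "\"[mh]"))
    }
    body <- if (needs_quotes(x$text)) paste0("\"", x$text, "\"") else x$text
    return(paste0(body, "[tiab]"))
  }
  parts <- vapply(x$operands, function(o) {
    s <- format(o)
    if (o$type == "op") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", x$op, " "))
}

#' @export
format.boolean_strategy <- function(x, ...) {
  vapply(seq_along(x$lines),
         function(k) paste0(k, "\t", format(x$lines[[k]])),
         character(1))
}

#' Write a strategy in the numbered-line dialect
#'
#' Serializes so that [parse_strategy()] of the output reconstructs an
#' equivalent strategy (identical expression tree).
#'
#' @param strategy a `boolean_strategy`.
#' @param file path or connection; `""` returns the lines.
#' @export
write_strategy <- function(strategy, file = "") {
  stopifnot(inherits(strategy, "boolean_strategy"))
  lines <- format(strategy)
  if (identical(file, "")) return(lines)
  write_output_lines(lines, file)
}

#' Collapse a numbered strategy to a single expression
#'
#' Substitutes every `#N` reference with the (already substituted)
#' expression of line `N`; the result is a stand-alone query semantically
#' equivalent to line-wise execution — the "single-line syntax" of a
#' strategy.
#'
#' @param strategy a `boolean_strategy`.
#' @return a `query_expr` with no line references.
#' @export
compile_single_line <- function(strategy) {
  stopifnot(inherits(strategy, "boolean_strategy"))
  compiled <- vector("list", length(strategy$lines))
  subst <- function(e) {
    if (e$type == "ref") return(compiled[[e$n]])
    if (e$type == "op") {
      e$operands <- lapply(e$operands, subst)
      return(e)
    }
    e
  }
  for (k in seq_along(strategy$lines)) compiled[[k]] <- subst(strategy$lines[[k]])
  compiled[[strategy$result_line]]
}
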