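# Term mining: tokenization, binary term-document matrix, per-term document
# prevalence, and differential-prevalence term selection.

# ordered lowercase token stream; no filtering (used by query matching)
token_stream <- function(text) {
  if (!length(text) || is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

filter_tokens <- function(toks) {
  toks[nchar(toks) > 1L & !grepl("^[0-9]+$", toks)]
}

#' Tokenize a record's title and abstract
#'
#' The free-text term-mining tokenizer: the title and abstract are
#' lowercased and split on every non-alphanumeric character; purely numeric
#' tokens and single-character tokens are dropped. There is no stemming and
#' no stopword list — ubiquitous words are removed downstream by the
#' differential-prevalence filter, and inflectional variants ("nurse",
#' "nurses", "nursing") are deliberately kept as distinct terms because a
#' search strategy must spell each variant out.
#'
#' @param x a [medline_record()] or a character scalar.
#' @return character vector of distinct tokens (a set, in first-occurrence
#'   order).
#' @export
#' @examples
#' tokenize("Nurse-to-patient ratios in 12 ICUs")
tokenize <- function(x) {
  text <- if (inherits(x, "medline_record")) paste(x$title, x$abstract) else x
  stopifnot(is.character(text), length(text) == 1L)
  unique(filter_tokens(token_stream(text)))
}

#' Binary term-document matrix of a corpus
#'
#' Builds a sparse binary matrix with one row per distinct token and one
#' column per record; entry 1 means the term occurs at least once in the
#' record's title or abstract (see [tokenize()]). Document frequency — not
#' within-document counts — is what term prevalence and selection use, so
#' presence suffices.
#'
#' @param corpus a non-empty [medline_corpus()].
#' @return a sparse [Matrix::sparseMatrix()] (binary, class `dgCMatrix`) with
#'   terms as rownames (sorted) and PMIDs as colnames.
#' @export
build_tdm <- function(corpus) {
  stopifnot(inherits(corpus, "medline_corpus"))
  if (!length(corpus)) stop("cannot build a term-document matrix from an empty corpus")
  texts <- vapply(corpus$records, function(r) paste(r$title, r$abstract), character(1))
  raw <- strsplit(tolower(texts), "[^a-z0-9]+")
  j <- rep.int(seq_along(raw), lengths(raw))
  tok <- unlist(raw, use.names = FALSE)
  keep <- nchar(tok) > 1L & !grepl("^[0-9]+$", tok)
  tok <- tok[keep]
  j <- j[keep]
  terms <- sort(unique(tok))
  i <- match(tok, terms)
  first <- !duplicated((j - 1) * length(terms) + i)  # presence, not counts
  i <- i[first]
  j <- j[first]
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(terms), length(corpus)),
                       dimnames = list(terms, pmids(corpus)))
}

is_tdm <- function(x) {
  (methods::is(x, "Matrix") || is.matrix(x)) &&
    !is.null(rownames(x)) && !is.null(colnames(x))
}

#' Export a term-document matrix as sparse triplets
#'
#' Writes one `term<TAB>pmid<TAB>1` line per nonzero entry.
#'
#' @param tdm a [build_tdm()] result.
#' @param file path or connection; `""` returns the lines.
#' @export
write_tdm <- function(tdm, file = "") {
  stopifnot(is_tdm(tdm))
  tr <- Matrix::summary(methods::as(tdm, "TsparseMatrix"))
  lines <- sprintf("%s\t%s\t1", rownames(tdm)[tr$i], colnames(tdm)[tr$j])
  if (identical(file, "")) return(lines)
  write_output_lines(lines, file)
}

#' Per-term document prevalence
#'
#' For every term of a term-document matrix, the number of documents
#' containing it and the fraction of the corpus that number represents.
#' Prevalences are stored at full precision; reports round to 2 decimals
#' (see [format_prevalence()]).
#'
#' @param tdm a [build_tdm()] result.
#' @return data.frame with columns `term`, `doc_count`, `n_docs`,
#'   `prevalence`, one row per term.
#' @export
term_prevalence <- function(tdm) {
  stopifnot(is_tdm(tdm))
  counts <- Matrix::rowSums(tdm)
  data.frame(term = rownames(tdm),
             doc_count = as.integer(counts),
             n_docs = ncol(tdm),
             prevalence = as.numeric(counts) / ncol(tdm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @param prevalence numeric fraction.
#' @rdname term_prevalence
#' @export
format_prevalence <- function(prevalence) {
  sprintf("%.2f", round_half_up(prevalence, 2))
}

# order by doc_count descending, ties alphabetical ascending
rank_terms <- function(df) df[order(-df$doc_count, df$term), , drop = FALSE]

#' Candidate terms by development-set prevalence
#'
#' Terms present in at least `min_dev_prevalence` of the development set
#' (inclusive threshold) are candidates for a search strategy.
#'
#' @param dev_prev [term_prevalence()] table of the development corpus.
#' @param min_dev_prevalence inclusive lower bound, default 0.05.
#' @return character vector of candidate terms, ranked by development
#'   document count (descending, ties alphabetical).
#' @export
candidate_terms <- function(dev_prev, min_dev_prevalence = 0.05) {
  stopifnot(is.data.frame(dev_prev), min_dev_prevalence >= 0, min_dev_prevalence <= 1)
  keep <- dev_prev[dev_prev$prevalence >= min_dev_prevalence, , drop = FALSE]
  rank_terms(keep)$term
}

#' Select over-represented terms
#'
#' The core term-selection rule of empirical filter development: among the
#' development-set candidates (prevalence `>= min_dev_prevalence`), keep the
#' terms whose prevalence in the random population sample is
#' `<= max_pop_prevalence` (terms never seen in the population sample count
#' as prevalence 0 and are eligible), rank them by development-set document
#' count descending (ties alphabetical), and return the first `top_k`.
#'
#' @param dev_prev,pop_prev [term_prevalence()] tables of the development and
#'   population corpora, computed with identical tokenization.
#' @param min_dev_prevalence inclusive development-set threshold (default
#'   0.05, i.e. "at least five percent").
#' @param max_pop_prevalence inclusive population-set ceiling (default 0.02,
#'   i.e. "2% or fewer").
#' @param top_k maximum number of terms returned (default 25).
#' @return data.frame with columns `rank`, `term`, `dev_count`,
#'   `dev_prevalence`, `pop_count`, `pop_prevalence`.
#' @export
select_overrepresented <- function(dev_prev, pop_prev,
                                   min_dev_prevalence = 0.05,
                                   max_pop_prevalence = 0.02,
                                   top_k = 25) {
  stopifnot(is.data.frame(dev_prev), is.data.frame(pop_prev),
            is_count(top_k), top_k >= 1,
            max_pop_prevalence >= 0, max_pop_prevalence <= 1)
  cand <- dev_prev[dev_prev$prevalence >= min_dev_prevalence, , drop = FALSE]
  m <- match(cand$term, pop_prev$term)
  pop_count <- ifelse(is.na(m), 0L, pop_prev$doc_count[m])
  pop_prevalence <- ifelse(is.na(m), 0, pop_prev$prevalence[m])
  sel <- data.frame(term = cand$term,
                    dev_count = cand$doc_count,
                    dev_prevalence = cand$prevalence,
                    pop_count = as.integer(pop_count),
                    pop_prevalence = pop_prevalence,
                    stringsAsFactors = FALSE)
  sel <- sel[sel$pop_prevalence <= max_pop_prevalence, , drop = FALSE]
  sel <- sel[order(-sel$dev_count, sel$term), , drop = FALSE]
  sel <- utils::head(sel, top_k)
  if (nrow(sel)) sel <- cbind(rank = seq_len(nrow(sel)), sel)
  else sel <- cbind(rank = integer(), sel)
  rownames(sel) <- NULL
  sel
}

#' MeSH descriptor frequency ranking
#'
#' Ranks descriptors by the number of records carrying them (subheadings are
#' ignored for counting), descending with alphabetical tie-break. The final
#' judgement of which frequent headings are relevant to the topic is a human
#' step: this function only supplies the ranked list for curation.
#'
#' @param corpus a [medline_corpus()].
#' @return data.frame with columns `descriptor`, `doc_count`, ranked.
#' @export
mesh_frequency <- function(corpus) {
  stopifnot(inherits(corpus, "medline_corpus"))
  per_rec <- lapply(corpus$records, function(r)
    unique(vapply(r$mesh, function(h) h$descriptor, character(1))))
  all_desc <- unlist(per_rec, use.names = FALSE)
  if (!length(all_desc))
    return(data.frame(descriptor = character(), doc_count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(all_desc)
  df <- data.frame(descriptor = names(tab), doc_count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$doc_count, df$descriptor), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Combined term-prevalence report
#'
#' A side-by-side development/population prevalence table for all
#' development-set candidate terms, flagging the selected over-represented
#' terms — the layout used to report a filter's empirical term basis.
#'
#' @inheritParams select_overrepresented
#' @return data.frame with columns `term`, `dev_count`, `dev_prevalence`,
#'   `pop_count`, `pop_prevalence`, `selected`; prevalences rounded to 2
#'   decimals for reporting.
#' @export
term_report <- function(dev_prev, pop_prev,
                        min_dev_prevalence = 0.05,
                        max_pop_prevalence = 0.02,
                        top_k = 25) {
  sel <- select_overrepresented(dev_prev, pop_prev, min_dev_prevalence,
                                max_pop_prevalence, top_k)
  cand <- dev_prev[dev_prev$prevalence >= min_dev_prevalence, , drop = FALSE]
  cand <- rank_terms(cand)
  m <- match(cand$term, pop_prev$term)
  out <- data.frame(term = cand$term,
                    dev_count = cand$doc_count,
                    dev_prevalence = round_half_up(cand$prevalence, 2),
                    pop_count = as.integer(ifelse(is.na(m), 0L, pop_prev$doc_count[m])),
                    pop_prevalence = round_half_up(ifelse(is.na(m), 0, pop_prev$prevalence[m]), 2),
                    selected = cand$term %in% sel$term,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @param report a [term_report()] data.frame.
#' @param file path or connection; `""` returns the lines.
#' @rdname term_report
#' @export
write_term_report <- function(report, file = "") {
  lines <- c(paste(names(report), collapse = "\t"),
             paste(report$term, report$dev_count,
                   sprintf("%.2f", report$dev_prevalence),
                   report$pop_count,
                   sprintf("%.2f", report$pop_prevalence),
                   as.integer(report$selected), sep = "\t"))
  if (identical(file, "")) return(lines)
  write_output_lines(lines, file)
}
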