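# Seeded generator of labelled MEDLINE-like corpora with controlled
# per-term and per-heading document prevalences. Every profiled term is an
# independent Bernoulli inclusion per record, conditional on the record's
# class (relevant vs background); filler tokens from a disjoint nonsense
# vocabulary pad abstracts to a configured length. This is deliberately a
# bag-of-words caricature of bibliographic text — sufficient to exercise
# term selection, query execution and evaluation, not to imitate prose.

#' Specification of a synthetic labelled corpus
#'
#' @param n_relevant,n_background number of records in the relevant class
#'   (the gold standard) and the background class.
#' @param term_profile data.frame with columns `term`, `p_relevant`,
#'   `p_background`: per-document inclusion probabilities of each profiled
#'   term, by class.
#' @param mesh_profile data.frame (possibly empty) with columns
#'   `descriptor`, `p_relevant`, `p_background`, `subheading` (`NA` for
#'   none), `p_subheading` (probability that an assigned heading carries
#'   the subheading).
#' @param filler_vocab_size number of distinct filler tokens; the filler
#'   vocabulary is enumerated deterministically and must be disjoint from
#'   the profiled terms.
#' @param tokens_per_abstract integer `c(min, max)`: abstract length drawn
#'   uniformly in this range.
#' @param title_term_prob probability that a profiled term present in a
#'   record also appears in its title (so title-vs-abstract matching is
#'   exercised); presence itself is decided by the abstract inclusion.
#' @param year_range inclusive publication-year range, uniform per record.
#' @param seed default seed used by [generate_corpus()].
#' @return object of class `corpus_spec`.
#' @seealso [generate_corpus()], [nurse_staffing_spec()]
#' @export
corpus_spec <- function(n_relevant, n_background, term_profile,
                        mesh_profile = empty_mesh_profile(),
                        filler_vocab_size = 2000,
                        tokens_per_abstract = c(80L, 200L),
                        title_term_prob = 0.3,
                        year_range = c(1982L, 2006L),
                        seed = NULL) {
  stopifnot(is_count(n_relevant), is_count(n_background),
            is.data.frame(term_profile),
            all(c("term", "p_relevant", "p_background") %in% names(term_profile)),
            is.data.frame(mesh_profile),
            is_count(filler_vocab_size),
            length(tokens_per_abstract) == 2L,
            tokens_per_abstract[1] <= tokens_per_abstract[2],
            title_term_prob >= 0, title_term_prob <= 1,
            length(year_range) == 2L, year_range[1] <= year_range[2])
  probs <- c(term_profile$p_relevant, term_profile$p_background,
             if (nrow(mesh_profile)) c(mesh_profile$p_relevant, mesh_profile$p_background))
  if (any(probs < 0 | probs > 1)) stop("prevalences must lie in [0, 1]")
  if (anyDuplicated(term_profile$term)) stop("duplicate profiled term")
  structure(list(n_relevant = as.integer(n_relevant),
                 n_background = as.integer(n_background),
                 term_profile = term_profile,
                 mesh_profile = mesh_profile,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 tokens_per_abstract = as.integer(tokens_per_abstract),
                 title_term_prob = title_term_prob,
                 year_range = as.integer(year_range),
                 seed = seed),
            class = "corpus_spec")
}

empty_mesh_profile <- function() {
  data.frame(descriptor = character(), p_relevant = numeric(),
             p_background = numeric(), subheading = character(),
             p_subheading = numeric(), stringsAsFactors = FALSE)
}

# deterministic pronounceable nonsense vocabulary: 2- then 3-syllable
# consonant-vowel words ("baba", "babe", ...), disjoint from real terms by
# construction and verified against the profile at generation time
make_filler_vocab <- function(size) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  two <- as.vector(outer(syl, syl, paste0))
  if (size <= length(two)) return(two[seq_len(size)])
  three <- as.vector(outer(two, syl, paste0))
  if (size > length(two) + length(three)) stop("filler vocabulary too large")
  c(two, three[seq_len(size - length(two))])
}

#' Generate a labelled synthetic corpus
#'
#' Draws every profiled term/heading independently per record with its
#' class-conditional probability, pads abstracts with filler tokens, and
#' assigns uniform publication years. The first `n_relevant` PMIDs form the
#' gold-standard relevant set. Identical seeds give bit-identical corpora;
#' the caller's RNG state is untouched.
#'
#' @param spec a [corpus_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return object of class `labelled_corpus`: a list with `corpus` (a
#'   [medline_corpus()]) and `relevant_ids`.
#' @export
generate_corpus <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- make_filler_vocab(spec$filler_vocab_size)
  clash <- intersect(tolower(spec$term_profile$term), vocab)
  if (length(clash))
    stop("profiled terms overlap the filler vocabulary: ",
         paste(utils::head(clash, 3), collapse = ", "))
  with_seed_(seed, {
    rel <- generate_class(spec, class = "relevant", vocab = vocab, id_offset = 0L)
    bg <- generate_class(spec, class = "background", vocab = vocab,
                         id_offset = spec$n_relevant)
    corpus <- medline_corpus(c(rel, bg), label = "synthetic")
    structure(list(corpus = corpus,
                   relevant_ids = vapply(rel, function(r) r$pmid, character(1))),
              class = "labelled_corpus")
  })
}

#' @export
print.labelled_corpus <- function(x, ...) {
  cat(sprintf("<labelled_corpus: %d records, %d relevant>\n",
              length(x$corpus), length(x$relevant_ids)))
  invisible(x)
}

generate_class <- function(spec, class, vocab, id_offset) {
  n <- if (class == "relevant") spec$n_relevant else spec$n_background
  if (n == 0L) return(list())
  tp <- spec$term_profile
  p <- if (class == "relevant") tp$p_relevant else tp$p_background
  K <- nrow(tp)
  pres <- matrix(stats::runif(n * K), n, K) < rep(p, each = n)
  in_title <- pres & (matrix(stats::runif(n * K), n, K) < spec$title_term_prob)

  lens <- sample(seq(spec$tokens_per_abstract[1], spec$tokens_per_abstract[2]),
                 n, replace = TRUE)
  filler <- split(vocab[sample.int(length(vocab), sum(lens), replace = TRUE)],
                  rep.int(seq_len(n), lens))
  tlens <- sample(3:6, n, replace = TRUE)
  tfiller <- split(vocab[sample.int(length(vocab), sum(tlens), replace = TRUE)],
                   rep.int(seq_len(n), tlens))

  mp <- spec$mesh_profile
  mesh_pres <- NULL
  mesh_sub <- NULL
  if (nrow(mp)) {
    mq <- if (class == "relevant") mp$p_relevant else mp$p_background
    M <- nrow(mp)
    mesh_pres <- matrix(stats::runif(n * M), n, M) < rep(mq, each = n)
    mesh_sub <- matrix(stats::runif(n * M), n, M) < rep(mp$p_subheading, each = n)
  }

  years <- sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)

  lapply(seq_len(n), function(i) {
    ab <- sample(c(tp$term[pres[i, ]], filler[[i]]))
    ti <- sample(c(tp$term[in_title[i, ]], tfiller[[i]]))
    mesh <- list()
    if (!is.null(mesh_pres)) {
      for (m in which(mesh_pres[i, ])) {
        sub <- if (!is.na(mp$subheading[m]) && mesh_sub[i, m]) mp$subheading[m]
        mesh[[length(mesh) + 1L]] <-
          mesh_heading(mp$descriptor[m],
                       subheadings = if (is.null(sub)) character() else sub)
      }
    }
    medline_record(pmid = as.character(id_offset + i),
                   title = paste(ti, collapse = " "),
                   abstract = paste(ab, collapse = " "),
                   mesh = mesh,
                   pub_year = years[i],
                   journal = if (class == "relevant") "Synthetic Journal of Staffing"
                             else "Synthetic Background Journal")
  })
}

# ---- spec files ----------------------------------------------------------

#' Read a corpus spec from a YAML file
#'
#' Layout: scalar fields as in [corpus_spec()]; profiled terms under `terms`
#' as `term: {relevant: p, background: p}`; headings under `mesh` as a list
#' of `{descriptor, relevant, background, subheading, p_subheading}`
#' entries.
#'
#' @param file path to a YAML file.
#' @return a [corpus_spec()].
#' @export
read_corpus_spec <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$terms) || !length(y$terms)) stop("spec has no 'terms' table")
  tp <- data.frame(term = names(y$terms),
                   p_relevant = vapply(y$terms, function(t) as.numeric(t$relevant), numeric(1)),
                   p_background = vapply(y$terms, function(t) as.numeric(t$background), numeric(1)),
                   stringsAsFactors = FALSE)
  mp <- empty_mesh_profile()
  if (length(y$mesh)) {
    mp <- do.call(rbind, lapply(y$mesh, function(m) data.frame(
      descriptor = m$descriptor,
      p_relevant = as.numeric(m$relevant),
      p_background = as.numeric(m$background),
      subheading = if (is.null(m$subheading)) NA_character_ else m$subheading,
      p_subheading = if (is.null(m$p_subheading)) 0 else as.numeric(m$p_subheading),
      stringsAsFactors = FALSE)))
  }
  corpus_spec(
    n_relevant = y$n_relevant, n_background = y$n_background,
    term_profile = tp, mesh_profile = mp,
    filler_vocab_size = y$filler_vocab_size %||% 2000,
    tokens_per_abstract = unlist(y$tokens_per_abstract %||% c(80L, 200L)),
    title_term_prob = y$title_term_prob %||% 0.3,
    year_range = unlist(y$year_range %||% c(1982L, 2006L)),
    seed = y$seed)
}
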