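# Shared fixtures and independent oracles. The oracles deliberately use a
# different mechanism than the engine: per-record recursive truth evaluation
# with padded-string phrase search, instead of vectorized set masks.

QUERY_VOCAB <- c("alpha", "bravo", "charlie", "delta", "echo", "foxtrot",
                 "golf", "hotel", "india", "juliet", "kilo", "lima", "mike",
                 "november", "oscar", "papa", "quebec", "romeo", "sierra",
                 "tango")
MESH_VOCAB <- c("Nursing Staff, Hospital", "Hospital Units",
                "Intensive Care Units", "Outcome Assessment")

random_query_corpus <- function(n = 100) {
  records <- lapply(seq_len(n), function(i) {
    title <- paste(sample(QUERY_VOCAB, sample(2:5, 1), replace = TRUE),
                   collapse = " ")
    abstract <- if (stats::runif(1) < 0.9)
      paste(sample(QUERY_VOCAB, sample(5:15, 1), replace = TRUE), collapse = " ")
    else ""
    mesh <- lapply(sample(MESH_VOCAB, sample(0:2, 1)), function(d)
      mesh_heading(d, subheadings = if (stats::runif(1) < 0.4) "manpower"
                                    else character()))
    medline_record(as.character(i), title = title, abstract = abstract,
                   mesh = mesh, pub_year = sample(1980:2010, 1))
  })
  medline_corpus(records)
}

# records with messy-but-legal field values for round-trip testing
random_medline_corpus <- function(n = 20) {
  words <- c("Nurse", "staffing", "outcomes,", "hospital-wide", "ratios:",
             "care", "units", "(mix)", "skill", "12-bed")
  records <- lapply(seq_len(n), function(i) {
    mesh <- lapply(seq_len(sample(0:3, 1)), function(k)
      mesh_heading(sample(MESH_VOCAB, 1),
                   subheadings = sample(c("manpower", "organization & administration"),
                                        sample(0:2, 1)),
                   major_topic = stats::runif(1) < 0.3))
    medline_record(
      pmid = as.character(1000 + i),
      title = paste(sample(words, sample(3:6, 1), replace = TRUE), collapse = " "),
      abstract = if (stats::runif(1) < 0.7)
        paste(sample(words, sample(8:20, 1), replace = TRUE), collapse = " ") else "",
      mesh = mesh,
      pub_year = if (stats::runif(1) < 0.8) sample(1960:2010, 1) else NA,
      journal = if (stats::runif(1) < 0.5) "J Test Fixtures" else NA)
  })
  medline_corpus(records, label = "roundtrip")
}

random_term_node_ <- function() {
  u <- stats::runif(1)
  if (u < 0.15) {
    term_node(sample(MESH_VOCAB, 1), "mh",
              subheading = if (stats::runif(1) < 0.3) "manpower")
  } else if (u < 0.30) {
    term_node(paste(sample(QUERY_VOCAB, 2), collapse = " "), "tiab")
  } else {
    term_node(sample(QUERY_VOCAB, 1), "tiab")
  }
}

random_expr <- function(depth = 2, max_ref = 0) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    if (max_ref > 0 && stats::runif(1) < 0.3)
      return(line_ref(sample.int(max_ref, 1)))
    return(random_term_node_())
  }
  op <- sample(c("OR", "AND", "NOT"), 1, prob = c(0.45, 0.35, 0.2))
  k <- if (op == "NOT") 2L else sample(2:3, 1)
  op_node(op, lapply(seq_len(k), function(...) random_expr(depth - 1, max_ref)))
}

random_strategy <- function(n_lines = sample(2:5, 1)) {
  lines <- lapply(seq_len(n_lines), function(k)
    random_expr(depth = 2, max_ref = k - 1L))
  structure(list(name = "random", lines = lines, result_line = n_lines),
            class = "boolean_strategy")
}

# ---- independent per-record truth-evaluation oracle ---------------------

oracle_tokens <- function(text) {
  t <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  t[nzchar(t)]
}

oracle_text_match <- function(text, phrase) {
  padded <- paste0(" ", paste(oracle_tokens(text), collapse = " "), " ")
  grepl(paste0(" ", phrase, " "), padded, fixed = TRUE)
}

oracle_match_record <- function(expr, record, lines = NULL) {
  switch(expr$type,
    term = if (expr$field == "tiab") {
      phrase <- paste(oracle_tokens(expr$text), collapse = " ")
      oracle_text_match(record$title, phrase) ||
        oracle_text_match(record$abstract, phrase)
    } else {
      any(vapply(record$mesh, function(h) {
        tolower(h$descriptor) == tolower(expr$text) &&
          (is.null(expr$subheading) ||
             tolower(expr$subheading) %in% tolower(h$subheadings))
      }, logical(1)))
    },
    ref = oracle_match_record(lines[[expr$n]], record, lines),
    op = {
      vals <- vapply(expr$operands, oracle_match_record, logical(1),
                     record = record, lines = lines)
      switch(expr$op, OR = any(vals), AND = all(vals),
             NOT = vals[1] && !vals[2])
    })
}

oracle_execute <- function(strategy, corpus) {
  result <- strategy$lines[[strategy$result_line]]
  keep <- vapply(corpus$records, function(r)
    oracle_match_record(result, r, strategy$lines), logical(1))
  pmids(corpus)[keep]
}

# small hand-built MeSH tree: Personnel Staffing and Scheduling with one
# child and one grandchild descriptor
fixture_mesh_tree <- function() {
  mesh_tree(
    tree_number = c("N02.350", "N02.350.300", "N02.350.300.100", "N04.590"),
    descriptor = c("Personnel Staffing and Scheduling",
                   "Nurse Staffing Ratios",
                   "Mandated Staffing Ratios",
                   "Outcome Assessment"))
}
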