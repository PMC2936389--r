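small_profile <- function() {
  data.frame(term = c("staffing", "nurse", "outcomes"),
             p_relevant = c(0.6, 0.8, 0.4),
             p_background = c(0.01, 0.05, 0.1))
}

test_that("generation is bit-identical under a fixed seed and varies across seeds", {
  spec <- corpus_spec(30, 50, small_profile(), tokens_per_abstract = c(10L, 20L))
  a <- generate_corpus(spec, seed = 5)
  b <- generate_corpus(spec, seed = 5)
  c <- generate_corpus(spec, seed = 6)
  expect_identical(a$corpus$records, b$corpus$records)
  expect_identical(a$relevant_ids, b$relevant_ids)
  expect_false(identical(a$corpus$records, c$corpus$records))
  expect_equal(length(a$relevant_ids), 30L)
  expect_true(all(a$relevant_ids %in% pmids(a$corpus)))
  expect_equal(length(a$corpus), 80L)
})

test_that("deterministic and degenerate prevalences are honoured exactly", {
  prof <- data.frame(term = c("always", "never"),
                     p_relevant = c(1, 0), p_background = c(0, 1))
  lc <- generate_corpus(corpus_spec(25, 25, prof,
                                    tokens_per_abstract = c(5L, 10L)), seed = 2)
  prev_rel <- term_prevalence(build_tdm(lc$corpus[1:25]))
  prev_bg <- term_prevalence(build_tdm(lc$corpus[26:50]))
  expect_equal(prev_rel$prevalence[prev_rel$term == "always"], 1)
  expect_false("never" %in% prev_rel$term)
  expect_equal(prev_bg$prevalence[prev_bg$term == "never"], 1)
  expect_false("always" %in% prev_bg$term)
})

test_that("an all-empty spec produces an empty labelled corpus", {
  lc <- generate_corpus(corpus_spec(0, 0, small_profile()), seed = 1)
  expect_equal(length(lc$corpus), 0L)
  expect_equal(length(lc$relevant_ids), 0L)
})

test_that("profiled terms colliding with the filler vocabulary are rejected", {
  prof <- data.frame(term = c("staffing", "baba"),
                     p_relevant = c(0.5, 0.5), p_background = c(0, 0))
  expect_error(generate_corpus(corpus_spec(5, 5, prof), seed = 1),
               "filler vocabulary")
  expect_error(corpus_spec(5, 5, data.frame(term = "x", p_relevant = 1.2,
                                            p_background = 0)),
               "\\[0, 1\\]")
})

test_that("empirical prevalences track the generating probabilities within 3 binomial SEs", {
  spec <- nurse_staffing_spec()
  checks <- 0L
  ok <- 0L
  for (seed in 1:5) {
    lc <- generate_corpus(spec, seed = seed)
    dev <- term_prevalence(build_tdm(lc$corpus[seq_len(78)]))
    pop <- term_prevalence(build_tdm(lc$corpus[79:length(lc$corpus)]))
    for (i in seq_len(nrow(spec$term_profile))) {
      tm <- spec$term_profile$term[i]
      for (side in c("dev", "pop")) {
        p <- if (side == "dev") spec$term_profile$p_relevant[i]
             else spec$term_profile$p_background[i]
        n <- if (side == "dev") 78 else 10000
        tab <- if (side == "dev") dev else pop
        obs <- if (tm %in% tab$term) tab$prevalence[tab$term == tm] else 0
        se <- sqrt(p * (1 - p) / n)
        checks <- checks + 1L
        if (abs(obs - p) <= 3 * se) ok <- ok + 1L
      }
    }
  }
  expect_gte(ok / checks, 0.99)
})

test_that("profiled terms are conditionally independent within a class", {
  prof <- data.frame(term = paste0("term", letters[1:5]),
                     p_relevant = rep(0.3, 5), p_background = rep(0.3, 5))
  lc <- generate_corpus(corpus_spec(400, 0, prof,
                                    tokens_per_abstract = c(10L, 20L)), seed = 9)
  tdm <- build_tdm(lc$corpus)
  pres <- t(as.matrix(tdm[prof$term, ]))
  cors <- cor(pres)
  off <- cors[upper.tri(cors)]
  expect_lt(abs(mean(off)), 0.05)
  expect_lt(max(abs(off)), 0.2)
})

test_that("an OR of differential terms reaches its analytic sensitivity under independence", {
  spec <- nurse_staffing_spec(n_background = 100)
  lc <- generate_corpus(spec, seed = 13)
  top5 <- spec$term_profile[order(-spec$term_profile$p_relevant), ][1:5, ]
  q <- op_node("OR", lapply(top5$term, term_node, field = "tiab"))
  rep <- evaluate_strategy(q, lc$corpus, lc$relevant_ids)
  analytic <- 1 - prod(1 - top5$p_relevant)
  se <- sqrt(analytic * (1 - analytic) / 78)
  expect_lt(abs(rep$sensitivity - analytic), 3 * se)
})

test_that("profiled terms reach titles at the configured rate, never exceeding presence", {
  prof <- data.frame(term = "beacon", p_relevant = 1, p_background = 0)
  always <- generate_corpus(corpus_spec(60, 0, prof, title_term_prob = 1,
                                        tokens_per_abstract = c(5L, 8L)), seed = 3)
  in_title <- vapply(always$corpus$records, function(r)
    "beacon" %in% tokenize(r$title), logical(1))
  expect_true(all(in_title))
  never <- generate_corpus(corpus_spec(60, 0, prof, title_term_prob = 0,
                                       tokens_per_abstract = c(5L, 8L)), seed = 3)
  in_title <- vapply(never$corpus$records, function(r)
    "beacon" %in% tokenize(r$title), logical(1))
  in_abstract <- vapply(never$corpus$records, function(r)
    "beacon" %in% tokenize(r$abstract), logical(1))
  expect_false(any(in_title))
  expect_true(all(in_abstract))
})

test_that("MeSH profiles assign descriptors and subheadings class-conditionally", {
  mp <- data.frame(descriptor = c("Nursing Staff, Hospital", "Intensive Care Units"),
                   p_relevant = c(1, 1), p_background = c(0, 0),
                   subheading = c(NA, "manpower"), p_subheading = c(0, 1))
  lc <- generate_corpus(corpus_spec(20, 20, small_profile(), mesh_profile = mp,
                                    tokens_per_abstract = c(5L, 8L)), seed = 4)
  rel <- lc$corpus[seq_len(20)]
  bg <- lc$corpus[21:40]
  expect_true(all(vapply(rel$records, match_mesh, logical(1),
                         descriptor = "Nursing Staff, Hospital")))
  expect_true(all(vapply(rel$records, match_mesh, logical(1),
                         descriptor = "Intensive Care Units",
                         subheading = "manpower")))
  expect_false(any(vapply(bg$records, match_mesh, logical(1),
                          descriptor = "Nursing Staff, Hospital")))
})

test_that("years are drawn inside the configured range", {
  lc <- generate_corpus(corpus_spec(40, 40, small_profile(),
                                    year_range = c(1990L, 1995L),
                                    tokens_per_abstract = c(5L, 8L)), seed = 8)
  yrs <- vapply(lc$corpus$records, `[[`, integer(1), "pub_year")
  expect_true(all(yrs >= 1990 & yrs <= 1995))
  expect_identical(filter_by_year(lc$corpus, 1990, 1995)$records, lc$corpus$records)
})

test_that("YAML corpus specs round-trip into equivalent generators", {
  yaml_text <- c(
    "n_relevant: 10",
    "n_background: 15",
    "seed: 77",
    "tokens_per_abstract: [5, 10]",
    "year_range: [1982, 2006]",
    "terms:",
    "  staffing: {relevant: 0.9, background: 0.02}",
    "  nurse: {relevant: 0.7, background: 0.05}",
    "mesh:",
    "  - descriptor: Hospital Units",
    "    relevant: 0.5",
    "    background: 0.01",
    "    subheading: manpower",
    "    p_subheading: 0.5")
  tmp <- withr::local_tempfile(lines = yaml_text)
  spec <- read_corpus_spec(tmp)
  expect_s3_class(spec, "corpus_spec")
  expect_equal(spec$n_relevant, 10L)
  expect_equal(spec$term_profile$p_relevant[spec$term_profile$term == "staffing"], 0.9)
  expect_equal(spec$mesh_profile$subheading, "manpower")
  lc <- generate_corpus(spec)  # uses the spec's own seed
  expect_identical(lc$corpus$records, generate_corpus(spec, seed = 77)$corpus$records)
  tmp_bad <- withr::local_tempfile(lines = c("n_relevant: 1", "n_background: 1"))
  expect_error(read_corpus_spec(tmp_bad), "terms")
})

test_that("the bundled case-study spec carries the published prevalence profile", {
  spec <- nurse_staffing_spec()
  expect_true(all(nurse_staffing_terms()$term %in% spec$term_profile$term))
  # plus the two documented frequent-but-unspecific words
  expect_setequal(setdiff(spec$term_profile$term, nurse_staffing_terms()$term),
                  c("patients", "outcomes"))
  expect_equal(spec$term_profile$p_background[spec$term_profile$term == "patients"],
               0.77)
  expect_equal(spec$n_relevant, 78L)
  expect_equal(spec$n_background, 10000L)
  expect_equal(spec$term_profile$p_relevant[spec$term_profile$term == "staffing"],
               49 / 78)
  expect_equal(spec$term_profile$p_background[spec$term_profile$term == "staffing"],
               10 / 10000)
})
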