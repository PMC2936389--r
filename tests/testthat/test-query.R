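test_that("the bundled strategies parse with their documented structure", {
  sens <- nurse_staffing_strategy("sensitive")
  prec <- nurse_staffing_strategy("precise")
  bal <- nurse_staffing_strategy("balanced")
  expect_equal(length(sens$lines), 11L)
  expect_equal(length(prec$lines), 10L)
  expect_equal(length(bal$lines), 8L)
  expect_equal(sens$result_line, 11L)

  # sensitive line 4: MeSH descriptor with subheading
  l4 <- sens$lines[[4]]
  expect_s3_class(l4, "query_term")
  expect_equal(l4$field, "mh")
  expect_equal(l4$text, "Intensive Care Units")
  expect_equal(l4$subheading, "manpower")

  # sensitive line 1 contains unquoted multi-word [tiab] phrases
  l1_terms <- vapply(sens$lines[[1]]$operands, `[[`, "", "text")
  expect_true(all(c("skill mix", "length of stay") %in% l1_terms))

  # balanced line 5: (nurse OR nurses) AND staffing
  l5 <- bal$lines[[5]]
  expect_equal(l5$op, "AND")
  expect_equal(l5$operands[[1]]$op, "OR")
  expect_equal(vapply(l5$operands[[1]]$operands, `[[`, "", "text"),
               c("nurse", "nurses"))
  expect_equal(l5$operands[[2]]$text, "staffing")

  # precise line 5 uses a lowercase 'or' operator
  expect_equal(prec$lines[[5]]$op, "OR")
})

test_that("parse errors carry line numbers and reject malformed strategies", {
  expect_error(parse_strategy(c("1 a[tiab]", "2 b[tiab]", "3 #9")),
               "line 3.*#9")
  expect_error(parse_strategy(c("1 a[tiab]", "2 #2")), "line 2")  # self-reference
  expect_error(parse_strategy("1 term[foo]"), "unknown field tag")
  expect_error(parse_strategy('1 "unbalanced[mh]'), "quote")
  expect_error(parse_strategy("1 (a[tiab] OR b[tiab]"), "parenthesis")
  expect_error(parse_strategy(c("1 a[tiab]", "3 b[tiab]")), "consecutive")
  expect_error(parse_strategy("1 naked term"), "field tag")
  expect_error(parse_strategy("1 a[tiab] OR"), "unexpected end")
})

test_that("field tags are case-insensitive", {
  s <- parse_strategy(c('1 staffing[TIAB]', '2 "Hospital Units"[MH]', "3 #1 OR #2"))
  expect_equal(s$lines[[1]]$field, "tiab")
  expect_equal(s$lines[[2]]$field, "mh")
})

test_that("serialization round-trips bundled and random strategies", {
  for (nm in c("sensitive", "precise", "balanced")) {
    s <- nurse_staffing_strategy(nm)
    back <- parse_strategy(write_strategy(s), name = nm)
    expect_identical(back$lines, s$lines)
  }
  set.seed(21)
  for (k in 1:25) {
    s <- random_strategy()
    back <- parse_strategy(write_strategy(s), name = "random")
    expect_identical(back$lines, s$lines)
  }
})

test_that("single-line compilation substitutes references and preserves retrieval", {
  one <- parse_strategy("1 nurse[tiab]")
  expect_identical(compile_single_line(one), one$lines[[1]])

  s <- parse_strategy(c("1 alpha[tiab]", "2 bravo[tiab]", "3 #1 OR #2"))
  ex <- compile_single_line(s)
  expect_equal(ex$op, "OR")
  expect_equal(vapply(ex$operands, `[[`, "", "text"), c("alpha", "bravo"))

  set.seed(31)
  for (k in 1:50) {
    corp <- random_query_corpus(n = 40)
    s <- random_strategy()
    expect_identical(execute_strategy(compile_single_line(s), corp),
                     execute_strategy(s, corp))
  }
})

test_that("[tiab] matching is exact-token with consecutive phrases inside one field", {
  rec <- medline_record("1", title = "Hospital nurse staffing levels",
                        abstract = "The skill mix of the unit varied.")
  expect_true(match_tiab(rec, "staffing"))
  expect_false(match_tiab(rec, "staff"))      # no substring/stem matching
  expect_true(match_tiab(rec, "Skill Mix"))   # case-insensitive phrase
  expect_true(match_tiab(rec, "nurse staffing"))
  rec2 <- medline_record("2", abstract = "skill and grade mix")
  expect_false(match_tiab(rec2, "skill mix")) # not adjacent
  rec3 <- medline_record("3", title = "good skill", abstract = "mix here")
  expect_false(match_tiab(rec3, "skill mix")) # never crosses the boundary
})

test_that("[mh] matching honours subheadings and tree explosion", {
  rec <- medline_record("1", mesh = list(
    mesh_heading("Intensive Care Units", subheadings = "manpower"),
    mesh_heading("Nurse Staffing Ratios")))
  expect_true(match_mesh(rec, "intensive care units"))
  expect_true(match_mesh(rec, "Intensive Care Units", subheading = "manpower"))
  expect_false(match_mesh(rec, "Intensive Care Units", subheading = "trends"))
  expect_false(match_mesh(rec, "Personnel Staffing and Scheduling"))

  tree <- fixture_mesh_tree()
  expect_true(match_mesh(rec, "Personnel Staffing and Scheduling",
                         explode = TRUE, tree = tree))  # child matches
  expect_false(match_mesh(rec, "Outcome Assessment", explode = TRUE, tree = tree))
  expect_error(match_mesh(rec, "Personnel Staffing and Scheduling", explode = TRUE),
               "tree")

  rec2 <- medline_record("2", mesh = list(mesh_heading("Mandated Staffing Ratios")))
  expect_true(match_mesh(rec2, "Personnel Staffing and Scheduling",
                         explode = TRUE, tree = tree))  # grandchild
})

test_that("a MeSH tree file reads with and without a header", {
  lines <- c("tree_number\tdescriptor",
             "N02.350\tPersonnel Staffing and Scheduling",
             "N02.350.300\tNurse Staffing Ratios")
  tmp <- withr::local_tempfile(lines = lines)
  tr <- read_mesh_tree(tmp)
  expect_equal(nrow(tr), 2L)
  tmp2 <- withr::local_tempfile(lines = lines[-1])
  expect_equal(nrow(read_mesh_tree(tmp2)), 2L)
  tmp3 <- withr::local_tempfile(lines = "onlyonecolumn")
  expect_error(read_mesh_tree(tmp3), "line 1")
})

test_that("execution follows set semantics on simple corpora", {
  corp <- medline_corpus(list(
    medline_record("1", title = "alpha bravo", pub_year = 1990),
    medline_record("2", title = "bravo charlie", pub_year = 2000),
    medline_record("3", title = "delta", pub_year = 2010)))
  expect_equal(execute_strategy(parse_query("bravo[tiab]"), corp), c("1", "2"))
  expect_equal(execute_strategy(parse_query("alpha[tiab] OR delta[tiab]"), corp),
               c("1", "3"))
  expect_equal(execute_strategy(parse_query("bravo[tiab] NOT alpha[tiab]"), corp),
               "2")
  expect_equal(execute_strategy(parse_query("bravo[tiab] AND charlie[tiab]"), corp),
               "2")
  # precedence: NOT > AND > OR
  expect_equal(execute_strategy(
    parse_query("delta[tiab] OR bravo[tiab] AND charlie[tiab]"), corp),
    c("2", "3"))
  # year limit applies before matching
  expect_equal(execute_strategy(parse_query("bravo[tiab]"), corp,
                                year_range = c(1995, 2006)), "2")
  expect_equal(execute_strategy(parse_query("x[tiab]"), medline_corpus()),
               character())
})

test_that("the engine agrees with the per-record truth-evaluation oracle", {
  set.seed(41)
  for (rep in 1:4) {
    corp <- random_query_corpus(n = 60)
    for (k in 1:50) {
      s <- random_strategy()
      expect_identical(execute_strategy(s, corp), oracle_execute(s, corp))
    }
  }
})

test_that("retrieval is monotone under OR-widening and AND-narrowing", {
  set.seed(51)
  for (k in 1:20) {
    corp <- random_query_corpus(n = 50)
    a <- random_expr(depth = 2)
    b <- random_expr(depth = 1)
    ra <- execute_strategy(a, corp)
    expect_true(all(ra %in% execute_strategy(op_node("OR", list(a, b)), corp)))
    expect_true(all(execute_strategy(op_node("AND", list(a, b)), corp) %in% ra))
    expect_identical(execute_strategy(op_node("OR", list(a, a)), corp), ra)
    expect_identical(execute_strategy(op_node("AND", list(a, a)), corp), ra)
    expect_true(all(ra %in% pmids(corp)))
  }
})

test_that("the run-level explosion default applies to strategies without explicit flags", {
  corp <- medline_corpus(list(
    medline_record("1", mesh = list(mesh_heading("Nurse Staffing Ratios"))),
    medline_record("2", mesh = list(mesh_heading("Personnel Staffing and Scheduling")))))
  q <- parse_query('"Personnel Staffing and Scheduling"[mh]')
  tree <- fixture_mesh_tree()
  expect_equal(execute_strategy(q, corp), "2")
  expect_equal(execute_strategy(q, corp, tree = tree, explode = TRUE), c("1", "2"))
  expect_error(execute_strategy(q, corp, explode = TRUE), "tree")
})
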