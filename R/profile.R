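# Bundled nurse-staffing case study: the empirical term profile and the
# three published-style search strategies that the package's workflow
# produces for this topic. Nurse staffing research (the association between
# nurse-to-patient ratios and nursing/patient outcomes) is the canonical
# hard case for topic filters: methodologically diverse, terminologically
# inconsistent, and poorly served by any single MeSH heading.

#' Nurse-staffing term-prevalence profile
#'
#' The 25 single-word free-text terms most over-represented in nurse
#' staffing research reports relative to MEDLINE at large, with their
#' observed document frequencies in a 78-reference development set of
#' known-relevant papers and a 10,000-record random population sample.
#' `dev_prevalence`/`pop_prevalence` are the 2-decimal reported values;
#' exact fractions are `dev_count/78` and `pop_count/10000`.
#'
#' @return data.frame with columns `term`, `dev_count`, `dev_prevalence`,
#'   `pop_count`, `pop_prevalence`, in over-representation order.
#' @seealso [nurse_staffing_spec()] for the matching synthetic-corpus spec.
#' @export
nurse_staffing_terms <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
term           dev_count dev_prevalence pop_count pop_prevalence
nurse          55        0.71           79        0.01
hospitals      50        0.64           114       0.01
staffing       49        0.63           10        0.00
nursing        45        0.58           186       0.02
nurses         39        0.50           114       0.01
staff          22        0.28           88        0.01
stay           21        0.27           146       0.01
registered     20        0.26           40        0.00
units          20        0.26           173       0.02
mix            17        0.22           17        0.00
relationships  17        0.22           181       0.02
organizational 15        0.19           30        0.00
ratios         16        0.21           173       0.02
odds           16        0.21           189       0.02
intensive      15        0.19           143       0.01
adjusted       14        0.18           175       0.02
teaching       13        0.17           52        0.01
falls          12        0.15           33        0.00
rns            10        0.13           8         0.00
satisfaction   11        0.14           143       0.01
skill          10        0.13           22        0.00
proportion     11        0.14           179       0.02
medicare       10        0.13           57        0.01
multivariate   11        0.14           189       0.02
tract          11        0.14           192       0.02
")
  df
}

#' Synthetic-corpus spec matching the nurse-staffing case study
#'
#' A [corpus_spec()] whose term profile reproduces the observed
#' nurse-staffing prevalences ([nurse_staffing_terms()], as exact fractions
#' of 78 and 10,000) over a 78-record relevant class and a 10,000-record
#' background class. A small MeSH profile covers the descriptors used by
#' the bundled strategies at plausible class-conditional rates, so that
#' `[mh]` lines retrieve sensibly on generated corpora.
#'
#' @param n_relevant,n_background class sizes; defaults 78 and 10,000.
#' @param seed default seed carried by the spec.
#' @return a [corpus_spec()].
#' @export
#' @examples
#' spec <- nurse_staffing_spec(seed = 1)
#' lc <- generate_corpus(spec)
#' lc
nurse_staffing_spec <- function(n_relevant = 78L, n_background = 10000L,
                                seed = NULL) {
  tab <- nurse_staffing_terms()
  term_profile <- data.frame(term = tab$term,
                             p_relevant = tab$dev_count / 78,
                             p_background = tab$pop_count / 10000,
                             stringsAsFactors = FALSE)
  # two frequent-but-unspecific words that real abstracts carry and the
  # differential selection must reject: "patients" at its observed 65%/77%
  # rates, "outcomes" at a comparable split. Without them the bundled
  # precise strategy (which requires outcomes[tiab]) would be degenerate on
  # generated corpora.
  term_profile <- rbind(term_profile,
                        data.frame(term = c("patients", "outcomes"),
                                   p_relevant = c(0.65, 0.70),
                                   p_background = c(0.77, 0.10)))
  mesh_profile <- utils::read.table(header = TRUE, sep = ",", strip.white = TRUE,
                             stringsAsFactors = FALSE, text = "
descriptor, p_relevant, p_background, subheading, p_subheading
Nursing Staff; Hospital, 0.60, 0.005, NA, 0
Personnel Staffing and Scheduling, 0.35, 0.003, NA, 0
Intensive Care Units, 0.15, 0.004, manpower, 0.5
Nursing Administration Research, 0.10, 0.001, NA, 0
Health Services Administration, 0.90, 0.050, NA, 0
Hospital Units, 0.30, 0.004, NA, 0
Outcome and Process Assessment (Health Care), 0.40, 0.010, NA, 0
")
  # commas are field separators above; restore the one descriptor that
  # legitimately contains a comma
  mesh_profile$descriptor <- sub("Nursing Staff; Hospital",
                                 "Nursing Staff, Hospital",
                                 mesh_profile$descriptor, fixed = TRUE)
  corpus_spec(n_relevant = n_relevant, n_background = n_background,
              term_profile = term_profile, mesh_profile = mesh_profile,
              seed = seed)
}

#' Bundled nurse-staffing search strategies
#'
#' Three PubMed-dialect strategies for retrieving nurse staffing research —
#' one maximising sensitivity, one maximising precision and one balancing
#' the two — shipped as numbered-line text files under
#' `inst/extdata/strategies/`.
#'
#' @param name `"sensitive"`, `"precise"` or `"balanced"`.
#' @return `nurse_staffing_strategy()` returns the parsed
#'   `boolean_strategy`; `nurse_staffing_strategy_path()` the file path.
#' @export
#' @examples
#' nurse_staffing_strategy("balanced")
nurse_staffing_strategy <- function(name = c("sensitive", "precise", "balanced")) {
  name <- match.arg(name)
  read_strategy(nurse_staffing_strategy_path(name), name = name)
}

#' @rdname nurse_staffing_strategy
#' @export
nurse_staffing_strategy_path <- function(name = c("sensitive", "precise", "balanced")) {
  name <- match.arg(name)
  path <- system.file("extdata", "strategies", paste0(name, ".txt"),
                      package = "hedgedev", mustWork = TRUE)
  path
}
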