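# Retrieval evaluation: sensitivity, precision, number needed to read,
# cross-strategy comparison tables, and the sample-based estimate of the
# total number of relevant references in a database.

#' Retrieval result against a gold standard
#'
#' Joins a retrieved id set with a gold-standard relevant id set. The
#' intersection is always recomputed here — callers cannot supply their own
#' overlap count, which keeps the three metrics mutually consistent.
#'
#' @param retrieved_ids character vector of retrieved PMIDs.
#' @param relevant_ids character vector of gold-standard relevant PMIDs.
#' @return object of class `retrieval_result` with elements `retrieved`,
#'   `relevant`, `relevant_retrieved` (all de-duplicated character vectors).
#' @export
retrieval_result <- function(retrieved_ids, relevant_ids) {
  retrieved <- unique(as.character(retrieved_ids))
  relevant <- unique(as.character(relevant_ids))
  structure(list(retrieved = retrieved, relevant = relevant,
                 relevant_retrieved = intersect(retrieved, relevant)),
            class = "retrieval_result")
}

#' Retrieval performance metrics
#'
#' The three standard measures of a search strategy tested against a
#' gold-standard set:
#' \deqn{sensitivity = relevant\ retrieved / all\ relevant}
#' \deqn{precision = relevant\ retrieved / all\ retrieved}
#' \deqn{NNR = all\ retrieved / relevant\ retrieved = 1 / precision}
#' All three return unrounded fractions/ratios; reports show sensitivity
#' and precision as percentages with 1 decimal and NNR rounded to the
#' nearest integer (half away from zero). Zero denominators are errors, not
#' sentinel values: a strategy retrieving nothing has no defined precision.
#'
#' @param x a [retrieval_result()].
#' @return numeric scalar (fraction for sensitivity/precision, ratio for
#'   `nnr`).
#' @export
#' @examples
#' r <- retrieval_result(retrieved_ids = as.character(1:25),
#'                       relevant_ids = as.character(18:34))
#' sensitivity(r)  # 8/17
#' precision(r)    # 8/25
#' nnr(r)          # 25/8
sensitivity <- function(x) {
  stopifnot(inherits(x, "retrieval_result"))
  if (!length(x$relevant)) stop("sensitivity undefined: empty gold-standard set")
  length(x$relevant_retrieved) / length(x$relevant)
}

#' @rdname sensitivity
#' @export
precision <- function(x) {
  stopifnot(inherits(x, "retrieval_result"))
  if (!length(x$retrieved)) stop("precision undefined: nothing retrieved")
  length(x$relevant_retrieved) / length(x$retrieved)
}

#' @rdname sensitivity
#' @export
nnr <- function(x) {
  stopifnot(inherits(x, "retrieval_result"))
  if (!length(x$relevant_retrieved))
    stop("NNR undefined: no relevant records retrieved")
  length(x$retrieved) / length(x$relevant_retrieved)
}

#' Performance report from counts
#'
#' Builds the per-strategy report row from the three counts. Metrics whose
#' denominator is zero are reported as `NA` (the scalar accessors
#' [sensitivity()] etc. raise errors instead; a comparison table must be
#' able to carry a no-hit strategy without crashing).
#'
#' @param retrieved_count,relevant_count,relevant_retrieved_count
#'   non-negative integers; the overlap may exceed neither other count.
#' @return object of class `performance_report`: a list with the three
#'   counts and `sensitivity`, `precision` (fractions) and `nnr` (ratio),
#'   `NA` where undefined.
#' @export
#' @examples
#' performance_report(210, 17, 17)
performance_report <- function(retrieved_count, relevant_count,
                               relevant_retrieved_count) {
  stopifnot(is_count(retrieved_count), is_count(relevant_count),
            is_count(relevant_retrieved_count))
  if (relevant_retrieved_count > min(retrieved_count, relevant_count))
    stop("overlap count exceeds a marginal count")
  structure(list(
    retrieved_count = as.integer(retrieved_count),
    relevant_count = as.integer(relevant_count),
    relevant_retrieved_count = as.integer(relevant_retrieved_count),
    sensitivity = if (relevant_count > 0)
      relevant_retrieved_count / relevant_count else NA_real_,
    precision = if (retrieved_count > 0)
      relevant_retrieved_count / retrieved_count else NA_real_,
    nnr = if (relevant_retrieved_count > 0)
      retrieved_count / relevant_retrieved_count else NA_real_),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("retrieved %d [%d relevant retrieved of %d relevant]\n",
              x$retrieved_count, x$relevant_retrieved_count, x$relevant_count))
  cat(sprintf("sensitivity %s%%  precision %s%%  NNR %s\n",
              format_pct(x$sensitivity), format_pct(x$precision),
              format_nnr(x$nnr)))
  invisible(x)
}

# reporting formats: percent to 1 decimal, NNR to nearest integer
format_pct <- function(frac) {
  ifelse(is.na(frac), "NA", sprintf("%.1f", round_half_up(100 * frac, 1)))
}
format_nnr <- function(ratio) {
  ifelse(is.na(ratio), "NA", sprintf("%d", as.integer(round_half_up(ratio, 0))))
}

#' Evaluate a strategy against a labelled corpus
#'
#' Executes the strategy (see [execute_strategy()]) and scores the retrieval
#' against the gold-standard relevant ids.
#'
#' @param strategy a `boolean_strategy` or `query_expr`.
#' @param corpus a [medline_corpus()].
#' @param relevant_ids gold-standard PMIDs (must be a subset of the corpus).
#' @param tree,explode,year_range passed to [execute_strategy()]. The year
#'   range also restricts the gold standard, so sensitivity refers to the
#'   date-limited relevant set.
#' @return a [performance_report()].
#' @export
evaluate_strategy <- function(strategy, corpus, relevant_ids, tree = NULL,
                              explode = FALSE, year_range = NULL) {
  relevant_ids <- unique(as.character(relevant_ids))
  missing <- setdiff(relevant_ids, pmids(corpus))
  if (length(missing))
    stop("relevant ids not in corpus: ", paste(utils::head(missing, 5), collapse = ", "))
  if (!is.null(year_range)) {
    corpus <- filter_by_year(corpus, year_range[1], year_range[2])
    relevant_ids <- intersect(relevant_ids, pmids(corpus))
  }
  retrieved <- execute_strategy(strategy, corpus, tree = tree, explode = explode)
  rr <- retrieval_result(retrieved, relevant_ids)
  performance_report(length(rr$retrieved), length(rr$relevant),
                     length(rr$relevant_retrieved))
}

#' Compare several strategies on one labelled corpus
#'
#' One row per strategy: retrieved count, relevant-retrieved count,
#' sensitivity %, precision % and NNR, the layout in which competing search
#' filters are reported.
#'
#' @param strategies named list of `boolean_strategy`/`query_expr` objects.
#' @param corpus,relevant_ids,tree,explode,year_range as in
#'   [evaluate_strategy()].
#' @return data.frame with columns `strategy`, `retrieved`,
#'   `relevant_retrieved`, `sensitivity_pct`, `precision_pct`, `nnr`
#'   (display-rounded; `NA` where undefined).
#' @export
compare_strategies <- function(strategies, corpus, relevant_ids, tree = NULL,
                               explode = FALSE, year_range = NULL) {
  stopifnot(is.list(strategies), length(strategies) >= 1L)
  nm <- names(strategies)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(seq_along(strategies), function(k) {
      s <- strategies[[k]]
      if (inherits(s, "boolean_strategy") && nzchar(s$name)) s$name
      else paste0("strategy_", k)
    }, character(1))
  rows <- lapply(strategies, evaluate_strategy, corpus = corpus,
                 relevant_ids = relevant_ids, tree = tree, explode = explode,
                 year_range = year_range)
  data.frame(
    strategy = nm,
    retrieved = vapply(rows, `[[`, integer(1), "retrieved_count"),
    relevant_retrieved = vapply(rows, `[[`, integer(1), "relevant_retrieved_count"),
    sensitivity_pct = round_half_up(100 * vapply(rows, `[[`, numeric(1), "sensitivity"), 1),
    precision_pct = round_half_up(100 * vapply(rows, `[[`, numeric(1), "precision"), 1),
    nnr = as.integer(round_half_up(vapply(rows, `[[`, numeric(1), "nnr"), 0)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @param comparison a [compare_strategies()] data.frame.
#' @param file path or connection; `""` returns the lines.
#' @rdname compare_strategies
#' @export
write_comparison <- function(comparison, file = "") {
  lines <- c(paste(names(comparison), collapse = "\t"),
             do.call(paste, c(unname(comparison), sep = "\t")))
  if (identical(file, "")) return(lines)
  write_output_lines(lines, file)
}

#' OR-pool of several strategies' retrievals
#'
#' The union of the individual retrieved sets — the joint retrieval from
#' which a precision sample is drawn. Equals executing a single OR over the
#' compiled strategies.
#'
#' @inheritParams compare_strategies
#' @return character vector of PMIDs, in corpus order.
#' @export
union_pool <- function(strategies, corpus, tree = NULL, explode = FALSE,
                       year_range = NULL) {
  stopifnot(is.list(strategies), length(strategies) >= 1L)
  sets <- lapply(strategies, execute_strategy, corpus = corpus, tree = tree,
                 explode = explode, year_range = year_range)
  ids <- unique(unlist(sets, use.names = FALSE))
  intersect(pmids(corpus), ids)  # corpus order
}

#' Estimate the total number of relevant references
#'
#' From a joint retrieval of size `joint_retrieved` (all candidate
#' strategies ORed together, assumed to capture essentially all relevant
#' records), a random sample of `sample_size` records is screened and
#' `sample_relevant` are found relevant. The expected total is
#' `joint_retrieved * sample_relevant / sample_size`, with a binomial
#' confidence interval on the sample proportion scaled by `joint_retrieved`
#' and truncated below at zero.
#'
#' @param joint_retrieved size of the ORed retrieval pool.
#' @param sample_size number of screened records (drawn from the pool).
#' @param sample_relevant number of screened records judged relevant.
#' @param ci_level confidence level, default 0.95.
#' @param ci_method `"wald"` (default; normal approximation), `"wilson"`
#'   (score interval, [stats::prop.test()] without continuity correction) or
#'   `"clopper-pearson"` (exact, [stats::binom.test()]).
#' @return object of class `population_estimate` with elements `point`,
#'   `ci_low`, `ci_high`, `joint_retrieved`, `sample_size`,
#'   `sample_relevant`, `ci_level`, `ci_method`.
#' @export
#' @examples
#' estimate_total_relevant(35708, 2195, 6)
estimate_total_relevant <- function(joint_retrieved, sample_size, sample_relevant,
                                    ci_level = 0.95,
                                    ci_method = c("wald", "wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(is_count(joint_retrieved), is_count(sample_size), is_count(sample_relevant),
            ci_level > 0, ci_level < 1)
  if (sample_size == 0) stop("sample_size must be positive")
  if (sample_relevant > sample_size)
    stop("sample_relevant exceeds sample_size")
  if (sample_size > joint_retrieved)
    stop("sample_size exceeds the joint retrieval it was drawn from")
  phat <- sample_relevant / sample_size
  ci <- switch(ci_method,
    wald = {
      half <- stats::qnorm(1 - (1 - ci_level) / 2) *
        sqrt(phat * (1 - phat) / sample_size)
      c(max(0, phat - half), min(1, phat + half))
    },
    wilson = as.numeric(stats::prop.test(sample_relevant, sample_size,
                                         conf.level = ci_level,
                                         correct = FALSE)$conf.int),
    `clopper-pearson` = as.numeric(stats::binom.test(sample_relevant, sample_size,
                                                     conf.level = ci_level)$conf.int))
  structure(list(point = joint_retrieved * phat,
                 ci_low = joint_retrieved * ci[1],
                 ci_high = joint_retrieved * ci[2],
                 joint_retrieved = as.integer(joint_retrieved),
                 sample_size = as.integer(sample_size),
                 sample_relevant = as.integer(sample_relevant),
                 ci_level = ci_level, ci_method = ci_method),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("expected relevant references: %.1f [%.1f-%.1f] (%d%% CI, %s)\n",
              round_half_up(x$point, 1), round_half_up(x$ci_low, 1),
              round_half_up(x$ci_high, 1), round(100 * x$ci_level), x$ci_method))
  cat(sprintf("  pool %d, screened sample %d, relevant in sample %d\n",
              x$joint_retrieved, x$sample_size, x$sample_relevant))
  invisible(x)
}
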