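#' Bibliographic record containers
#'
#' A `medline_record` holds the fields of one MEDLINE citation that the
#' filter-development pipeline consumes: the PMID, title, abstract, MeSH
#' headings, publication year and (optionally) the journal title. A
#' `medline_corpus` is an ordered collection of records with unique PMIDs,
#' optionally labelled with the name of the reference set it represents
#' (development set, population set, ...).
#'
#' @param pmid non-empty character scalar identifier.
#' @param title,abstract free text; an empty abstract is representable and is
#'   omitted when the record is written back to MEDLINE format.
#' @param mesh list of [mesh_heading()] objects.
#' @param pub_year integer 4-digit publication year, or `NA` when unknown.
#' @param journal journal title or `NA`.
#' @return `medline_record()` returns an object of class `medline_record`.
#' @seealso [read_medline()], [write_medline()]
#' @export
#' @examples
#' r <- medline_record("1", title = "Nurse staffing and patient outcomes.",
#'                     mesh = list(mesh_heading("Nursing Staff, Hospital", "manpower")))
#' r$pmid
medline_record <- function(pmid, title = "", abstract = "", mesh = list(),
                           pub_year = NA_integer_, journal = NA_character_) {
  pmid <- as.character(pmid)
  if (length(pmid) != 1L || is.na(pmid) || !nzchar(pmid))
    stop("'pmid' must be a non-empty string")
  pub_year <- as.integer(pub_year)
  if (!is.na(pub_year) && (pub_year < 1000L || pub_year > 9999L))
    stop("'pub_year' must be a 4-digit year, got ", pub_year)
  stopifnot(is.list(mesh))
  structure(
    list(pmid = pmid, title = as.character(title), abstract = as.character(abstract),
         mesh = mesh, pub_year = pub_year, journal = as.character(journal)),
    class = "medline_record")
}

#' MeSH heading attached to a record
#'
#' @param descriptor canonical heading text, e.g. `"Nursing Staff, Hospital"`.
#' @param subheadings character vector of qualifiers, e.g. `"manpower"`; may
#'   be empty.
#' @param major_topic logical; `TRUE` when the heading (starred in MEDLINE
#'   exports) is a major topic of the record.
#' @return object of class `mesh_heading`.
#' @export
mesh_heading <- function(descriptor, subheadings = character(), major_topic = FALSE) {
  descriptor <- as.character(descriptor)
  if (length(descriptor) != 1L || is.na(descriptor) || !nzchar(descriptor))
    stop("'descriptor' must be a non-empty string")
  structure(list(descriptor = descriptor,
                 subheadings = as.character(subheadings),
                 major_topic = isTRUE(major_topic)),
            class = "mesh_heading")
}

#' @param records list of [medline_record()] objects.
#' @param label free-text name of the reference set.
#' @rdname medline_record
#' @export
medline_corpus <- function(records = list(), label = "") {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$pmid, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate PMID in corpus: ", paste(unique(dup), collapse = ", "))
  structure(list(records = records, label = as.character(label)),
            class = "medline_corpus")
}

#' @export
length.medline_corpus <- function(x) length(x$records)

#' @export
`[.medline_corpus` <- function(x, i) {
  medline_corpus(x$records[i], label = x$label)
}

#' @export
print.medline_corpus <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" (", x$label, ")") else ""
  cat(sprintf("<medline_corpus%s: %d records>\n", lab, length(x)))
  invisible(x)
}

#' @export
print.medline_record <- function(x, ...) {
  cat(sprintf("<medline_record %s> %s\n", x$pmid, x$title))
  invisible(x)
}

#' PMIDs of a corpus
#' @param corpus a [medline_corpus()].
#' @return character vector of record identifiers, in corpus order.
#' @export
pmids <- function(corpus) {
  stopifnot(inherits(corpus, "medline_corpus"))
  vapply(corpus$records, function(r) r$pmid, character(1))
}

# ---- MEDLINE tagged format ----------------------------------------------

# "TAG - value"; real exports pad the tag to 4 characters.
MEDLINE_TAG_RE <- "^([A-Z][A-Z0-9]{1,3})\\s{0,3}- (.*)$"

parse_mesh_field <- function(value) {
  major <- grepl("*", value, fixed = TRUE)
  value <- gsub("*", "", value, fixed = TRUE)
  parts <- strsplit(value, "/", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  mesh_heading(parts[1], subheadings = parts[-1], major_topic = major)
}

#' Parse MEDLINE tagged-format text
#'
#' Parses the line-tagged record format produced by PubMed's "MEDLINE"
#' export: `PMID-`, `TI  -`, `AB  -`, `MH  -`, `DP  -`, `JT  -` lines, with
#' indented continuation lines joined by single spaces and records separated
#' by blank lines. A leading `*` on an `MH` value (descriptor or qualifier)
#' marks the heading as a major topic; `Descriptor/qualifier1/qualifier2`
#' splits into the descriptor and its subheadings. The publication year is
#' the first 4-digit token of the `DP` field. Unrecognised tags are ignored.
#'
#' @param lines character vector of raw lines (one element per line).
#' @param label set label passed on to [medline_corpus()].
#' @return a [medline_corpus()].
#' @seealso [read_medline()] to read from a file, [write_medline()] for the
#'   inverse operation.
#' @export
#' @examples
#' parse_medline(c("PMID- 1",
#'                 "TI  - Nurse staffing.",
#'                 "MH  - *Nursing Staff, Hospital/manpower"))
parse_medline <- function(lines, label = "") {
  stopifnot(is.character(lines))
  if (!length(lines)) return(medline_corpus(list(), label = label))
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1])) # block id per line
  records <- list()
  for (g in split(seq_along(lines), grp)) {
    g <- g[!blank[g]]
    if (!length(g)) next
    fields <- list()  # list of c(tag, value)
    for (i in g) {
      line <- lines[i]
      m <- regmatches(line, regexec(MEDLINE_TAG_RE, line))[[1]]
      if (length(m)) {
        fields[[length(fields) + 1L]] <- c(m[2], m[3])
      } else if (grepl("^\\s+\\S", line)) {
        if (!length(fields))
          stop("line ", i, ": continuation line with no preceding field")
        prev <- fields[[length(fields)]]
        fields[[length(fields)]] <- c(prev[1], paste(prev[2], trimws(line)))
      } else {
        stop("line ", i, ": not a tagged field or continuation: ", line)
      }
    }
    tags <- vapply(fields, `[`, "", 1L)
    vals <- vapply(fields, `[`, "", 2L)
    if (!any(tags == "PMID"))
      stop("record block starting at line ", min(g), " has no PMID field")
    if (sum(tags == "PMID") > 1L)
      stop("record block starting at line ", min(g),
           " has multiple PMID fields; records must be blank-line separated")
    pmid <- trimws(vals[match("PMID", tags)])
    dp <- if ("DP" %in% tags) vals[match("DP", tags)] else NA_character_
    year <- NA_integer_
    if (!is.na(dp)) {
      ym <- regmatches(dp, regexpr("[0-9]{4}", dp))
      if (length(ym)) year <- as.integer(ym)
    }
    records[[length(records) + 1L]] <- medline_record(
      pmid = pmid,
      title = if ("TI" %in% tags) vals[match("TI", tags)] else "",
      abstract = if ("AB" %in% tags) vals[match("AB", tags)] else "",
      mesh = lapply(vals[tags == "MH"], parse_mesh_field),
      pub_year = year,
      journal = if ("JT" %in% tags) vals[match("JT", tags)] else NA_character_)
  }
  medline_corpus(records, label = label)
}

#' @param file path, connection, or `"stdin"`.
#' @rdname parse_medline
#' @export
read_medline <- function(file, label = "") {
  parse_medline(read_input_lines(file), label = label)
}

#' Write a corpus as MEDLINE tagged text
#'
#' The inverse of [parse_medline()]: emits one `PMID-`/`TI  -`/`AB  -`/
#' `JT  -`/`DP  -`/`MH  -` block per record, blank-line separated. Fields
#' are written unwrapped (one line per field), so the output reparses to an
#' identical corpus. Empty abstracts produce no `AB` line; a missing year no
#' `DP` line.
#'
#' @param corpus a [medline_corpus()].
#' @param file path or connection; `""` (default) returns the lines invisibly
#'   without writing.
#' @return character vector of output lines, invisibly when written to a file.
#' @export
write_medline <- function(corpus, file = "") {
  stopifnot(inherits(corpus, "medline_corpus"))
  out <- character()
  for (r in corpus$records) {
    block <- paste0("PMID- ", r$pmid)
    if (nzchar(r$title))    block <- c(block, paste0("TI  - ", r$title))
    if (nzchar(r$abstract)) block <- c(block, paste0("AB  - ", r$abstract))
    if (!is.na(r$journal))  block <- c(block, paste0("JT  - ", r$journal))
    if (!is.na(r$pub_year)) block <- c(block, paste0("DP  - ", r$pub_year))
    for (h in r$mesh) {
      v <- paste0(if (h$major_topic) "*", h$descriptor,
                  if (length(h$subheadings))
                    paste0("/", paste(h$subheadings, collapse = "/")))
      block <- c(block, paste0("MH  - ", v))
    }
    out <- c(out, block, "")
  }
  if (length(out)) out <- out[-length(out)]
  if (identical(file, "")) return(out)
  write_output_lines(out, file)
}

# ---- PMID lists ----------------------------------------------------------

#' Read and write PMID list files
#'
#' A PMID list is a plain-text file with one numeric identifier per line,
#' the format in which retrieval results are saved for screening. Blank
#' lines are ignored; order is preserved.
#'
#' @param file path, connection, or `"stdin"`.
#' @return `read_pmid_list()` returns a character vector of ids.
#' @export
read_pmid_list <- function(file) {
  lines <- read_input_lines(file)
  keep <- !grepl("^\\s*$", lines)
  ids <- trimws(lines[keep])
  bad <- which(!grepl("^[0-9]+$", ids))
  if (length(bad))
    stop("line ", which(keep)[bad[1]], ": not a numeric PMID: ", ids[bad[1]])
  ids
}

#' @param x character vector of ids, or a [medline_corpus()] (its [pmids()]
#'   are written).
#' @rdname read_pmid_list
#' @export
write_pmid_list <- function(x, file = "") {
  if (inherits(x, "medline_corpus")) x <- pmids(x)
  stopifnot(is.character(x) || is.numeric(x))
  lines <- as.character(x)
  if (identical(file, "")) return(lines)
  write_output_lines(lines, file)
}

# ---- corpus subsetting ---------------------------------------------------

#' Seeded uniform sample of a corpus
#'
#' Draws `n` records uniformly without replacement, as when a random
#' population sample is taken from a database-wide PMID list. The caller's
#' RNG state is left untouched; the same seed always yields the same sample.
#' Records keep their original corpus order.
#'
#' @param corpus a [medline_corpus()].
#' @param n number of records to draw, `0 <= n <= length(corpus)`.
#' @param seed integer seed; `NULL` uses (and advances) the session RNG.
#' @return a [medline_corpus()] of `n` records.
#' @export
sample_corpus <- function(corpus, n, seed = NULL) {
  stopifnot(inherits(corpus, "medline_corpus"), is_count(n))
  if (n > length(corpus))
    stop("cannot sample ", n, " records from a corpus of ", length(corpus))
  idx <- with_seed_(seed, sort(sample.int(length(corpus), n)))
  corpus[idx]
}

#' Restrict a corpus to a publication-year window
#'
#' Keeps records with `start_year <= pub_year <= end_year` (both bounds
#' inclusive); records with no publication year are dropped, mirroring a
#' database date limit.
#'
#' @param corpus a [medline_corpus()].
#' @param start_year,end_year inclusive 4-digit bounds.
#' @return the filtered [medline_corpus()].
#' @export
filter_by_year <- function(corpus, start_year, end_year) {
  stopifnot(inherits(corpus, "medline_corpus"), start_year <= end_year)
  yrs <- vapply(corpus$records, function(r) r$pub_year %||% NA_integer_, integer(1))
  keep <- !is.na(yrs) & yrs >= start_year & yrs <= end_year
  corpus[keep]
}
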