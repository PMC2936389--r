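# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for reported ratios such as the number needed to
#' read, where 55.5 reads as 56. Base [round()] rounds half to even, which is
#' right for numerics but not for report tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

# read lines from a path, connection, or "-"/"stdin"
read_input_lines <- function(file) {
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  stopifnot(is.character(file), length(file) == 1L)
  if (file %in% c("-", "stdin")) return(readLines(file("stdin"), warn = FALSE))
  readLines(file, warn = FALSE, encoding = "UTF-8")
}

write_output_lines <- function(lines, file) {
  if (is.null(file) || identical(file, "")) return(lines)
  con <- if (inherits(file, "connection")) file else base::file(file, "w", encoding = "UTF-8")
  if (!inherits(file, "connection")) on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}
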