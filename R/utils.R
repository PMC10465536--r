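#' @importFrom stats runif rpois setNames
#' @importFrom utils head tail write.table read.table
NULL

RULESET_VERSION <- "rumenvirome-ruleset/1.0"

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a locally scoped RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Random DNA string of a given length
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Total length of the union of integer intervals
#'
#' Intervals are 0-based half-open `[start, end)`.
#' @keywords internal
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  stopifnot(length(starts) == length(ends), all(ends >= starts))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(ir))
}

#' Write a data frame as TSV with a commented header line
#'
#' The first line is `# <ruleset>: col1<TAB>col2...`; rows follow untitled.
#' @keywords internal
write_tsv_rv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0("# ", RULESET_VERSION, ": ", paste(names(df), collapse = "\t"))
  writeLines(hdr, con, sep = "\n")
  if (nrow(df) > 0) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv_rv()]
#' @keywords internal
read_tsv_rv <- function(path, colClasses = NA) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^# [^:]+: ", "", first), "\t", fixed = TRUE)[[1]]
  df <- read.table(path, sep = "\t", quote = "", comment.char = "#",
                   col.names = cols, colClasses = colClasses,
                   stringsAsFactors = FALSE)
  df
}

fmt_num <- function(x, digits = 3) {
  formatC(x, format = "f", digits = digits, drop0trailing = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
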