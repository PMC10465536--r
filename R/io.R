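#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the canonical 12-column tab-separated BLAST output. Coordinates
#' are kept 1-based inclusive exactly as in the file; minus-strand subject
#' hits keep `sstart > send`.
#'
#' @param path Path to a 12-column tab-separated file (no header).
#' @return A data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bitscore`.
#' @export
read_blast6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blast6())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 12L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BLAST6 row at line %d: expected 12 columns, got %d",
                 bad[1], nfield[bad[1]]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$percent_identity) || anyNA(df$alignment_length)) {
    stop("malformed BLAST6 row: non-numeric identity or length field")
  }
  df
}

empty_blast6 <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             query_start = integer(), query_end = integer(),
             subject_start = integer(), subject_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in BLAST tabular (outfmt 6) format
#'
#' Inverse of [read_blast6()]: writing a table read from a canonical file
#' reproduces it byte for byte. Identity is printed with three decimals and
#' e-values in BLAST's compact scientific form.
#'
#' @param blocks Data frame as returned by [read_blast6()].
#' @param path Output path.
#' @export
write_blast6 <- function(blocks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(blocks) > 0) {
    rows <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                    blocks$query_id, blocks$subject_id,
                    fmt_num(blocks$percent_identity, 3),
                    blocks$alignment_length, blocks$mismatches,
                    blocks$gap_opens,
                    blocks$query_start, blocks$query_end,
                    blocks$subject_start, blocks$subject_end,
                    format_evalue(blocks$evalue),
                    fmt_num(blocks$bitscore, 1))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

format_evalue <- function(e) {
  ifelse(e == 0, "0.0", formatC(e, format = "e", digits = 2))
}

#' Read sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header is the sequence id;
#' the remainder is kept as the description.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences; descriptions (possibly
#'   empty) in attribute `"description"`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  out <- setNames(as.character(ss), ids)
  attr(out, "description") <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA, wrapped at 80 columns
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a GFF3-like gene table
#'
#' Nine tab-separated columns with 1-based inclusive coordinates and
#' `key=value;` attribute pairs in column 9. Returns a gene feature table
#' with 0-based half-open intervals (the package-internal convention) and
#' the controlled-vocabulary annotation fields unpacked from attributes:
#' `gene_id`, `category`, `labels` (comma-joined), `amg_category`.
#'
#' @param path Path to the gene table.
#' @return Data frame of gene features ordered as in the file.
#' @export
read_gene_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(contig_id = character(), gene_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      category = character(), labels = character(),
                      amg_category = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) stop("gene table rows must have 9 columns")
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  attr_field <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    found <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[found] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  amg <- attr_field(m[, 9], "amg_category")
  data.frame(
    contig_id = m[, 1],
    gene_id = attr_field(m[, 9], "ID"),
    start = as.integer(m[, 4]) - 1L,          # to 0-based half-open
    end = as.integer(m[, 5]),
    strand = m[, 7],
    category = attr_field(m[, 9], "category"),
    labels = ifelse(is.na(attr_field(m[, 9], "labels")), "",
                    attr_field(m[, 9], "labels")),
    amg_category = ifelse(is.na(amg), NA_integer_, as.integer(amg)),
    stringsAsFactors = FALSE
  )
}

#' Write a gene feature table as GFF3-like TSV
#'
#' @param genes Data frame in the layout of [read_gene_table()] (0-based
#'   half-open `start`/`end`).
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("##gene-table ", RULESET_VERSION), con, sep = "\n")
  if (nrow(genes) > 0) {
    attrs <- paste0("ID=", genes$gene_id,
                    ";category=", genes$category,
                    ifelse(nzchar(genes$labels), paste0(";labels=", genes$labels), ""),
                    ifelse(is.na(genes$amg_category), "",
                           paste0(";amg_category=", genes$amg_category)))
    rows <- sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    genes$contig_id, genes$start + 1L, genes$end,
                    genes$strand, attrs)
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Read a binary prevalence matrix TSV
#'
#' @param path TSV written by [write_prevalence_matrix()].
#' @return Integer matrix (vOTU rows, sample columns).
#' @export
read_prevalence_matrix <- function(path) {
  df <- read_tsv_rv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a binary prevalence matrix TSV
#' @param mat Binary matrix, vOTUs in rows, samples in columns.
#' @param path Output path.
#' @export
write_prevalence_matrix <- function(mat, path) {
  df <- data.frame(votu_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_rv(df, path)
}
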