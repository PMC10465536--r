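# Virus-host linkage: integrated-prophage alignment evidence and exact
# CRISPR-spacer matches, plus host-range and per-genus infection summaries.

#' Call a prophage-based host link for one (vOTU, genome) pair
#'
#' Blocks are first filtered to identity strictly greater than 90%; a link
#' requires (a) at least one retained block longer than 2,500 bp and (b)
#' the union of retained-block vOTU intervals to cover at least 75% of the
#' vOTU length.
#'
#' @param blocks BLAST6-layout data frame for one (vOTU, genome) pair;
#'   query = vOTU, subject = host genome.
#' @param votu_length vOTU length in bp.
#' @param min_identity Per-block identity threshold (strict `>`).
#' @param min_block_len Minimum single-block length in bp (strict `>`).
#' @param min_votu_cover Minimum vOTU coverage fraction (inclusive `>=`).
#' @return One-row data frame link (`votu_id`, `genome_id`, `evidence`,
#'   `n_blocks`, `max_block_len`, `votu_coverage`) or `NULL`.
#' @export
call_prophage_link <- function(blocks, votu_length, min_identity = 90,
                               min_block_len = 2500, min_votu_cover = 0.75) {
  if (votu_length <= 0) stop("call_prophage_link: votu_length must be positive")
  if (nrow(blocks) == 0) return(NULL)
  stopifnot(length(unique(blocks$query_id)) == 1L,
            length(unique(blocks$subject_id)) == 1L)
  kept <- blocks[blocks$percent_identity > min_identity, , drop = FALSE]
  if (nrow(kept) == 0) return(NULL)
  if (!any(kept$alignment_length > min_block_len)) return(NULL)
  q1 <- pmin(kept$query_start, kept$query_end)
  q2 <- pmax(kept$query_start, kept$query_end)
  cov <- interval_union_length(q1 - 1L, q2) / votu_length
  if (cov < min_votu_cover) return(NULL)
  data.frame(votu_id = kept$query_id[1], genome_id = kept$subject_id[1],
             evidence = "prophage", n_blocks = nrow(kept),
             max_block_len = max(kept$alignment_length),
             votu_coverage = cov, detail = "", stringsAsFactors = FALSE)
}

#' Call prophage links over a full hit table
#'
#' @param hits BLAST6 data frame of vOTU-vs-genome hits.
#' @param votu_lengths Named integer vector of vOTU lengths.
#' @param ... Passed to [call_prophage_link()].
#' @return Data frame of links (possibly 0 rows).
#' @export
call_prophage_links <- function(hits, votu_lengths, ...) {
  if (nrow(hits) == 0) return(empty_links())
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(ix) {
    h <- hits[ix, , drop = FALSE]
    call_prophage_link(h, votu_lengths[[h$query_id[1]]], ...)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(empty_links())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$votu_id, res$genome_id), , drop = FALSE]
}

empty_links <- function() {
  data.frame(votu_id = character(), genome_id = character(),
             evidence = character(), n_blocks = integer(),
             max_block_len = integer(), votu_coverage = numeric(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Detect CRISPR arrays in a genome (minimal repeat finder)
#'
#' A minimal array finder in the spirit of standard CRISPR detection
#' tools. Candidate loci are positions whose minimal-length k-mer recurs
#' elsewhere in the genome; from each candidate the finder walks
#' occurrences of the seed spaced within the admissible repeat+spacer
#' window, then fixes the repeat length as the longest extension on which
#' all consecutive occurrence pairs agree. Arrays need at least
#' `min_repeats` identical repeats; repeat lengths and inter-repeat gaps
#' must fall inside the configured windows.
#'
#' @param genome_seq DNA string.
#' @param genome_id Genome identifier stamped on the output.
#' @param min_repeats Minimum number of identical repeats per array.
#' @param repeat_len Length window for repeats (bp).
#' @param spacer_len Length window for spacers (bp).
#' @return Data frame of spacers: `spacer_id`, `genome_id`, `sequence`,
#'   `start`, `end` (0-based half-open on the genome).
#' @export
detect_crispr_arrays <- function(genome_seq, genome_id = "genome",
                                 min_repeats = 2L,
                                 repeat_len = c(23L, 47L),
                                 spacer_len = c(26L, 50L)) {
  n <- nchar(genome_seq)
  k <- repeat_len[1]
  if (n < 2L * k + spacer_len[1]) return(empty_spacers())
  kmers <- substring(genome_seq, 1:(n - k + 1L), k:n)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  candidates <- which(dup)
  if (length(candidates) == 0) return(empty_spacers())
  chars <- strsplit(genome_seq, "", fixed = TRUE)[[1]]
  agree_right <- function(anchors, cap) {
    r <- 0L
    while (r < cap) {
      pos <- anchors + r
      if (any(pos > n) || length(unique(chars[pos])) != 1L) break
      r <- r + 1L
    }
    r
  }
  agree_left <- function(anchors, cap) {
    l <- 0L
    while (l < cap) {
      pos <- anchors - l - 1L
      if (any(pos < 1L) || length(unique(chars[pos])) != 1L) break
      l <- l + 1L
    }
    l
  }
  out <- list()
  skip_until <- 0L
  for (i in candidates) {
    if (i <= skip_until) next
    seed <- kmers[i]
    # pass 1: walk occurrences of the seed at admissible spacings
    starts <- i
    repeat {
      prev <- starts[length(starts)]
      win_from <- prev + k + spacer_len[1]
      win_to <- min(n - k + 1L, prev + repeat_len[2] + spacer_len[2])
      if (win_from > win_to) break
      window <- substr(genome_seq, win_from, win_to + k - 1L)
      rel <- regexpr(seed, window, fixed = TRUE)
      if (rel == -1L) break
      starts <- c(starts, win_from + as.integer(rel) - 1L)
    }
    if (length(starts) < max(2L, min_repeats)) next
    # pass 2: re-anchor on a core k-mer of the provisional repeat, then
    # trim both boundaries to the minimum agreement over all occurrence
    # pairs (chance context matches around a single pair cannot shift
    # the repeat when three or more copies vote)
    r0 <- agree_right(starts, min(repeat_len[2] + k,
                                  min(diff(starts)) - spacer_len[1]))
    core_off <- max(0L, (r0 - k) %/% 2L)
    core <- substr(genome_seq, i + core_off, i + core_off + k - 1L)
    span_from <- max(1L, i - repeat_len[2] - spacer_len[2])
    span_to <- min(n, starts[length(starts)] + 2L *
                     (repeat_len[2] + spacer_len[2]) *
                     (length(starts) + 2L))
    region <- substr(genome_seq, span_from, span_to)
    occ <- as.integer(gregexpr(core, region, fixed = TRUE)[[1]])
    occ <- occ[occ > 0] + span_from - 1L
    # maximal chain of admissibly spaced occurrences containing i+core_off
    d_ok <- diff(occ) >= (repeat_len[1] + spacer_len[1]) &
      diff(occ) <= (repeat_len[2] + spacer_len[2])
    anchor0 <- which(occ == i + core_off)[1]
    lo <- anchor0
    while (lo > 1L && d_ok[lo - 1L]) lo <- lo - 1L
    hi <- anchor0
    while (hi < length(occ) && d_ok[hi]) hi <- hi + 1L
    anchors <- occ[lo:hi]
    if (length(anchors) < max(2L, min_repeats)) next
    cap <- min(diff(anchors)) - spacer_len[1]
    rext <- agree_right(anchors, cap)
    lext <- agree_left(anchors, max(0L, cap - rext))
    rlen <- lext + rext
    if (rlen < repeat_len[1] || rlen > repeat_len[2]) next
    rep_starts <- anchors - lext
    gaps <- diff(rep_starts) - rlen
    if (any(gaps < spacer_len[1] | gaps > spacer_len[2])) next
    sp <- lapply(seq_len(length(rep_starts) - 1L), function(m) {
      s_from <- rep_starts[m] + rlen        # 1-based start of spacer
      s_to <- rep_starts[m + 1L] - 1L
      data.frame(spacer_id = sprintf("%s_arr%d_sp%d", genome_id,
                                     rep_starts[1], m),
                 genome_id = genome_id,
                 sequence = substr(genome_seq, s_from, s_to),
                 start = s_from - 1L, end = s_to,
                 stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- do.call(rbind, sp)
    skip_until <- rep_starts[length(rep_starts)] + rlen
  }
  if (length(out) == 0) return(empty_spacers())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_spacers <- function() {
  data.frame(spacer_id = character(), genome_id = character(),
             sequence = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Call a CRISPR-spacer host link
#'
#' A link is called iff the full spacer occurs exactly (100% identity,
#' 100% coverage; no ambiguity codes) in the vOTU sequence on either
#' strand.
#'
#' @param spacer_seq Spacer DNA string.
#' @param votu_seq vOTU DNA string.
#' @return `TRUE`/`FALSE`.
#' @export
call_spacer_link <- function(spacer_seq, votu_seq) {
  if (!nzchar(spacer_seq)) stop("call_spacer_link: empty spacer")
  grepl(spacer_seq, votu_seq, fixed = TRUE) ||
    grepl(revcomp(spacer_seq), votu_seq, fixed = TRUE)
}

#' Call spacer links over spacer and vOTU sets
#'
#' @param spacers Data frame as from [detect_crispr_arrays()].
#' @param votu_seqs Named character vector of vOTU sequences.
#' @return Data frame of links with `evidence = "spacer"`.
#' @export
call_spacer_links <- function(spacers, votu_seqs) {
  if (nrow(spacers) == 0) return(empty_links())
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    for (vid in names(votu_seqs)) {
      if (call_spacer_link(spacers$sequence[i], votu_seqs[[vid]])) {
        out[[length(out) + 1L]] <- data.frame(
          votu_id = vid, genome_id = spacers$genome_id[i],
          evidence = "spacer", n_blocks = 1L,
          max_block_len = nchar(spacers$sequence[i]), votu_coverage = NA_real_,
          detail = spacers$spacer_id[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_links())
  res <- do.call(rbind, out)
  res[order(res$votu_id, res$genome_id), , drop = FALSE]
}

#' Summarize host range per vOTU
#'
#' Links whose genome lacks taxonomy are dropped from the roll-up with a
#' warning. `multi_species` means at least two distinct host species;
#' `cross_phylum` at least two distinct host phyla.
#'
#' @param links Data frame of host links.
#' @param taxonomy Data frame with `genome_id` and GTDB-style rank
#'   columns (`species`, `genus`, `phylum`).
#' @return Data frame per vOTU with set sizes and flags.
#' @export
aggregate_host_range <- function(links, taxonomy) {
  missing <- setdiff(unique(links$genome_id), taxonomy$genome_id)
  if (length(missing) > 0) {
    warning("aggregate_host_range: no taxonomy for genome(s) ",
            paste(missing, collapse = ", "), "; links excluded")
    links <- links[!links$genome_id %in% missing, , drop = FALSE]
  }
  m <- match(links$genome_id, taxonomy$genome_id)
  links$species <- taxonomy$species[m]
  links$genus <- taxonomy$genus[m]
  links$phylum <- taxonomy$phylum[m]
  out <- lapply(split(links, links$votu_id), function(l) {
    data.frame(votu_id = l$votu_id[1],
               n_species = length(unique(l$species)),
               n_genera = length(unique(l$genus)),
               n_phyla = length(unique(l$phylum)),
               multi_species = length(unique(l$species)) >= 2L,
               cross_phylum = length(unique(l$phylum)) >= 2L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-genus phage statistics
#'
#' For every host genus: the number of distinct linked vOTUs, phages per
#' genome (distinct linked vOTUs divided by the number of genomes of the
#' genus), and the lysogeny rate (% of linked vOTUs classified
#' lysogenic). Every linked vOTU must carry a lysogeny call.
#'
#' @param links Data frame of host links.
#' @param genomes Data frame with `genome_id` and `genus`.
#' @param lysogeny_calls Named logical vector per vOTU.
#' @return Data frame per genus.
#' @export
genus_stats <- function(links, genomes, lysogeny_calls) {
  m <- match(links$genome_id, genomes$genome_id)
  if (anyNA(m)) stop("genus_stats: link to unknown genome")
  links$genus <- genomes$genus[m]
  miss <- setdiff(unique(links$votu_id), names(lysogeny_calls))
  if (length(miss) > 0) {
    stop("genus_stats: missing lysogeny call for vOTU(s) ",
         paste(miss, collapse = ", "))
  }
  n_genomes <- table(genomes$genus)
  out <- lapply(split(links, links$genus), function(l) {
    votus <- unique(l$votu_id)
    data.frame(genus = l$genus[1],
               n_phages = length(votus),
               n_genomes = as.integer(n_genomes[[l$genus[1]]]),
               phages_per_genome = length(votus) / n_genomes[[l$genus[1]]],
               lysogeny_rate = 100 * mean(lysogeny_calls[votus]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
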