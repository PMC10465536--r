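# Species-level vOTU clustering: pairwise ANI / aligned fraction from
# local alignment blocks, then greedy centroid clustering at 95% ANI over
# 85% of the shorter contig.

#' Load viral contigs with the >5 kb admission filter
#'
#' Contigs of 5,000 bp or shorter are rejected (the detection tools'
#' false-positive rate rises steeply below 5 kb, so only contigs strictly
#' longer than 5 kb are admitted).
#'
#' @param path FASTA path.
#' @param completeness Optional data frame (`contig_id`, `completeness`,
#'   `quality_tier`) merged onto the contig table.
#' @param min_length Admission floor in bp (strict `>`).
#' @return Data frame with `id`, `length`, `completeness`, `quality_tier`
#'   and the sequences in attribute `"sequences"`.
#' @export
load_contigs <- function(path, completeness = NULL, min_length = 5000L) {
  seqs <- read_fasta(path)
  keep <- nchar(seqs) > min_length
  seqs <- seqs[keep]
  df <- data.frame(id = names(seqs), length = nchar(seqs),
                   completeness = NA_real_, quality_tier = "unknown",
                   stringsAsFactors = FALSE)
  if (!is.null(completeness)) {
    m <- match(df$id, completeness$contig_id)
    df$completeness <- completeness$completeness[m]
    if ("quality_tier" %in% names(completeness)) {
      df$quality_tier <- ifelse(is.na(m), "unknown", completeness$quality_tier[m])
    }
  }
  attr(df, "sequences") <- seqs
  df
}

#' Gapless seed-and-extend local alignment of two contigs
#'
#' A deliberately simple all-vs-all nucleotide search for package-internal
#' use: exact k-mer seeds on both strands are grouped by diagonal and
#' extended gaplessly with an X-drop criterion. Blocks are reported with
#' BLAST-convention 1-based inclusive coordinates; minus-strand hits have
#' `subject_start > subject_end`.
#'
#' @param a,b DNA strings (query, subject).
#' @param k Seed length; must be >= 11.
#' @param x_drop Score drop tolerated during extension (match +1,
#'   mismatch -2).
#' @return BLAST6-layout data frame of alignment blocks.
#' @export
local_align <- function(a, b, k = 15L, x_drop = 20L) {
  if (k < 11L) stop("local_align: k must be >= 11")
  if (nchar(a) < k || nchar(b) < k) stop("local_align: sequences shorter than k")
  plus <- align_one_strand(a, b, k, x_drop)
  minus <- align_one_strand(a, revcomp(b), k, x_drop)
  if (nrow(minus) > 0) {
    # map subject coords back to the forward strand; start > end flags '-'
    nb <- nchar(b)
    s1 <- nb - minus$subject_start + 1L
    s2 <- nb - minus$subject_end + 1L
    minus$subject_start <- s1
    minus$subject_end <- s2
  }
  out <- rbind(plus, minus)
  if (nrow(out) == 0) return(empty_blast6())
  out <- out[order(-out$bitscore, out$query_start), ]
  rownames(out) <- NULL
  out
}

# k-mer seeding + per-diagonal gapless X-drop extension on the plus strand
align_one_strand <- function(a, b, k, x_drop) {
  na_ <- nchar(a); nb <- nchar(b)
  ka <- substring(a, 1:(na_ - k + 1L), k:na_)
  kb <- substring(b, 1:(nb - k + 1L), k:nb)
  idx_b <- split(seq_along(kb), kb)
  hit_a <- which(ka %in% names(idx_b))
  if (length(hit_a) == 0) return(empty_blast6())
  qpos <- integer(0); spos <- integer(0)
  for (i in hit_a) {
    js <- idx_b[[ka[i]]]
    qpos <- c(qpos, rep.int(i, length(js)))
    spos <- c(spos, js)
  }
  diag <- qpos - spos
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  blocks <- list()
  for (d in unique(diag)) {
    sel <- diag == d
    q <- sort(unique(qpos[sel]))
    # merge seeds on this diagonal into runs, then X-drop extend each run
    gaps <- which(diff(q) > k)
    run_start <- q[c(1L, gaps + 1L)]
    run_end <- q[c(gaps, length(q))] + k - 1L
    for (r in seq_along(run_start)) {
      q1 <- run_start[r]; q2 <- run_end[r]
      ext <- xdrop_extend(av, bv, q1, q2, d, x_drop)
      blocks[[length(blocks) + 1L]] <- ext
    }
  }
  out <- do.call(rbind, blocks)
  out <- unique(out)
  ali_len <- out$q2 - out$q1 + 1L
  matches <- out$matches
  data.frame(query_id = "query", subject_id = "subject",
             percent_identity = 100 * matches / ali_len,
             alignment_length = ali_len,
             mismatches = ali_len - matches, gap_opens = 0L,
             query_start = out$q1, query_end = out$q2,
             subject_start = out$q1 - d_of(out), subject_end = out$q2 - d_of(out),
             evalue = 0, bitscore = 2 * matches - 3 * (ali_len - matches),
             stringsAsFactors = FALSE)
}

d_of <- function(out) out$d

xdrop_extend <- function(av, bv, q1, q2, d, x_drop) {
  na_ <- length(av); nb <- length(bv)
  score <- function(qi) if (av[qi] == bv[qi - d]) 1L else -2L
  # right extension
  best <- 0L; cur <- 0L; best_q2 <- q2
  qi <- q2 + 1L
  while (qi <= na_ && (qi - d) <= nb) {
    cur <- cur + score(qi)
    if (cur > best) { best <- cur; best_q2 <- qi }
    if (best - cur > x_drop) break
    qi <- qi + 1L
  }
  # left extension
  best <- 0L; cur <- 0L; best_q1 <- q1
  qi <- q1 - 1L
  while (qi >= 1L && (qi - d) >= 1L) {
    cur <- cur + score(qi)
    if (cur > best) { best <- cur; best_q1 <- qi }
    if (best - cur > x_drop) break
    qi <- qi - 1L
  }
  idx <- best_q1:best_q2
  matches <- sum(av[idx] == bv[idx - d])
  data.frame(q1 = best_q1, q2 = best_q2, d = d, matches = matches)
}

#' Pairwise ANI and aligned fractions from alignment blocks
#'
#' ANI is the alignment-length-weighted mean identity over the blocks;
#' the aligned fraction of each sequence is the fraction covered by the
#' union of its block intervals (so overlapping blocks never push AF past
#' 100%). An empty block list yields ANI and AF of 0.
#'
#' @param blocks BLAST6-layout data frame, all rows sharing one
#'   (query, subject) pair.
#' @param len_q,len_s Sequence lengths in bp.
#' @return One-row data frame: `query_id`, `subject_id`, `ani`,
#'   `af_query`, `af_subject`.
#' @export
compute_pairwise_ani <- function(blocks, len_q, len_s) {
  if (nrow(blocks) == 0) {
    return(data.frame(query_id = NA_character_, subject_id = NA_character_,
                      ani = 0, af_query = 0, af_subject = 0,
                      stringsAsFactors = FALSE))
  }
  stopifnot(length(unique(blocks$query_id)) == 1L,
            length(unique(blocks$subject_id)) == 1L)
  q1 <- pmin(blocks$query_start, blocks$query_end)
  q2 <- pmax(blocks$query_start, blocks$query_end)
  s1 <- pmin(blocks$subject_start, blocks$subject_end)  # normalize '-' strand
  s2 <- pmax(blocks$subject_start, blocks$subject_end)
  if (any(q2 > len_q) || any(s2 > len_s) || any(q1 < 1) || any(s1 < 1)) {
    stop("compute_pairwise_ani: block interval exceeds stated sequence length")
  }
  w <- blocks$alignment_length
  ani <- sum(blocks$percent_identity * w) / sum(w)
  af_q <- 100 * interval_union_length(q1 - 1L, q2) / len_q
  af_s <- 100 * interval_union_length(s1 - 1L, s2) / len_s
  data.frame(query_id = blocks$query_id[1], subject_id = blocks$subject_id[1],
             ani = ani, af_query = af_q, af_subject = af_s,
             stringsAsFactors = FALSE)
}

#' Build the full pairwise ANI table from a BLAST6 hit table
#'
#' Groups hits by (query, subject), drops self pairs, computes ANI/AF per
#' pair and collapses the two directions of each pair into one canonical
#' (lexicographic) row, preferring the direction with more aligned bases.
#'
#' @param hits BLAST6 data frame (e.g. from [read_blast6()]).
#' @param lengths Named integer vector of contig lengths.
#' @return Data frame of canonical pairwise ANI rows.
#' @export
ani_table_from_hits <- function(hits, lengths) {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      ani = numeric(), af_query = numeric(),
                      af_subject = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(hits)), key), function(ix) {
    h <- hits[ix, , drop = FALSE]
    compute_pairwise_ani(h, lengths[[h$query_id[1]]], lengths[[h$subject_id[1]]])
  })
  tab <- do.call(rbind, rows)
  # canonicalize pair order
  flip <- tab$query_id > tab$subject_id
  tab[flip, c("query_id", "subject_id")] <- tab[flip, c("subject_id", "query_id")]
  tab[flip, c("af_query", "af_subject")] <- tab[flip, c("af_subject", "af_query")]
  key2 <- paste(tab$query_id, tab$subject_id, sep = "\r")
  keep <- !duplicated(key2)
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Greedy centroid clustering of contigs into vOTUs
#'
#' Contigs are processed longest first (ties: higher completeness, then
#' id); each contig joins the first existing centroid it matches at
#' `ani >= ani_min` with an aligned fraction of the shorter contig of the
#' pair `>= af_min`, otherwise it founds a new centroid. Membership is
#' tested against centroids only, never against other members, matching
#' the behaviour of the standard ANI-clustering script used for viral
#' species delineation.
#'
#' @param contigs Data frame with `id`, `length` and optionally
#'   `completeness` columns; duplicate ids are an error.
#' @param ani_table Data frame as from [ani_table_from_hits()].
#' @param ani_min,af_min Clustering thresholds (percent).
#' @return Data frame with `representative_id`, `member_id`.
#' @export
cluster_votus <- function(contigs, ani_table, ani_min = 95, af_min = 85) {
  if (anyDuplicated(contigs$id)) stop("cluster_votus: duplicate contig ids")
  comp <- contigs$completeness %||% rep(NA_real_, nrow(contigs))
  if (is.null(contigs$completeness)) contigs$completeness <- NA_real_
  comp_key <- ifelse(is.na(contigs$completeness), -1, contigs$completeness)
  ord <- order(-contigs$length, -comp_key, contigs$id)
  ids <- contigs$id[ord]
  lens <- setNames(contigs$length, contigs$id)

  # lookup: canonical pair -> (ani, af of shorter contig)
  pair_ani <- new.env(parent = emptyenv())
  if (nrow(ani_table) > 0) {
    for (i in seq_len(nrow(ani_table))) {
      q <- ani_table$query_id[i]; s <- ani_table$subject_id[i]
      shorter_af <- if (lens[[q]] <= lens[[s]]) ani_table$af_query[i]
                    else ani_table$af_subject[i]
      kk <- if (q < s) paste(q, s, sep = "\r") else paste(s, q, sep = "\r")
      assign(kk, c(ani_table$ani[i], shorter_af), envir = pair_ani)
    }
  }
  match_centroid <- function(a, b) {
    kk <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    v <- get0(kk, envir = pair_ani)
    !is.null(v) && v[1] >= ani_min && v[2] >= af_min
  }

  centroids <- character(0)
  member_of <- character(0)
  for (id in ids) {
    placed <- FALSE
    for (c_ in centroids) {
      if (match_centroid(id, c_)) {
        member_of[id] <- c_
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      member_of[id] <- id
    }
  }
  out <- data.frame(representative_id = unname(member_of[contigs$id]),
                    member_id = contigs$id, stringsAsFactors = FALSE)
  out[order(out$representative_id, out$member_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Select the representative contig of a vOTU
#'
#' The longest member wins; ties fall to the highest completeness, then
#' the lexicographically smallest id.
#'
#' @param member_ids Character vector of member contig ids.
#' @param contigs Data frame with `id`, `length`, `completeness`.
#' @return A single contig id.
#' @export
select_representative <- function(member_ids, contigs) {
  stopifnot(length(member_ids) >= 1)
  sub <- contigs[match(member_ids, contigs$id), , drop = FALSE]
  comp <- ifelse(is.na(sub$completeness), -1, sub$completeness)
  sub$id[order(-sub$length, -comp, sub$id)][1]
}
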