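# Family-level taxonomy by the majority rule, crAss-like flagging,
# lysogeny classification, and the marker-concatemer retention filter.

#' Family assignment by the protein-majority rule
#'
#' Hits below bitscore 50 are discarded (50 itself is kept); each protein
#' votes with its single best-bitscore hit (a tie across families makes
#' the protein abstain); a family is called only when strictly more than
#' half of ALL proteins of the vOTU vote for it.
#'
#' @param hits Data frame with `protein_index`, `reference_family`,
#'   `bitscore` for one vOTU.
#' @param n_proteins Total protein count of the vOTU.
#' @param min_bitscore Qualifying-hit floor (inclusive).
#' @return List with `family` (or `"unclassified"`) and
#'   `supporting_fraction`.
#' @export
assign_family_majority <- function(hits, n_proteins, min_bitscore = 50) {
  stopifnot(n_proteins >= 1)
  hits <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  if (nrow(hits) > 0 && length(unique(hits$protein_index)) > n_proteins) {
    stop("assign_family_majority: more matched proteins than n_proteins")
  }
  votes <- character(0)
  for (ix in split(seq_len(nrow(hits)), hits$protein_index)) {
    h <- hits[ix, , drop = FALSE]
    best <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    fams <- unique(best$reference_family)
    if (length(fams) == 1L) votes <- c(votes, fams)   # ties abstain
  }
  if (length(votes) == 0) {
    return(list(family = "unclassified", supporting_fraction = 0))
  }
  tab <- sort(table(votes), decreasing = TRUE)
  frac <- as.numeric(tab[1]) / n_proteins
  if (frac > 0.5) {
    list(family = names(tab)[1], supporting_fraction = frac)
  } else {
    list(family = "unclassified", supporting_fraction = frac)
  }
}

#' Flag a vOTU as crAss-like
#'
#' True iff, for some crAss-like reference, the union of its intervals in
#' blocks with identity >= 80% covers at least 50% of that reference's
#' length. Coverage is measured on the reference, not the query.
#'
#' @param blocks BLAST6-layout hits of one vOTU against the crAss-like
#'   reference set (`subject_id` = reference).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param min_identity,min_ref_cover Thresholds (percent).
#' @return Logical flag.
#' @export
flag_crass_like <- function(blocks, ref_lengths, min_identity = 80,
                            min_ref_cover = 50) {
  if (nrow(blocks) == 0) return(FALSE)
  unknown <- setdiff(unique(blocks$subject_id), names(ref_lengths))
  if (length(unknown) > 0) {
    stop("flag_crass_like: unknown reference id(s): ",
         paste(unknown, collapse = ", "))
  }
  blocks <- blocks[blocks$percent_identity >= min_identity, , drop = FALSE]
  if (nrow(blocks) == 0) return(FALSE)
  for (ref in unique(blocks$subject_id)) {
    h <- blocks[blocks$subject_id == ref, , drop = FALSE]
    s1 <- pmin(h$subject_start, h$subject_end)
    s2 <- pmax(h$subject_start, h$subject_end)
    cov <- 100 * interval_union_length(s1 - 1L, s2) / ref_lengths[[ref]]
    if (cov >= min_ref_cover) return(TRUE)
  }
  FALSE
}

#' Classify a vOTU as lysogenic
#'
#' Lysogenic iff the contig derives from an excised prophage or any of its
#' genes is labelled as an integrase.
#'
#' @param is_prophage Logical provenance flag.
#' @param gene_labels Character vector of gene label strings
#'   (comma-separated controlled vocabulary).
#' @return Logical flag.
#' @export
classify_lysogenic <- function(is_prophage, gene_labels = character(0)) {
  isTRUE(is_prophage) || any(grepl("(^|,)integrase($|,)", gene_labels))
}

#' Marker-concatemer retention filter
#'
#' Iterates to a fixed point: concatemers (rows) with <= `min_markers`
#' present markers are dropped, then marker columns present in
#' <= `min_prevalence` (fraction) of the remaining rows are dropped, and
#' so on until nothing changes. Both thresholds are strict.
#'
#' @param mat Logical/0-1 matrix, vOTU concatemers in rows, marker genes
#'   in columns.
#' @param min_markers Row retention threshold (keep rows with strictly
#'   more present markers).
#' @param min_prevalence Column retention threshold (keep columns present
#'   in strictly more than this fraction of remaining rows).
#' @return List with `rows` and `cols`: retained row/column names.
#' @export
filter_marker_concatemers <- function(mat, min_markers = 3, min_prevalence = 0.05) {
  stopifnot(nrow(mat) > 0, ncol(mat) > 0)
  m <- mat > 0
  rows <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cols <- colnames(m) %||% as.character(seq_len(ncol(m)))
  rownames(m) <- rows; colnames(m) <- cols
  repeat {
    keep_r <- rowSums(m) > min_markers
    m2 <- m[keep_r, , drop = FALSE]
    if (nrow(m2) == 0) {
      warning("filter_marker_concatemers: all concatemers eliminated")
      return(list(rows = character(0), cols = character(0)))
    }
    keep_c <- colMeans(m2) > min_prevalence
    m2 <- m2[, keep_c, drop = FALSE]
    if (identical(dim(m2), dim(m))) break
    m <- m2
  }
  list(rows = rownames(m), cols = colnames(m))
}

#' Assign taxonomy for a set of vOTUs
#'
#' Applies the majority rule per vOTU (vOTUs with a genus assignment from
#' an external gene-sharing network table are reported with that method
#' and skipped by the majority rule) and flags crAss-like vOTUs.
#'
#' @param protein_hits Data frame with `votu_id`, `protein_index`,
#'   `reference_family`, `bitscore`.
#' @param n_proteins Named integer vector: proteins per vOTU.
#' @param genus_table Optional data frame (`votu_id`, `genus`) from an
#'   external gene-sharing clustering.
#' @param crass_flags Optional named logical vector per vOTU.
#' @return Data frame `votu_id`, `rank`, `name`, `method`,
#'   `supporting_fraction`.
#' @export
assign_taxonomy <- function(protein_hits, n_proteins, genus_table = NULL,
                            crass_flags = NULL) {
  out <- lapply(names(n_proteins), function(vid) {
    if (!is.null(genus_table) && vid %in% genus_table$votu_id) {
      g <- genus_table$genus[match(vid, genus_table$votu_id)]
      return(data.frame(votu_id = vid, rank = "genus", name = g,
                        method = "genus_network", supporting_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    h <- protein_hits[protein_hits$votu_id == vid, , drop = FALSE]
    call <- assign_family_majority(h, n_proteins[[vid]])
    meth <- if (call$family == "unclassified") "unclassified" else "family_majority"
    data.frame(votu_id = vid,
               rank = if (meth == "unclassified") "none" else "family",
               name = call$family, method = meth,
               supporting_fraction = call$supporting_fraction,
               stringsAsFactors = FALSE)
  })
  tax <- do.call(rbind, out)
  if (!is.null(crass_flags)) {
    hit <- names(crass_flags)[crass_flags]
    tax$method[tax$votu_id %in% hit] <- "crass"
    tax$rank[tax$votu_id %in% hit] <- "group"
    tax$name[tax$votu_id %in% hit] <- "crAss-like"
  }
  tax
}
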