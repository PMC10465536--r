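# AMG curation cascade (complete-vMAG selection, flanking-context rules,
# genomic-island exclusion) and ARG calling/curation.

STRUCTURAL_LABELS <- c("capsid", "portal", "coat", "baseplate", "head",
                       "tail", "virion_structural", "terminase")
ISLAND_MARKERS <- c("endonuclease", "plasmid_stability", "lps_biosynthesis",
                    "GT11", "GT25", "nucleotidyltransferase",
                    "carbohydrate_kinase", "nucleotide_sugar_epimerase")
MOBILE_LABELS <- c("integrase", "transposase", "tail_fiber")

has_label <- function(labels, what) {
  grepl(paste0("(^|,)(", paste(what, collapse = "|"), ")($|,)"), labels)
}
has_prefixed_label <- function(labels, prefix, what) {
  grepl(paste0("(^|,)", prefix, ":(", paste(what, collapse = "|"), ")($|,)"),
        labels)
}

#' Select vMAGs eligible for AMG screening
#'
#' Only complete viral genomes longer than 10 kb are screened for AMGs
#' (incomplete contigs risk carrying residual host sequence).
#'
#' @param contigs Data frame with `id`, `length`, `quality_tier`.
#' @return Character vector of eligible contig ids.
#' @export
select_vmags <- function(contigs) {
  contigs$id[contigs$quality_tier == "complete" & contigs$length > 10000L]
}

#' Screen AMG candidates by genomic context on one vMAG
#'
#' An AMG candidate survives iff it is not the first or last gene on the
#' contig, its immediate neighbours are one viral hallmark plus one
#' viral-like gene (either order) or two hallmark genes, and its
#' annotation confidence category is 1 or 2.
#'
#' @param genes Gene feature table of one contig (as from
#'   [read_gene_table()]); normalized by start position internally.
#' @return Data frame of all AMG candidates with `keep` and `reason`
#'   (`"retained"`, `"end_of_contig"`, `"bad_flank"`, `"bad_category"`).
#' @export
screen_amg_context <- function(genes) {
  genes <- genes[order(genes$start), , drop = FALSE]
  cand <- which(has_label(genes$labels, "amg_candidate"))
  if (length(cand) == 0) {
    return(data.frame(contig_id = character(), gene_id = character(),
                      keep = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  n <- nrow(genes)
  res <- lapply(cand, function(i) {
    reason <- if (i == 1L || i == n) {
      "end_of_contig"
    } else {
      left <- genes$category[i - 1L]; right <- genes$category[i + 1L]
      flank_ok <- (left == "viral_hallmark" && right %in% c("viral_like", "viral_hallmark")) ||
        (right == "viral_hallmark" && left %in% c("viral_like", "viral_hallmark"))
      if (!flank_ok) "bad_flank"
      else if (!isTRUE(genes$amg_category[i] %in% c(1L, 2L))) "bad_category"
      else "retained"
    }
    data.frame(contig_id = genes$contig_id[i], gene_id = genes$gene_id[i],
               keep = reason == "retained", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Genomic-island exclusion filter for one vMAG
#'
#' A vMAG is dropped when (a) its viral-annotated genes consist only of
#' integrase/transposase/tail-fiber genes, (b) it carries none of the
#' eight viral structural gene classes, or (c) any gene carries a
#' genomic-island marker label (endonuclease, plasmid stability, LPS
#' biosynthesis, GT11/GT25, nucleotidyltransferase, carbohydrate kinase,
#' nucleotide sugar epimerase).
#'
#' @param genes Gene feature table of one contig.
#' @return List with `keep` (logical) and `reason` (`"retained"`,
#'   `"only_mobile_genes"`, `"no_structural"`, `"island_marker"`).
#' @export
filter_genomic_islands <- function(genes) {
  viral <- genes$category %in% c("viral_hallmark", "viral_like")
  mobile <- has_label(genes$labels, MOBILE_LABELS)
  if (!any(viral & !mobile)) {
    return(list(keep = FALSE, reason = "only_mobile_genes"))
  }
  if (!any(has_prefixed_label(genes$labels, "structural", STRUCTURAL_LABELS))) {
    return(list(keep = FALSE, reason = "no_structural"))
  }
  if (any(has_prefixed_label(genes$labels, "island_marker", ISLAND_MARKERS))) {
    return(list(keep = FALSE, reason = "island_marker"))
  }
  list(keep = TRUE, reason = "retained")
}

#' Run the full AMG curation cascade
#'
#' Applies [select_vmags()], then per contig the island filter and the
#' flanking-context screen. Every decision carries one reason code.
#'
#' @param contigs Data frame with `id`, `length`, `quality_tier`.
#' @param genes Gene feature table over all contigs.
#' @return Data frame of AMG candidates with `keep` and `reason` (contig
#'   level reasons `not_complete_vmag`, `only_mobile_genes`,
#'   `no_structural`, `island_marker` propagate to their AMGs).
#' @export
curate_amgs <- function(contigs, genes) {
  eligible <- select_vmags(contigs)
  cand_rows <- genes[has_label(genes$labels, "amg_candidate"), , drop = FALSE]
  out <- lapply(unique(cand_rows$contig_id), function(cid) {
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    cands <- screen_amg_context(g)
    if (!cid %in% eligible) {
      cands$keep <- FALSE
      cands$reason <- "not_complete_vmag"
      return(cands)
    }
    isl <- filter_genomic_islands(g)
    if (!isl$keep) {
      cands$keep <- FALSE
      cands$reason <- isl$reason
    }
    cands
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig_id = character(), gene_id = character(),
                      keep = logical(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Call and curate ARGs on viral contigs
#'
#' Hits must reach 80% sequence identity and 40% reference coverage (both
#' inclusive). Calls on the first or last gene of a contig are dropped
#' unless the single inward neighbour is viral (hallmark or viral-like).
#'
#' @param hits Data frame with `contig_id`, `gene_id`, `arg_class`,
#'   `percent_identity`, `reference_coverage`.
#' @param genes Gene feature table over all contigs.
#' @param min_identity,min_coverage Thresholds (inclusive).
#' @return Data frame of calls with `keep` and `reason` (`"retained"`,
#'   `"low_identity"`, `"low_coverage"`, `"end_no_viral_neighbor"`).
#' @export
call_args <- function(hits, genes, min_identity = 80, min_coverage = 40) {
  if (nrow(hits) == 0) {
    return(data.frame(contig_id = character(), gene_id = character(),
                      arg_class = character(), keep = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    g <- genes[genes$contig_id == h$contig_id, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    gi <- match(h$gene_id, g$gene_id)
    if (is.na(gi)) {
      warning("call_args: hit on unknown gene ", h$gene_id, "; skipped")
      return(NULL)
    }
    reason <- if (h$percent_identity < min_identity) {
      "low_identity"
    } else if (h$reference_coverage < min_coverage) {
      "low_coverage"
    } else if (gi == 1L || gi == nrow(g)) {
      inward <- if (gi == 1L) gi + 1L else gi - 1L
      if (g$category[inward] %in% c("viral_hallmark", "viral_like")) "retained"
      else "end_no_viral_neighbor"
    } else {
      "retained"
    }
    data.frame(contig_id = h$contig_id, gene_id = h$gene_id,
               arg_class = h$arg_class, keep = reason == "retained",
               reason = reason, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) {
    return(data.frame(contig_id = character(), gene_id = character(),
                      arg_class = character(), keep = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pick the representative contig per ARG class
#'
#' Highest completeness wins; ties fall to the fewest cellular genes,
#' then the lexicographically smallest id.
#'
#' @param candidate_ids Contig ids carrying the ARG class.
#' @param completeness Data frame with `contig_id`, `completeness`.
#' @param genes Gene feature table (for cellular gene counts).
#' @return A single contig id.
#' @export
pick_representative_arg_contig <- function(candidate_ids, completeness, genes) {
  stopifnot(length(candidate_ids) >= 1)
  comp <- completeness$completeness[match(candidate_ids, completeness$contig_id)]
  comp[is.na(comp)] <- -1
  n_cellular <- vapply(candidate_ids, function(cid) {
    sum(genes$category[genes$contig_id == cid] == "cellular")
  }, integer(1))
  candidate_ids[order(-comp, n_cellular, candidate_ids)][1]
}
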