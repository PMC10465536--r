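# Virome ecology: read-alignment filters, trimmed-mean coverage, richness
# per Gbp, core-virome prevalence classes, shared-vOTU structure and
# study-level clustering.

#' Filter read alignments by identity and aligned fraction
#'
#' Keeps alignments with identity >= 95% and aligned fraction of the read
#' >= 0.75 (both inclusive), the standard read-mapping filters for
#' abundance estimation.
#'
#' @param alignments Data frame with `percent_identity` (0--100) and
#'   `aligned_fraction_of_read` (0--1).
#' @param min_identity Identity threshold in percent.
#' @param min_aligned_frac Aligned-fraction threshold in `[0, 1]`.
#' @return The retained rows.
#' @export
filter_read_alignments <- function(alignments, min_identity = 95,
                                   min_aligned_frac = 0.75) {
  keep <- alignments$percent_identity >= min_identity &
    alignments$aligned_fraction_of_read >= min_aligned_frac
  alignments[keep, , drop = FALSE]
}

#' Trimmed-mean coverage of one vOTU in one sample
#'
#' If fewer than `min_covered_frac` of positions have non-zero depth the
#' abundance is 0. Otherwise the depths are sorted, `floor(trim_frac * L)`
#' positions are removed from each extreme, and the arithmetic mean of
#' the remainder is returned.
#'
#' @param depth Non-negative integer vector of per-position depths.
#' @param trim_frac Fraction trimmed from each tail.
#' @param min_covered_frac Covered-fraction gate.
#' @return Abundance value (>= 0).
#' @export
trimmed_mean_coverage <- function(depth, trim_frac = 0.05,
                                  min_covered_frac = 0.70) {
  if (length(depth) == 0) stop("trimmed_mean_coverage: empty depth vector")
  covered <- mean(depth > 0)
  if (covered < min_covered_frac) return(0)
  L <- length(depth)
  k <- floor(trim_frac * L)
  s <- sort(depth)
  if (2 * k >= L) return(0)
  mean(s[(k + 1):(L - k)])
}

#' Viral richness per billion base pairs
#'
#' @param n_detected_votus Number of vOTUs with abundance > 0.
#' @param sample_bases Total sequenced bases of the sample.
#' @return `n_detected_votus * 1e9 / sample_bases`.
#' @export
richness_per_gbp <- function(n_detected_votus, sample_bases) {
  if (sample_bases <= 0) stop("richness_per_gbp: sample_bases must be positive")
  n_detected_votus * 1e9 / sample_bases
}

#' Core-virome classification of a binary prevalence matrix
#'
#' Per group, a vOTU is core when its prevalence among the group's
#' samples satisfies the threshold rule; the default is strict
#' (`prevalence > threshold`), switchable to inclusive (`>=`) because
#' both readings of "at least/more than half" circulate. A vOTU observed
#' in exactly one sample overall is `individualized`; otherwise its class
#' counts the groups it occurs in. The global core is the intersection of
#' all per-group cores.
#'
#' @param mat Binary matrix, vOTUs in rows, samples in columns.
#' @param groups Character vector of group labels, one per column.
#' @param core_threshold Prevalence threshold (fraction).
#' @param strict Use strict `>` (default) or inclusive `>=`.
#' @return List: `classification` (data frame per vOTU), `core_sets`
#'   (named list of per-group core vOTU ids), `global_core` (ids),
#'   `venn_counts` (named vector over group-set memberships), and
#'   `threshold_rule` metadata string.
#' @export
classify_core <- function(mat, groups, core_threshold = 0.5, strict = TRUE) {
  stopifnot(length(groups) == ncol(mat))
  if (any(!mat %in% c(0L, 1L))) stop("classify_core: matrix must be binary")
  glabs <- unique(groups)
  if (any(table(groups) == 0)) stop("classify_core: empty group")
  prev_by_group <- vapply(glabs, function(g) {
    rowMeans(mat[, groups == g, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(prev_by_group))) {
    prev_by_group <- matrix(prev_by_group, nrow = nrow(mat),
                            dimnames = list(rownames(mat), glabs))
  }
  core_by_group <- if (strict) prev_by_group > core_threshold
                   else prev_by_group >= core_threshold
  occ_by_group <- vapply(glabs, function(g) {
    rowSums(mat[, groups == g, drop = FALSE]) > 0
  }, logical(nrow(mat)))
  if (is.null(dim(occ_by_group))) {
    occ_by_group <- matrix(occ_by_group, nrow = nrow(mat))
  }
  total_occ <- rowSums(mat)
  n_groups_present <- rowSums(occ_by_group)
  level_words <- c("one_level", "two_levels", "three_levels")
  class_ <- ifelse(total_occ == 1L, "individualized",
                   ifelse(total_occ == 0L, "absent",
                          ifelse(n_groups_present <= 3L,
                                 level_words[pmax(n_groups_present, 1L)],
                                 paste0(n_groups_present, "_levels"))))
  classification <- data.frame(
    votu_id = rownames(mat), class = class_,
    global_core = rowSums(core_by_group) == length(glabs),
    stringsAsFactors = FALSE)
  for (g in glabs) classification[[paste0("core_", g)]] <- core_by_group[, g]
  core_sets <- lapply(glabs, function(g) rownames(mat)[core_by_group[, g]])
  names(core_sets) <- glabs
  # Venn-style counts over per-group core membership patterns
  pat <- apply(core_by_group, 1L, function(r) paste(glabs[r], collapse = "&"))
  pat <- pat[nzchar(pat)]
  venn_counts <- if (length(pat)) table(pat) else table(character(0))
  list(classification = classification, core_sets = core_sets,
       global_core = rownames(mat)[rowSums(core_by_group) == length(glabs)],
       venn_counts = venn_counts,
       threshold_rule = sprintf("prevalence %s %.2f per group",
                                if (strict) ">" else ">=", core_threshold))
}

#' Shared-vOTU counts for sample pairs
#'
#' @param mat Binary matrix, vOTUs in rows, samples in columns.
#' @param sample_pairs Data frame with `sample_a`, `sample_b` and
#'   optionally `label` (e.g. same_group / different_group).
#' @return Long-format data frame: `sample_a`, `sample_b`, `label`,
#'   `shared`.
#' @export
shared_votus <- function(mat, sample_pairs) {
  stopifnot(all(c(sample_pairs$sample_a, sample_pairs$sample_b) %in% colnames(mat)))
  shared <- vapply(seq_len(nrow(sample_pairs)), function(i) {
    sum(mat[, sample_pairs$sample_a[i]] == 1L &
          mat[, sample_pairs$sample_b[i]] == 1L)
  }, integer(1))
  data.frame(sample_a = sample_pairs$sample_a,
             sample_b = sample_pairs$sample_b,
             label = sample_pairs$label %||% NA_character_,
             shared = shared, stringsAsFactors = FALSE)
}

#' Between-study shared-vOTU structure and hierarchical clustering
#'
#' Studies with 12 or fewer samples are discarded (strict > 12). The
#' between-study sharing count is the number of vOTUs present in at
#' least one sample of each study; the clustering dissimilarity is
#' `1 - shared(a, b) / min(richness_a, richness_b)` under average
#' linkage.
#'
#' @param mat Binary matrix, vOTUs in rows, samples in columns.
#' @param study_labels Study label per column.
#' @param min_samples Retention threshold (strict `>`).
#' @return List: `shared` (matrix), `dissimilarity` (dist), `hclust`
#'   (the average-linkage tree), `retained_studies`.
#' @export
cluster_studies <- function(mat, study_labels, min_samples = 12L) {
  stopifnot(length(study_labels) == ncol(mat))
  counts <- table(study_labels)
  keep <- names(counts)[counts > min_samples]
  if (length(keep) < 2L) stop("cluster_studies: fewer than 2 studies retained")
  presence <- vapply(keep, function(s) {
    rowSums(mat[, study_labels == s, drop = FALSE]) > 0
  }, logical(nrow(mat)))
  shared <- crossprod(presence + 0L)
  richness <- diag(shared)
  denom <- outer(richness, richness, pmin)
  diss <- 1 - shared / denom
  diag(diss) <- 0
  d <- stats::as.dist(diss)
  hc <- stats::hclust(d, method = "average")
  list(shared = shared, dissimilarity = d, hclust = hc,
       retained_studies = keep)
}

#' Abundance matrix from long-format depth profiles
#'
#' @param depth Data frame with `votu_id`, `sample_id`, `position`,
#'   `depth`.
#' @param ... Passed to [trimmed_mean_coverage()].
#' @return Numeric matrix, vOTUs in rows, samples in columns.
#' @export
abundance_from_depth <- function(depth, ...) {
  votus <- sort(unique(depth$votu_id))
  samples <- sort(unique(depth$sample_id))
  out <- matrix(0, nrow = length(votus), ncol = length(samples),
                dimnames = list(votus, samples))
  for (v in votus) {
    dv <- depth[depth$votu_id == v, , drop = FALSE]
    for (s in unique(dv$sample_id)) {
      d <- dv[dv$sample_id == s, , drop = FALSE]
      out[v, s] <- trimmed_mean_coverage(d$depth[order(d$position)], ...)
    }
  }
  out
}
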