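# Independent oracles used to cross-check the package implementations.

# Brute-force greedy centroid clustering, written independently of
# cluster_votus: plain data-frame lookups, no environments.
oracle_greedy_cluster <- function(contigs, ani_table, ani_min = 95, af_min = 85) {
  comp <- ifelse(is.na(contigs$completeness), -1, contigs$completeness)
  ord <- order(-contigs$length, -comp, contigs$id)
  ids <- contigs$id[ord]
  lookup <- function(a, b) {
    hit <- ani_table[(ani_table$query_id == a & ani_table$subject_id == b) |
                       (ani_table$query_id == b & ani_table$subject_id == a), ,
                     drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    hit[1, ]
  }
  len <- function(x) contigs$length[contigs$id == x]
  assignment <- character(0)
  centroids <- character(0)
  for (id in ids) {
    home <- NA_character_
    for (cen in centroids) {
      row <- lookup(id, cen)
      if (is.null(row)) next
      shorter_is_query <- len(row$query_id) <= len(row$subject_id)
      af_short <- if (shorter_is_query) row$af_query else row$af_subject
      if (row$ani >= ani_min && af_short >= af_min) { home <- cen; break }
    }
    if (is.na(home)) { centroids <- c(centroids, id); home <- id }
    assignment[id] <- home
  }
  data.frame(representative_id = unname(assignment[sort(ids)]),
             member_id = sort(ids), stringsAsFactors = FALSE)
}

# Random clustering instance: n contigs, random symmetric ANI/AF table.
random_ani_instance <- function(n, seed) {
  set.seed(seed)
  contigs <- data.frame(
    id = sprintf("c%02d", seq_len(n)),
    length = sample(5001:50000, n, replace = TRUE),
    completeness = round(runif(n, 0, 100), 1),
    stringsAsFactors = FALSE)
  pairs <- t(combn(contigs$id, 2))
  keep <- runif(nrow(pairs)) < 0.6
  pairs <- pairs[keep, , drop = FALSE]
  ani_table <- data.frame(
    query_id = pairs[, 1], subject_id = pairs[, 2],
    ani = round(runif(nrow(pairs), 80, 100), 2),
    af_query = round(runif(nrow(pairs), 50, 100), 2),
    af_subject = round(runif(nrow(pairs), 50, 100), 2),
    stringsAsFactors = FALSE)
  list(contigs = contigs, ani_table = ani_table)
}

# Naive substring search over both strands via Biostrings (independent of
# the grepl-based implementation).
oracle_spacer_match <- function(spacer, votu) {
  v <- Biostrings::DNAString(votu)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(spacer), v)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(spacer)), v)
  length(fwd) > 0 || length(rev) > 0
}

# Brute-force average-linkage agglomeration on a dissimilarity matrix;
# returns the sets merged at each step (size-invariant representation).
oracle_average_linkage <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(j, i) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best_d)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# A small, fast community for loops over many seeds.
small_sim_config <- function(seed) {
  sim_config(seed = seed, n_viruses = 8L,
             virus_length_range = c(5000L, 15000L),
             n_hosts = 4L, host_length_range = c(30000L, 60000L),
             samples_per_group = c(5L, 5L, 5L),
             n_dup_co = 0L, n_dup_far = 0L, n_dup_part = 0L)
}
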