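# Synthetic rumen virome communities with planted ground truth.
#
# The generator emulates the inputs a rumen-virome analysis consumes
# downstream of viral detection: viral contigs, host genomes carrying
# integrated prophages at controlled divergence, CRISPR arrays whose
# spacers are exact protospacer copies, annotated gene tables with planted
# AMG/ARG/island-marker configurations, ideal alignment hit tables, depth
# profiles and a group-structured prevalence matrix. Every planted feature
# carries a truth record stating the decision the pipeline should reach.

#' Build a validated simulation configuration
#'
#' Defaults describe the study conditions the package is designed around:
#' viral genomes of 5--200 kb, three dietary concentrate levels
#' (low/medium/high) with 84/80/119 cattle, and prophages planted at 3%
#' nucleotide divergence (comfortably inside the >90% identity host-link
#' rule).
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the configuration including this seed.
#' @param n_viruses Number of base viral genomes (near-duplicate variants
#'   for clustering are added on top, see `n_dup_co` etc.).
#' @param virus_length_range Length range (bp) of viral genomes.
#' @param n_hosts Number of host genomes (MAG-scale fragments).
#' @param host_length_range Length range (bp) of host genomes.
#' @param prophage_divergence Substitution fraction applied to planted
#'   prophages that should be recovered as host links.
#' @param n_spacers_per_array Spacers per planted CRISPR array (>= 2).
#' @param spacer_length Spacer length in bp.
#' @param group_labels Sample group names (dietary concentrate levels).
#' @param samples_per_group Samples per group, recycled to the groups.
#' @param prevalence_profile Optional numeric matrix of per-vOTU,
#'   per-group occurrence probabilities (rows recycled over all virus
#'   contigs). `NULL` builds the default profile: sparse background with
#'   three forced-core vOTUs and two group-restricted vOTUs.
#' @param n_dup_co,n_dup_far,n_dup_part Numbers of planted clustering
#'   variants: co-cluster copies (2% divergence, full length), distant
#'   copies (10% divergence, below the 95% ANI bar) and partial copies
#'   (60% of the parent, below the 85% aligned-fraction bar).
#' @param gc GC content of generated sequences.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_viruses = 24L,
                       virus_length_range = c(5000L, 200000L),
                       n_hosts = 8L,
                       host_length_range = c(80000L, 200000L),
                       prophage_divergence = 0.03,
                       n_spacers_per_array = 3L,
                       spacer_length = 32L,
                       group_labels = c("low", "medium", "high"),
                       samples_per_group = c(84L, 80L, 119L),
                       prevalence_profile = NULL,
                       n_dup_co = 4L, n_dup_far = 2L, n_dup_part = 2L,
                       gc = 0.5) {
  cfg <- list(seed = as.integer(seed), n_viruses = as.integer(n_viruses),
              virus_length_range = as.integer(virus_length_range),
              n_hosts = as.integer(n_hosts),
              host_length_range = as.integer(host_length_range),
              prophage_divergence = prophage_divergence,
              n_spacers_per_array = as.integer(n_spacers_per_array),
              spacer_length = as.integer(spacer_length),
              group_labels = as.character(group_labels),
              samples_per_group = as.integer(samples_per_group),
              prevalence_profile = prevalence_profile,
              n_dup_co = as.integer(n_dup_co),
              n_dup_far = as.integer(n_dup_far),
              n_dup_part = as.integer(n_dup_part),
              gc = gc)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop("invalid config: ", msg, call. = FALSE)
  stop_if(length(cfg$seed) != 1 || is.na(cfg$seed), "seed must be a single integer")
  stop_if(cfg$n_viruses < 1, "n_viruses must be >= 1")
  stop_if(cfg$n_hosts < 1, "n_hosts must be >= 1")
  for (rng in list(cfg$virus_length_range, cfg$host_length_range)) {
    stop_if(length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2],
            "length ranges must be positive and ordered")
  }
  stop_if(cfg$prophage_divergence < 0 || cfg$prophage_divergence > 1,
          "prophage_divergence must lie in [0,1]")
  stop_if(cfg$n_spacers_per_array < 2, "n_spacers_per_array must be >= 2")
  stop_if(cfg$spacer_length < 1, "spacer_length must be positive")
  stop_if(length(cfg$group_labels) < 1, "at least one group label required")
  stop_if(any(cfg$samples_per_group < 1), "every group needs >= 1 sample")
  stop_if(cfg$gc <= 0 || cfg$gc >= 1, "gc must lie in (0,1)")
  invisible(cfg)
}

#' Apply point substitutions at an exact divergence
#'
#' Substitutes exactly `floor(divergence * nchar(seq))` positions, drawn
#' without replacement, each to a different base, so that planted identity
#' equals `1 - realized divergence` exactly (no indels).
#'
#' @param seq DNA string over `ACGT`.
#' @param divergence Substitution fraction in `[0, 1]`.
#' @param seed Integer seed; the result is a pure function of
#'   `(seq, divergence, seed)`.
#' @return Mutated sequence of equal length.
#' @export
mutate_sequence <- function(seq, divergence, seed) {
  if (!nzchar(seq)) stop("mutate_sequence: empty sequence")
  if (divergence < 0 || divergence > 1) stop("divergence must lie in [0,1]")
  n <- nchar(seq)
  n_mut <- floor(divergence * n)
  if (n_mut == 0) return(seq)
  with_seed(seed, {
    pos <- sample.int(n, n_mut)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in pos) {
      alternatives <- DNA_BASES[DNA_BASES != chars[p]]
      chars[p] <- alternatives[sample.int(3L, 1L)]
    }
    paste(chars, collapse = "")
  })
}

empty_truth <- function() {
  data.frame(kind = character(), virus_id = character(),
             host_id = character(), start = integer(), end = integer(),
             expected_decision = character(), detail = character(),
             stringsAsFactors = FALSE)
}

truth_record <- function(kind, virus_id, host_id = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         expected_decision, detail = "") {
  data.frame(kind = kind, virus_id = virus_id, host_id = host_id,
             start = start, end = end,
             expected_decision = expected_decision, detail = detail,
             stringsAsFactors = FALSE)
}

#' Insert a mutated prophage copy into a host genome
#'
#' The virus sequence (optionally truncated upstream by the caller) is
#' mutated to the requested divergence and inserted at `position`
#' (0-based offset; insertion, not replacement).
#'
#' @param host_seq,virus_seq DNA strings.
#' @param divergence Substitution fraction applied to the inserted copy.
#' @param position 0-based insertion offset into the host.
#' @param seed Integer seed for the mutation.
#' @param host_id,virus_id Identifiers recorded in the truth record.
#' @param expected_decision `"link"`/`"no_link"`; what the host-link rule
#'   should decide for this plant.
#' @return `list(sequence = <new host>, truth = <one-row truth record>)`.
#' @export
plant_prophage <- function(host_seq, virus_seq, divergence, position, seed,
                           host_id = "host", virus_id = "virus",
                           expected_decision = "link") {
  if (position < 0) stop("plant_prophage: negative position")
  if (position > nchar(host_seq)) stop("plant_prophage: position beyond host end")
  insert <- mutate_sequence(virus_seq, divergence, seed)
  new_seq <- paste0(substr(host_seq, 1, position), insert,
                    substr(host_seq, position + 1, nchar(host_seq)))
  tr <- truth_record("prophage", virus_id, host_id,
                     start = position, end = position + nchar(insert),
                     expected_decision = expected_decision,
                     detail = sprintf("divergence=%s", fmt_num(divergence, 4)))
  list(sequence = new_seq, truth = tr)
}

#' Append a CRISPR array of exact protospacer copies to a host genome
#'
#' The array is `repeat (spacer repeat) x n_spacers`; each spacer is an
#' exact substring of the protospacer source, on the forward or
#' reverse-complement strand with probability 0.5 (recorded in the truth
#' record detail).
#'
#' @param host_seq Host DNA string (array appended at the end).
#' @param source_seq Protospacer source (viral genome).
#' @param n_spacers Number of spacers (>= 2, the minimum-two-repeat
#'   detection setting).
#' @param spacer_length Spacer length in bp.
#' @param repeat_seq Repeat sequence (length must fall in the detector's
#'   repeat window for round-trip tests).
#' @param seed Integer seed.
#' @param host_id,virus_id Identifiers for the truth records.
#' @return `list(sequence, truth, spacers)` where `spacers` is the planted
#'   spacer character vector (as embedded in the host).
#' @export
plant_crispr_array <- function(host_seq, source_seq, n_spacers, spacer_length,
                               repeat_seq = "GTGTTCCCCGCGTGAGCGGGGATAAACC",
                               seed = 1L, host_id = "host", virus_id = "virus") {
  if (n_spacers < 2) stop("plant_crispr_array: n_spacers must be >= 2")
  if (spacer_length > nchar(source_seq)) {
    stop("plant_crispr_array: spacer_length exceeds protospacer source length")
  }
  with_seed(seed, {
    starts <- sample.int(nchar(source_seq) - spacer_length + 1L, n_spacers,
                         replace = TRUE)
    strands <- sample(c("+", "-"), n_spacers, replace = TRUE)
    protospacers <- substring(source_seq, starts, starts + spacer_length - 1L)
    spacers <- ifelse(strands == "-", vapply(protospacers, revcomp, ""),
                      protospacers)
    array_seq <- paste0(repeat_seq,
                        paste0(spacers, repeat_seq, collapse = ""))
    offset <- nchar(host_seq)
    new_seq <- paste0(host_seq, array_seq)
    sp_start <- offset + nchar(repeat_seq) +
      (seq_len(n_spacers) - 1L) * (spacer_length + nchar(repeat_seq))
    truth <- do.call(rbind, lapply(seq_len(n_spacers), function(i) {
      truth_record("spacer", virus_id, host_id,
                   start = sp_start[i], end = sp_start[i] + spacer_length,
                   expected_decision = "link",
                   detail = sprintf("strand=%s;source_start=%d",
                                    strands[i], starts[i] - 1L))
    }))
    list(sequence = new_seq, truth = truth, spacers = unname(spacers))
  })
}

# Ideal alignment block for a substitution-only planted copy: one row of
# BLAST6 with the analytically known identity, mismatch count and coords.
ideal_block <- function(query_id, subject_id, qlen_total, q_from, q_to,
                        s_from, s_to, divergence, minus = FALSE) {
  len <- q_to - q_from + 1L
  mm <- floor(divergence * len)
  pid <- 100 * (len - mm) / len
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = pid, alignment_length = len,
             mismatches = mm, gap_opens = 0L,
             query_start = q_from, query_end = q_to,
             subject_start = if (minus) s_to else s_from,
             subject_end = if (minus) s_from else s_to,
             evalue = 0, bitscore = round(1.9 * len - 3 * mm, 1),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic community bundle
#'
#' Produces, deterministically under `config$seed`, a bundle with viral
#' and host sequences, gene tables, ideal hit tables, an ARG hit table,
#' depth profiles, a prevalence matrix with group structure, sample
#' metadata, host taxonomy, and truth records for every planted feature.
#'
#' @param config A [sim_config()].
#' @return A list bundle; see [write_community_bundle()] for the on-disk
#'   layout.
#' @export
generate_community <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, generate_community_impl(config))
}

generate_community_impl <- function(cfg) {
  seed_pool <- sample.int(2^30, 512)  # per-feature sub-seeds
  next_seed <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      seed_pool[i]
    }
  })

  ## --- viral genomes -------------------------------------------------
  nv <- cfg$n_viruses
  v_ids <- sprintf("v%03d", seq_len(nv))
  v_len <- sample(seq(cfg$virus_length_range[1], cfg$virus_length_range[2]), nv,
                  replace = TRUE)
  # first six viruses host the AMG fixtures: complete and >10 kb when the
  # configured range allows it
  amg_idx <- seq_len(min(6L, nv))
  if (cfg$virus_length_range[2] > 12000L) {
    lo <- max(cfg$virus_length_range[1], 12000L)
    v_len[amg_idx] <- sample(seq(lo, cfg$virus_length_range[2]),
                             length(amg_idx), replace = TRUE)
  }
  viruses <- setNames(vapply(v_len, random_dna, "", gc = cfg$gc), v_ids)

  completeness <- data.frame(contig_id = v_ids,
                             completeness = round(runif(nv, 50, 99), 1),
                             stringsAsFactors = FALSE)
  completeness$completeness[amg_idx] <- 100
  # one incomplete >10 kb virus: exercises the complete-only vMAG gate
  if (nv >= 7L) completeness$completeness[7L] <- 95

  ## --- clustering variants -------------------------------------------
  clusters_truth <- data.frame(member_id = v_ids, parent_id = v_ids,
                               co_cluster = TRUE, stringsAsFactors = FALSE)
  vv_hits <- empty_blast6()
  dup_specs <- list(
    list(n = cfg$n_dup_co, tag = "dupco", div = 0.02, frac = 1, co = TRUE),
    list(n = cfg$n_dup_far, tag = "dupfar", div = 0.10, frac = 1, co = FALSE),
    list(n = cfg$n_dup_part, tag = "duppart", div = 0.02, frac = 0.6, co = FALSE)
  )
  for (spec in dup_specs) {
    if (spec$n < 1) next
    parents <- v_ids[((seq_len(spec$n) - 1L) %% nv) + 1L]
    for (j in seq_len(spec$n)) {
      p <- parents[j]
      plen <- nchar(viruses[[p]])
      keep <- floor(spec$frac * plen)
      frag <- substr(viruses[[p]], 1, keep)
      did <- paste0(p, "_", spec$tag, j)
      viruses[[did]] <- mutate_sequence(frag, spec$div, next_seed())
      completeness <- rbind(completeness,
                            data.frame(contig_id = did,
                                       completeness = round(runif(1, 30, 70), 1),
                                       stringsAsFactors = FALSE))
      vv_hits <- rbind(vv_hits,
                       ideal_block(did, p, keep, 1L, keep, 1L, keep, spec$div))
      clusters_truth <- rbind(clusters_truth,
                              data.frame(member_id = did, parent_id = p,
                                         co_cluster = spec$co,
                                         stringsAsFactors = FALSE))
    }
  }
  completeness$quality_tier <- ifelse(
    completeness$completeness >= 100, "complete",
    ifelse(completeness$completeness >= 90, "high",
           ifelse(completeness$completeness >= 50, "medium", "low")))

  ## --- host genomes and taxonomy --------------------------------------
  nh <- cfg$n_hosts
  h_ids <- sprintf("g%02d", seq_len(nh))
  h_len <- sample(seq(cfg$host_length_range[1], cfg$host_length_range[2]), nh,
                  replace = TRUE)
  hosts <- setNames(vapply(h_len, random_dna, "", gc = cfg$gc), h_ids)

  phyla <- c("p__Bacteroidota", "p__Bacillota_A", "p__Methanobacteriota")
  genera <- c("g__Prevotella", "g__Ruminococcus", "g__Methanobrevibacter",
              "g__Fibrobacter", "g__Butyrivibrio")
  phylum_of_genus <- c(g__Prevotella = "p__Bacteroidota",
                       g__Ruminococcus = "p__Bacillota_A",
                       g__Methanobrevibacter = "p__Methanobacteriota",
                       g__Fibrobacter = "p__Bacteroidota",
                       g__Butyrivibrio = "p__Bacillota_A")
  gidx <- ((seq_len(nh) - 1L) %% length(genera)) + 1L
  genus <- genera[gidx]
  # hosts 1 and 2 share a genus but not a species; host 3 sits in a third
  # phylum so a shared virus yields a cross-phylum host range
  if (nh >= 2L) genus[2L] <- genus[1L]
  host_tax <- data.frame(
    genome_id = h_ids,
    domain = ifelse(genus == "g__Methanobrevibacter", "d__Archaea", "d__Bacteria"),
    phylum = unname(phylum_of_genus[genus]),
    class = "c__Clostridia", order = "o__Oscillospirales", family = "f__Ruminococcaceae",
    genus = genus,
    species = paste0("s__", sub("g__", "", genus), "_sp", seq_len(nh)),
    source = "MAG", stringsAsFactors = FALSE
  )

  ## --- prophage plants -------------------------------------------------
  truth <- empty_truth()
  vh_hits <- empty_blast6()
  plant_one <- function(vid, hid, divergence, frac = 1, expected, minus = FALSE) {
    vseq <- viruses[[vid]]
    vlen <- nchar(vseq)
    keep <- floor(frac * vlen)
    frag <- substr(vseq, 1, keep)
    if (minus) frag <- revcomp(frag)
    pos <- sample.int(nchar(hosts[[hid]]) + 1L, 1L) - 1L
    pl <- plant_prophage(hosts[[hid]], frag, divergence, pos, next_seed(),
                         host_id = hid, virus_id = vid,
                         expected_decision = expected)
    hosts[[hid]] <<- pl$sequence
    truth <<- rbind(truth, pl$truth)
    vh_hits <<- rbind(vh_hits,
                      ideal_block(vid, hid, vlen, 1L, keep,
                                  pos + 1L, pos + keep, divergence,
                                  minus = minus))
  }
  n_pos <- min(6L, nv, nh)
  for (i in seq_len(n_pos)) {
    plant_one(v_ids[i], h_ids[((i - 1L) %% nh) + 1L], cfg$prophage_divergence,
              expected = "link", minus = (i == 2L))
  }
  if (nv >= 1L && nh >= 3L) {          # cross-phylum second host for v001
    plant_one(v_ids[1L], h_ids[3L], cfg$prophage_divergence, expected = "link")
  }
  # negatives: divergence beyond the >90% identity rule, and a short
  # fragment failing both the 2.5 kb block rule and the 75% coverage rule
  n_negdiv <- if (nv >= n_pos + 2L) 2L else 0L
  for (i in seq_len(n_negdiv)) {
    plant_one(v_ids[n_pos + i], h_ids[((i - 1L) %% nh) + 1L], 0.15,
              expected = "no_link")
  }
  n_negfrag <- if (nv >= n_pos + n_negdiv + 2L) 2L else 0L
  for (i in seq_len(n_negfrag)) {
    vid <- v_ids[n_pos + n_negdiv + i]
    frac <- 2000 / nchar(viruses[[vid]])
    plant_one(vid, h_ids[((i + 1L) %% nh) + 1L], 0, frac = frac,
              expected = "no_link")
  }

  ## --- CRISPR arrays ----------------------------------------------------
  n_arrays <- min(4L, nh, nv)
  spacer_sources <- v_ids[seq_len(n_arrays)]
  for (i in seq_len(n_arrays)) {
    hid <- h_ids[nh - i + 1L]
    res <- plant_crispr_array(hosts[[hid]], viruses[[spacer_sources[i]]],
                              cfg$n_spacers_per_array, cfg$spacer_length,
                              seed = next_seed(), host_id = hid,
                              virus_id = spacer_sources[i])
    hosts[[hid]] <- res$sequence
    tr <- res$truth
    if (i == 1L) {
      # decoy: corrupt the first spacer by one substitution in the host
      sp_start <- tr$start[1L]
      pos <- sp_start + sample.int(cfg$spacer_length, 1L)  # 1-based in host
      base <- substr(hosts[[hid]], pos, pos)
      substr(hosts[[hid]], pos, pos) <- DNA_BASES[DNA_BASES != base][1L]
      tr$expected_decision[1L] <- "no_link"
      tr$detail[1L] <- paste0(tr$detail[1L], ";decoy=1mismatch")
    }
    truth <- rbind(truth, tr)
  }

  ## --- gene tables and planted AMG/ARG fixtures ------------------------
  genes_list <- list()
  arg_hits <- data.frame(contig_id = character(), gene_id = character(),
                         arg_class = character(), percent_identity = numeric(),
                         reference_coverage = numeric(), stringsAsFactors = FALSE)
  all_v_ids <- names(viruses)
  for (vid in all_v_ids) {
    L <- nchar(viruses[[vid]])
    starts <- seq(0L, L - 900L, by = 1000L)
    if (length(starts) < 3L) starts <- seq(0L, max(0L, L - 300L), by = 300L)
    g <- data.frame(
      contig_id = vid,
      gene_id = sprintf("%s_g%03d", vid, seq_along(starts)),
      start = starts, end = pmin(starts + 900L, L),
      strand = sample(c("+", "-"), length(starts), replace = TRUE),
      category = sample(c("viral_hallmark", "viral_like", "cellular", "unannotated"),
                        length(starts), replace = TRUE,
                        prob = c(0.3, 0.3, 0.2, 0.2)),
      labels = "", amg_category = NA_integer_, stringsAsFactors = FALSE
    )
    genes_list[[vid]] <- g
  }
  put <- function(vid, idx, category = NULL, labels = NULL, amg = NULL) {
    g <- genes_list[[vid]]
    if (!is.null(category)) g$category[idx] <- category
    if (!is.null(labels)) g$labels[idx] <- labels
    if (!is.null(amg)) g$amg_category[idx] <- amg
    genes_list[[vid]] <<- g
  }
  add_amg_truth <- function(vid, idx, expected, reason = "") {
    g <- genes_list[[vid]]
    truth <<- rbind(truth, truth_record(
      "amg", vid, NA_character_, g$start[idx], g$end[idx],
      expected_decision = expected, detail = reason))
  }
  # integrase carriers for lysogeny classification
  lys_idx <- seq_len(min(2L, nv))
  for (i in lys_idx) put(v_ids[i], 2L, category = "viral_like", labels = "integrase")

  amg_ok <- function(vid, mid) {   # hallmark | AMG | viral_like, structural present
    put(vid, mid - 1L, category = "viral_hallmark")
    put(vid, mid + 1L, category = "viral_like")
    put(vid, mid, category = "cellular", labels = "amg_candidate", amg = 1L)
  }
  ngene <- function(vid) nrow(genes_list[[vid]])
  if (nv >= 6L && all(vapply(v_ids[1:6], ngene, 0L) >= 5L)) {
    mids <- vapply(v_ids[1:6], function(v) as.integer(ceiling(ngene(v) / 2)), 0L)
    # v001: retained AMG (good flanks, cat 1, structural gene, clean contig)
    amg_ok(v_ids[1], mids[1])
    put(v_ids[1], ngene(v_ids[1]) - 1L, category = "viral_hallmark",
        labels = "structural:capsid")
    add_amg_truth(v_ids[1], mids[1], "keep")
    # v002: AMG as last gene -> dropped (contig end)
    put(v_ids[2], ngene(v_ids[2]), category = "cellular",
        labels = "amg_candidate", amg = 1L)
    put(v_ids[2], 3L, labels = "structural:portal", category = "viral_hallmark")
    add_amg_truth(v_ids[2], ngene(v_ids[2]), "drop", "end_of_contig")
    # v003: AMG flanked by two cellular genes -> dropped
    put(v_ids[3], mids[3] - 1L, category = "cellular")
    put(v_ids[3], mids[3] + 1L, category = "cellular")
    put(v_ids[3], mids[3], category = "cellular", labels = "amg_candidate", amg = 1L)
    put(v_ids[3], 3L, labels = "structural:terminase", category = "viral_hallmark")
    add_amg_truth(v_ids[3], mids[3], "drop", "bad_flank")
    # v004: good flanks but DRAMv-style category 3 -> dropped
    amg_ok(v_ids[4], mids[4])
    put(v_ids[4], mids[4], amg = 3L)
    put(v_ids[4], 3L, labels = "structural:head", category = "viral_hallmark")
    add_amg_truth(v_ids[4], mids[4], "drop", "bad_category")
    # v005: clean AMG context but an island-marker gene on the contig
    amg_ok(v_ids[5], mids[5])
    put(v_ids[5], 3L, labels = "structural:portal", category = "viral_hallmark")
    put(v_ids[5], ngene(v_ids[5]) - 1L, category = "cellular",
        labels = "island_marker:GT25")
    add_amg_truth(v_ids[5], mids[5], "drop", "island_marker")
    # v006: clean AMG context but no structural gene anywhere
    amg_ok(v_ids[6], mids[6])
    g6 <- genes_list[[v_ids[6]]]
    g6$labels[grepl("structural:", g6$labels)] <- ""
    genes_list[[v_ids[6]]] <- g6
    add_amg_truth(v_ids[6], mids[6], "drop", "no_structural")
  }

  # ARG fixtures: identity/coverage boundaries and the end-of-contig rule
  add_arg <- function(vid, idx, arg_class, pid, cov, expected, reason = "") {
    g <- genes_list[[vid]]
    arg_hits <<- rbind(arg_hits, data.frame(
      contig_id = vid, gene_id = g$gene_id[idx], arg_class = arg_class,
      percent_identity = pid, reference_coverage = cov,
      stringsAsFactors = FALSE))
    truth <<- rbind(truth, truth_record(
      "arg", vid, NA_character_, g$start[idx], g$end[idx],
      expected_decision = expected,
      detail = paste0(arg_class, if (nzchar(reason)) paste0(";", reason))))
  }
  if (nv >= 11L && all(vapply(v_ids[7:11], ngene, 0L) >= 4L)) {
    mid7 <- as.integer(ceiling(ngene(v_ids[7]) / 2))
    add_arg(v_ids[7], mid7, "tetW", 85, 60, "keep")
    add_arg(v_ids[8], as.integer(ceiling(ngene(v_ids[8]) / 2)),
            "tetO", 85, 39, "drop", "low_coverage")
    add_arg(v_ids[9], as.integer(ceiling(ngene(v_ids[9]) / 2)),
            "vanG", 79, 60, "drop", "low_identity")
    put(v_ids[10], ngene(v_ids[10]) - 1L, category = "cellular")
    add_arg(v_ids[10], ngene(v_ids[10]), "vanWG", 90, 80,
            "drop", "end_no_viral_neighbor")
    put(v_ids[11], ngene(v_ids[11]) - 1L, category = "viral_hallmark")
    add_arg(v_ids[11], ngene(v_ids[11]), "aph3", 90, 80, "keep",
            "end_viral_neighbor")
  }
  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL

  ## --- protein hit table for the family majority rule -------------------
  families <- c("Siphoviridae", "Myoviridae", "Podoviridae")
  protein_hits <- do.call(rbind, lapply(seq_along(all_v_ids), function(i) {
    vid <- all_v_ids[i]
    np <- nrow(genes_list[[vid]])
    fam <- families[((i - 1L) %% 3L) + 1L]
    # even-indexed contigs get a >50% majority; odd ones stay unclassified
    n_hit <- if (i %% 2L == 0L) ceiling(np * 0.6) else floor(np * 0.4)
    if (n_hit == 0L) return(NULL)
    data.frame(votu_id = vid, protein_index = seq_len(n_hit),
               reference_family = fam,
               bitscore = round(runif(n_hit, 60, 300), 1),
               stringsAsFactors = FALSE)
  }))

  ## --- samples, prevalence, depth ---------------------------------------
  groups <- cfg$group_labels
  spg <- rep_len(cfg$samples_per_group, length(groups))
  sample_group <- rep(groups, spg)
  ns <- length(sample_group)
  if (ns < 1L) stop("invalid config: zero samples")
  s_ids <- sprintf("s%03d", seq_len(ns))
  metadata <- data.frame(
    sample_id = s_ids, group = sample_group,
    breed = rep_len(c("Holstein", "Jersey"), ns),
    study = sprintf("st%d", ((seq_len(ns) - 1L) %% 4L) + 1L),
    sample_bases = sample(seq(2e9, 8e9, by = 1e6), ns, replace = TRUE),
    stringsAsFactors = FALSE
  )

  nvt <- length(all_v_ids)
  prof <- cfg$prevalence_profile
  if (is.null(prof)) {
    prof <- matrix(0.08, nrow = nvt, ncol = length(groups),
                   dimnames = list(all_v_ids, groups))
    core_planted <- seq_len(min(3L, nvt))
    prof[core_planted, ] <- 1
    if (nvt >= 4L) prof[4L, ] <- c(0.9, rep(0.02, length(groups) - 1L))
    if (nvt >= 5L && length(groups) >= 2L) {
      prof[5L, ] <- c(0.02, 0.9, rep(0.02, length(groups) - 2L))
    }
  } else {
    prof <- matrix(rep_len(t(prof), nvt * length(groups)), nrow = nvt,
                   byrow = TRUE, dimnames = list(all_v_ids, groups))
  }
  prev <- matrix(0L, nrow = nvt, ncol = ns, dimnames = list(all_v_ids, s_ids))
  for (gi in seq_along(groups)) {
    cols <- which(sample_group == groups[gi])
    draws <- matrix(runif(nvt * length(cols)) < prof[, gi], nrow = nvt)
    prev[, cols] <- draws + 0L
  }
  if (nvt >= 6L) {                     # an individualized vOTU by construction
    prev[6L, ] <- 0L
    prev[6L, 1L] <- 1L
  }
  # truth: strict >50% prevalence in every group (the realized matrix is
  # the ground truth the ecology stage must recover)
  core_real <- apply(prev, 1L, function(row) {
    all(vapply(groups, function(g) {
      mean(row[sample_group == g]) > 0.5
    }, logical(1)))
  })
  for (vid in all_v_ids[core_real]) {
    truth <- rbind(truth, truth_record("core_votu", vid,
                                       expected_decision = "core"))
  }

  depth_votus <- all_v_ids[order(nchar(viruses), all_v_ids)][
    seq_len(min(3L, nvt))]
  depth_samples <- s_ids[seq_len(min(2L, ns))]
  depth <- do.call(rbind, lapply(depth_votus, function(vid) {
    L <- nchar(viruses[[vid]])
    do.call(rbind, lapply(seq_along(depth_samples), function(si) {
      d <- rpois(L, 8)
      if (vid == depth_votus[1L] && si == 1L) {
        d[seq_len(floor(0.4 * L))] <- 0L  # fails the 70% covered-fraction gate
      }
      data.frame(votu_id = vid, sample_id = depth_samples[si],
                 position = seq_len(L), depth = d, stringsAsFactors = FALSE)
    }))
  }))

  bundle <- list(config = cfg, viruses = viruses, hosts = hosts,
                 completeness = completeness, genes = genes,
                 protein_hits = protein_hits,
                 virus_virus_hits = vv_hits, virus_host_hits = vh_hits,
                 arg_hits = arg_hits, host_taxonomy = host_tax,
                 prevalence = prev, metadata = metadata, depth = depth,
                 truth = truth, clusters_truth = clusters_truth)
  check_bundle(bundle)
  bundle
}

check_bundle <- function(b) {
  seq_ids <- c(names(b$viruses), names(b$hosts))
  stopifnot(!anyDuplicated(seq_ids))
  stopifnot(all(b$genes$contig_id %in% seq_ids))
  stopifnot(all(b$truth$virus_id %in% names(b$viruses)))
  hid <- b$truth$host_id[!is.na(b$truth$host_id)]
  stopifnot(all(hid %in% names(b$hosts)))
  carrier <- ifelse(is.na(b$truth$host_id), b$truth$virus_id, b$truth$host_id)
  lens <- nchar(c(b$viruses, b$hosts))[carrier]
  has_iv <- !is.na(b$truth$start)
  stopifnot(all(b$truth$start[has_iv] >= 0),
            all(b$truth$end[has_iv] <= lens[has_iv]))
  invisible(b)
}

#' Write a community bundle to a directory
#'
#' Emits FASTA (80-column wrap), GFF3-like gene tables, BLAST6 hit tables,
#' depth/prevalence/metadata/truth TSVs and a YAML config echo. Identical
#' configurations produce byte-identical files.
#'
#' @param bundle Result of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_community_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$viruses, p("viruses.fna"))
  write_fasta(bundle$hosts, p("hosts.fna"))
  write_gene_table(bundle$genes, p("genes.tsv"))
  write_blast6(bundle$virus_virus_hits, p("virus_virus_hits.tsv"))
  write_blast6(bundle$virus_host_hits, p("virus_host_hits.tsv"))
  write_tsv_rv(bundle$completeness, p("completeness.tsv"))
  write_tsv_rv(bundle$protein_hits, p("protein_hits.tsv"))
  ah <- bundle$arg_hits
  ah$percent_identity <- fmt_num(ah$percent_identity, 1)
  ah$reference_coverage <- fmt_num(ah$reference_coverage, 1)
  write_tsv_rv(ah, p("arg_hits.tsv"))
  write_tsv_rv(bundle$host_taxonomy, p("host_taxonomy.tsv"))
  write_prevalence_matrix(bundle$prevalence, p("prevalence.tsv"))
  write_tsv_rv(bundle$metadata, p("metadata.tsv"))
  write_tsv_rv(bundle$depth, p("depth.tsv"))
  tr <- bundle$truth
  write_tsv_rv(tr, p("truth.tsv"))
  write_tsv_rv(bundle$clusters_truth, p("clusters_truth.tsv"))
  cfg <- bundle$config
  cfg_lines <- c(
    paste0("seed: ", cfg$seed),
    paste0("n_viruses: ", cfg$n_viruses),
    paste0("virus_length_range: [", paste(cfg$virus_length_range, collapse = ", "), "]"),
    paste0("n_hosts: ", cfg$n_hosts),
    paste0("host_length_range: [", paste(cfg$host_length_range, collapse = ", "), "]"),
    paste0("prophage_divergence: ", cfg$prophage_divergence),
    paste0("n_spacers_per_array: ", cfg$n_spacers_per_array),
    paste0("spacer_length: ", cfg$spacer_length),
    paste0("group_labels: [", paste(cfg$group_labels, collapse = ", "), "]"),
    paste0("samples_per_group: [", paste(cfg$samples_per_group, collapse = ", "), "]")
  )
  con <- file(p("config.yaml"), open = "wb")
  writeLines(cfg_lines, con, sep = "\n")
  close(con)
  invisible(dir)
}
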