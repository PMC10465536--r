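# Pipeline orchestration: stage functions over an on-disk bundle, a run
# manifest with checksums and record counts, and cache-aware reruns.

PIPELINE_STAGES <- c("simulate", "cluster", "taxonomy", "host", "curate",
                     "ecology")

#' Build a validated pipeline configuration
#'
#' @param seed Integer seed for the synthetic community.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param ani_min,af_min vOTU clustering thresholds (percent, in
#'   `[0, 100]`).
#' @param core_threshold Core-virome prevalence threshold (fraction).
#' @param core_strict Strict (`>`) or inclusive (`>=`) core rule.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), ani_min = 95, af_min = 85,
                            core_threshold = 0.5, core_strict = TRUE) {
  cfg <- list(seed = as.integer(seed), sim = sim, ani_min = ani_min,
              af_min = af_min, core_threshold = core_threshold,
              core_strict = isTRUE(core_strict))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("config error at '%s': %s", field, msg), call. = FALSE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) err("seed", "must be one integer")
  if (!is.numeric(cfg$ani_min) || cfg$ani_min < 0 || cfg$ani_min > 100) {
    err("ani_min", "must lie in [0, 100]")
  }
  if (!is.numeric(cfg$af_min) || cfg$af_min < 0 || cfg$af_min > 100) {
    err("af_min", "must lie in [0, 100]")
  }
  if (cfg$core_threshold < 0 || cfg$core_threshold > 1) {
    err("core_threshold", "must lie in [0, 1]")
  }
  if (!is.list(cfg$sim)) err("sim", "must be a list of sim_config overrides")
  do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))  # validates overrides
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with `seed`, `ani_min`, `af_min`,
#'   `core_threshold`, `core_strict` and an optional `sim:` block.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(seed = y$seed %||% 1L, sim = y$sim %||% list(),
                  ani_min = y$ani_min %||% 95, af_min = y$af_min %||% 85,
                  core_threshold = y$core_threshold %||% 0.5,
                  core_strict = y$core_strict %||% TRUE)
}

stage_io <- function(outdir) {
  sim <- file.path(outdir, "sim")
  list(
    simulate = list(
      inputs = character(0),
      outputs = file.path(sim, c("viruses.fna", "hosts.fna", "genes.tsv",
                                 "virus_virus_hits.tsv", "virus_host_hits.tsv",
                                 "completeness.tsv", "protein_hits.tsv",
                                 "arg_hits.tsv", "host_taxonomy.tsv",
                                 "prevalence.tsv", "metadata.tsv", "depth.tsv",
                                 "truth.tsv", "clusters_truth.tsv",
                                 "config.yaml"))),
    cluster = list(
      inputs = file.path(sim, c("viruses.fna", "virus_virus_hits.tsv",
                                "completeness.tsv")),
      outputs = file.path(outdir, c("ani_table.tsv", "clusters.tsv"))),
    taxonomy = list(
      inputs = file.path(sim, c("protein_hits.tsv", "genes.tsv")),
      outputs = file.path(outdir, c("taxonomy.tsv", "lysogeny.tsv"))),
    host = list(
      inputs = file.path(sim, c("viruses.fna", "hosts.fna",
                                "virus_host_hits.tsv", "host_taxonomy.tsv")),
      outputs = file.path(outdir, c("host_links.tsv", "host_range.tsv",
                                    "genus_stats.tsv", "spacers.tsv"))),
    curate = list(
      inputs = file.path(sim, c("genes.tsv", "completeness.tsv",
                                "arg_hits.tsv")),
      outputs = file.path(outdir, c("amg_curation.tsv", "arg_calls.tsv"))),
    ecology = list(
      inputs = file.path(sim, c("depth.tsv", "prevalence.tsv", "metadata.tsv")),
      outputs = file.path(outdir, c("abundance.tsv", "core_classification.tsv",
                                    "richness.tsv", "shared_counts.tsv",
                                    "study_clusters.tsv")))
  )
}

checksums <- function(paths) {
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  setNames(out, paths)
}

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes the stages `simulate -> cluster -> taxonomy -> host ->
#' curate -> ecology` in dependency order and writes a run manifest.
#' On a rerun with an unchanged configuration, stages whose input and
#' output checksums are unchanged are skipped and marked as cache hits.
#'
#' @param config A `pipeline_config`, a list of its fields, or a path to
#'   a YAML config file.
#' @param outdir Output directory.
#' @param stages Subset of stages to run (dependencies must already have
#'   outputs on disk).
#' @param force Rerun stages even when cached.
#' @param log_level One of `"quiet"`, `"info"`.
#' @return The run manifest (list), invisibly written to
#'   `outdir/manifest.yaml`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = PIPELINE_STAGES, force = FALSE,
                         log_level = "info") {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  validate_pipeline_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  io <- stage_io(outdir)
  say <- function(...) if (log_level != "quiet") message(sprintf(...))

  prev_manifest <- NULL
  mf_path <- file.path(outdir, "manifest.yaml")
  if (file.exists(mf_path)) {
    prev_manifest <- tryCatch(yaml::read_yaml(mf_path), error = function(e) NULL)
  }

  manifest <- list(ruleset = RULESET_VERSION,
                   config = unclass(config)[c("seed", "ani_min", "af_min",
                                              "core_threshold", "core_strict")],
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())

  for (st in PIPELINE_STAGES) {
    if (!st %in% stages) next
    spec <- io[[st]]
    miss <- spec$inputs[!file.exists(spec$inputs)]
    if (length(miss) > 0) {
      stop(sprintf("stage '%s': missing input file(s): %s", st,
                   paste(miss, collapse = ", ")))
    }
    in_sums <- checksums(spec$inputs)
    cached <- FALSE
    if (!force && !is.null(prev_manifest)) {
      ps <- prev_manifest$stages[[st]]
      same_cfg <- identical(prev_manifest$config, manifest$config)
      norm <- function(x) as.character(unname(unlist(x)))
      if (!is.null(ps) && same_cfg &&
          identical(norm(ps$input_md5), norm(in_sums)) &&
          all(file.exists(spec$outputs)) &&
          identical(norm(ps$output_md5), norm(checksums(spec$outputs)))) {
        cached <- TRUE
      }
    }
    if (cached) {
      say("[%s] cache hit, skipped", st)
      counts <- prev_manifest$stages[[st]]$records
    } else {
      say("[%s] running", st)
      counts <- run_stage(st, config, outdir)
    }
    manifest$stages[[st]] <- list(
      cached = cached,
      input_md5 = as.list(in_sums),
      output_md5 = as.list(checksums(spec$outputs)),
      records = counts)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, mf_path)
  invisible(manifest)
}

run_stage <- function(stage, config, outdir) {
  sim <- file.path(outdir, "sim")
  p <- function(f) file.path(outdir, f)
  ps <- function(f) file.path(sim, f)
  switch(stage,
    simulate = {
      bundle <- generate_community(do.call(sim_config,
                                           c(list(seed = config$seed), config$sim)))
      write_community_bundle(bundle, sim)
      list(viruses = length(bundle$viruses), hosts = length(bundle$hosts),
           truth_records = nrow(bundle$truth))
    },
    cluster = {
      comp <- read_tsv_rv(ps("completeness.tsv"))
      contigs <- load_contigs(ps("viruses.fna"), completeness = comp)
      hits <- read_blast6(ps("virus_virus_hits.tsv"))
      lens <- setNames(contigs$length, contigs$id)
      ani <- ani_table_from_hits(hits, lens)
      ani_out <- ani
      ani_out$ani <- fmt_num(ani_out$ani, 3)
      ani_out$af_query <- fmt_num(ani_out$af_query, 3)
      ani_out$af_subject <- fmt_num(ani_out$af_subject, 3)
      write_tsv_rv(ani_out, p("ani_table.tsv"))
      cl <- cluster_votus(contigs, ani, ani_min = config$ani_min,
                          af_min = config$af_min)
      write_tsv_rv(cl, p("clusters.tsv"))
      list(contigs_in = nrow(contigs), votus_out = length(unique(cl$representative_id)))
    },
    taxonomy = {
      ph <- read_tsv_rv(ps("protein_hits.tsv"))
      genes <- read_gene_table(ps("genes.tsv"))
      np_tab <- table(genes$contig_id)
      n_proteins <- setNames(as.integer(np_tab), names(np_tab))
      tax <- assign_taxonomy(ph, n_proteins)
      tax$supporting_fraction <- ifelse(is.na(tax$supporting_fraction), "NA",
                                        fmt_num(tax$supporting_fraction, 4))
      write_tsv_rv(tax, p("taxonomy.tsv"))
      lys <- vapply(names(n_proteins), function(cid) {
        classify_lysogenic(FALSE, genes$labels[genes$contig_id == cid])
      }, logical(1))
      write_tsv_rv(data.frame(votu_id = names(lys), lysogenic = unname(lys),
                              stringsAsFactors = FALSE), p("lysogeny.tsv"))
      list(votus = length(n_proteins),
           classified = sum(tax$method != "unclassified"))
    },
    host = {
      viruses <- read_fasta(ps("viruses.fna"))
      hosts <- read_fasta(ps("hosts.fna"))
      tax <- read_tsv_rv(ps("host_taxonomy.tsv"))
      hits <- read_blast6(ps("virus_host_hits.tsv"))
      vlens <- setNames(nchar(viruses), names(viruses))
      pro <- call_prophage_links(hits, vlens)
      spacers <- do.call(rbind, lapply(names(hosts), function(h) {
        detect_crispr_arrays(hosts[[h]], genome_id = h)
      }))
      if (is.null(spacers)) spacers <- empty_spacers()
      write_tsv_rv(spacers, p("spacers.tsv"))
      spa <- call_spacer_links(spacers, viruses)
      links <- rbind(pro, spa)
      out_links <- links
      out_links$votu_coverage <- ifelse(is.na(out_links$votu_coverage), "NA",
                                        fmt_num(out_links$votu_coverage, 4))
      write_tsv_rv(out_links, p("host_links.tsv"))
      hr <- aggregate_host_range(links, tax)
      write_tsv_rv(hr, p("host_range.tsv"))
      lys_path <- p("lysogeny.tsv")
      if (file.exists(lys_path)) {
        ldf <- read_tsv_rv(lys_path)
        lys <- setNames(as.logical(ldf$lysogenic), ldf$votu_id)
        gs <- genus_stats(links, tax, lys)
        gs$phages_per_genome <- fmt_num(gs$phages_per_genome, 4)
        gs$lysogeny_rate <- fmt_num(gs$lysogeny_rate, 2)
        write_tsv_rv(gs, p("genus_stats.tsv"))
      } else {
        write_tsv_rv(data.frame(), p("genus_stats.tsv"))
      }
      list(prophage_links = nrow(pro), spacer_links = nrow(spa),
           spacers_detected = nrow(spacers))
    },
    curate = {
      genes <- read_gene_table(ps("genes.tsv"))
      comp <- read_tsv_rv(ps("completeness.tsv"))
      contigs <- data.frame(id = comp$contig_id,
                            length = NA_integer_,
                            quality_tier = comp$quality_tier,
                            stringsAsFactors = FALSE)
      lens <- vapply(split(genes$end, genes$contig_id), max, 0)
      # contig length from FASTA (gene span is a lower bound only)
      viruses <- read_fasta(ps("viruses.fna"))
      contigs$length <- nchar(viruses)[contigs$id]
      amg <- curate_amgs(contigs, genes)
      write_tsv_rv(amg, p("amg_curation.tsv"))
      ah <- read_tsv_rv(ps("arg_hits.tsv"))
      args_ <- call_args(ah, genes)
      write_tsv_rv(args_, p("arg_calls.tsv"))
      list(amg_candidates = nrow(amg), amg_retained = sum(amg$keep),
           arg_hits = nrow(ah), arg_retained = sum(args_$keep))
    },
    ecology = {
      depth <- read_tsv_rv(ps("depth.tsv"))
      ab <- abundance_from_depth(depth)
      ab_df <- data.frame(votu_id = rownames(ab),
                          apply(ab, 2, fmt_num, digits = 4),
                          check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv_rv(ab_df, p("abundance.tsv"))
      prev <- read_prevalence_matrix(ps("prevalence.tsv"))
      meta <- read_tsv_rv(ps("metadata.tsv"))
      groups <- meta$group[match(colnames(prev), meta$sample_id)]
      core <- classify_core(prev, groups, core_threshold = config$core_threshold,
                            strict = config$core_strict)
      cc <- core$classification
      cc$threshold_rule <- core$threshold_rule
      write_tsv_rv(cc, p("core_classification.tsv"))
      rich <- data.frame(
        sample_id = colnames(prev),
        richness_per_gbp = fmt_num(vapply(seq_len(ncol(prev)), function(i) {
          richness_per_gbp(sum(prev[, i] > 0),
                           meta$sample_bases[match(colnames(prev)[i],
                                                   meta$sample_id)])
        }, numeric(1)), 4), stringsAsFactors = FALSE)
      write_tsv_rv(rich, p("richness.tsv"))
      ns <- min(ncol(prev), 24L)
      pairs <- t(utils::combn(colnames(prev)[seq_len(ns)], 2L))
      gp <- meta$group[match(pairs, meta$sample_id)]
      dim(gp) <- dim(pairs)
      sp <- shared_votus(prev, data.frame(
        sample_a = pairs[, 1], sample_b = pairs[, 2],
        label = ifelse(gp[, 1] == gp[, 2], "same_group", "different_group"),
        stringsAsFactors = FALSE))
      write_tsv_rv(sp, p("shared_counts.tsv"))
      study <- meta$study[match(colnames(prev), meta$sample_id)]
      cs <- tryCatch(cluster_studies(prev, study), error = function(e) NULL)
      if (is.null(cs)) {
        write_tsv_rv(data.frame(note = "fewer than 2 studies retained"),
                     p("study_clusters.tsv"))
      } else {
        mg <- cs$hclust$merge
        write_tsv_rv(data.frame(step = seq_len(nrow(mg)),
                                left = mg[, 1], right = mg[, 2],
                                height = fmt_num(cs$hclust$height, 6),
                                stringsAsFactors = FALSE),
                     p("study_clusters.tsv"))
      }
      list(votus = nrow(prev), samples = ncol(prev),
           global_core = length(core$global_core))
    },
    stop("unknown stage: ", stage))
}

#' Command-line entry point
#'
#' Thin argument parser behind the `rvk` launcher script
#' (`inst/cli/rvk.R`). Subcommands: `simulate`, `cluster`, `taxonomy`,
#' `host`, `curate`, `ecology`, `all`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 success, 2 validation error).
#' @export
rvk_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: rvk <simulate|cluster|taxonomy|host|curate|ecology|all>",
                 "[--config FILE] [--seed N] [--outdir DIR] [--log-level LVL]")
  if (length(argv) == 0) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- list(config = NULL, seed = NULL, outdir = "rvk_out",
               `log-level` = "info")
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      message("unknown or valueless option: ", argv[i]); return(2L)
    }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  res <- tryCatch({
    config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
              else pipeline_config()
    if (!is.null(opts$seed)) {
      config <- pipeline_config(seed = as.integer(opts$seed), sim = config$sim,
                                ani_min = config$ani_min, af_min = config$af_min,
                                core_threshold = config$core_threshold,
                                core_strict = config$core_strict)
    }
    stages <- if (cmd == "all") PIPELINE_STAGES else cmd
    if (!all(stages %in% PIPELINE_STAGES)) {
      message(usage); return(2L)
    }
    run_pipeline(config, outdir = opts$outdir, stages = stages,
                 log_level = opts$`log-level`)
    0L
  }, error = function(e) {
    message("rvk: ", conditionMessage(e))
    if (grepl("config error|invalid config", conditionMessage(e))) 2L else 1L
  })
  res
}
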