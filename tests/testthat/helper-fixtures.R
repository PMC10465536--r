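# Hand-built curation fixture: 20 contigs exercising every AMG and ARG
# decision reason exactly once (drop reasons) plus the retained paths.

curation_fixture <- function() {
  mk_genes <- function(cid, cats, labels = rep("", length(cats)),
                       amg = rep(NA_integer_, length(cats))) {
    n <- length(cats)
    data.frame(contig_id = cid,
               gene_id = sprintf("%s_g%d", cid, seq_len(n)),
               start = (seq_len(n) - 1L) * 1000L,
               end = (seq_len(n) - 1L) * 1000L + 900L,
               strand = "+", category = cats, labels = labels,
               amg_category = amg, stringsAsFactors = FALSE)
  }
  H <- "viral_hallmark"; V <- "viral_like"; C <- "cellular"; U <- "unannotated"
  contigs <- data.frame(
    id = sprintf("c%02d", 1:20),
    length = c(rep(20000L, 7), 10000L, rep(20000L, 12)),
    quality_tier = c(rep("complete", 7), "complete", "high",
                     rep("complete", 11)),
    stringsAsFactors = FALSE)

  genes <- rbind(
    # c01: AMG retained (hallmark | AMG cat1 | viral_like; capsid present)
    mk_genes("c01", c(H, C, V, H, V),
             c("structural:capsid", "amg_candidate", "", "", ""),
             c(NA, 1L, NA, NA, NA)),
    # c02: AMG at contig end -> end_of_contig
    mk_genes("c02", c(H, V, H, V, C),
             c("structural:portal", "", "", "", "amg_candidate"),
             c(NA, NA, NA, NA, 1L)),
    # c03: AMG flanked by cellular genes -> bad_flank
    mk_genes("c03", c(H, C, C, C, V),
             c("structural:terminase", "", "amg_candidate", "", ""),
             c(NA, NA, 1L, NA, NA)),
    # c04: good flanks but category 3 -> bad_category
    mk_genes("c04", c(H, H, C, V, V),
             c("structural:head", "", "amg_candidate", "", ""),
             c(NA, NA, 3L, NA, NA)),
    # c05: island marker (GT25) on the contig -> island_marker
    mk_genes("c05", c(H, H, C, V, C),
             c("structural:portal", "", "amg_candidate", "",
               "island_marker:GT25"),
             c(NA, NA, 1L, NA, NA)),
    # c06: no structural gene anywhere -> no_structural
    mk_genes("c06", c(H, H, C, V, V),
             c("", "", "amg_candidate", "", ""),
             c(NA, NA, 1L, NA, NA)),
    # c07: viral genes are only integrase/tail_fiber -> only_mobile_genes
    mk_genes("c07", c(V, C, C, V, U),
             c("integrase", "", "amg_candidate", "tail_fiber", ""),
             c(NA, NA, 1L, NA, NA)),
    # c08: 10,000 bp exactly -> not eligible (strict > 10 kb)
    mk_genes("c08", c(H, H, C, V, V),
             c("structural:capsid", "", "amg_candidate", "", ""),
             c(NA, NA, 1L, NA, NA)),
    # c09: high quality, no AMG candidate (background)
    mk_genes("c09", c(H, H, C, V, V),
             c("structural:capsid", "", "", "", "")),
    # c10--c14: ARG cases
    mk_genes("c10", c(H, V, C, V, H)),        # interior keep
    mk_genes("c11", c(H, V, C, V, H)),        # low_coverage
    mk_genes("c12", c(H, V, C, V, H)),        # low_identity
    mk_genes("c13", c(H, V, C, C, C)),        # end, cellular neighbour
    mk_genes("c14", c(H, V, C, H, C)),        # end, viral neighbour -> keep
    # c15--c20: background contigs without candidates
    mk_genes("c15", c(H, V, C, V, H)),
    mk_genes("c16", c(H, V, U, V, H)),
    mk_genes("c17", c(V, V, C, V, H)),
    mk_genes("c18", c(H, U, C, V, H)),
    mk_genes("c19", c(H, V, C, V, V)),
    mk_genes("c20", c(H, V, C, U, H))
  )

  arg_hits <- data.frame(
    contig_id = c("c10", "c11", "c12", "c13", "c14"),
    gene_id = c("c10_g3", "c11_g3", "c12_g3", "c13_g5", "c14_g5"),
    arg_class = c("tetW", "tetO", "vanG", "vanWG", "aph3"),
    percent_identity = c(85, 85, 79, 90, 90),
    reference_coverage = c(45, 39.9, 60, 80, 80),
    stringsAsFactors = FALSE)

  expected_amg <- data.frame(
    contig_id = sprintf("c%02d", 1:8),
    keep = c(TRUE, rep(FALSE, 7)),
    reason = c("retained", "end_of_contig", "bad_flank", "bad_category",
               "island_marker", "no_structural", "only_mobile_genes",
               "not_complete_vmag"),
    stringsAsFactors = FALSE)
  expected_arg <- data.frame(
    contig_id = sprintf("c%02d", 10:14),
    keep = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    reason = c("retained", "low_coverage", "low_identity",
               "end_no_viral_neighbor", "retained"),
    stringsAsFactors = FALSE)

  list(contigs = contigs, genes = genes, arg_hits = arg_hits,
       expected_amg = expected_amg, expected_arg = expected_arg)
}
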