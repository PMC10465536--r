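mk_block <- function(pid, len, q1 = 1L, votu = "v", genome = "g") {
  data.frame(query_id = votu, subject_id = genome, percent_identity = pid,
             alignment_length = len, mismatches = 0L, gap_opens = 0L,
             query_start = q1, query_end = q1 + len - 1L,
             subject_start = 1L, subject_end = len, evalue = 0, bitscore = 0)
}

test_that("prophage link rule: >90% identity, one block >2,500 bp, >=75% vOTU coverage", {
  expect_false(is.null(call_prophage_link(mk_block(95, 8000L), 10000)))
  # identity exactly 90.0 fails the strict > rule
  expect_null(call_prophage_link(mk_block(90, 8000L), 10000))
  # two 2,000 bp blocks cover 80% of a 5 kb vOTU but no block exceeds 2,500 bp
  two <- rbind(mk_block(95, 2000L, q1 = 1L), mk_block(95, 2000L, q1 = 2001L))
  expect_null(call_prophage_link(two, 5000))
  # one qualifying block plus small helpers can reach coverage together
  mix <- rbind(mk_block(95, 6000L, q1 = 1L), mk_block(95, 2000L, q1 = 6500L))
  link <- call_prophage_link(mix, 10000)
  expect_equal(link$n_blocks, 2L)
  expect_equal(link$votu_coverage, 0.80)   # 6,000 + 2,000 bp of a 10 kb vOTU
  # coverage boundary is inclusive (>= 75%)
  expect_false(is.null(call_prophage_link(mk_block(95, 7500L), 10000)))
  expect_null(call_prophage_link(mk_block(95, 7499L), 10000))
  expect_error(call_prophage_link(mk_block(95, 100L), 0), "positive")
})

test_that("CRISPR detector recovers planted arrays and rejects degenerate ones", {
  rep28 <- "GTGTTCCCCGCGTGAGCGGGGATAAACC"
  set.seed(31)
  host <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  virus <- paste(sample(c("A", "C", "G", "T"), 9000, TRUE), collapse = "")
  res <- plant_crispr_array(host, virus, n_spacers = 3, spacer_length = 32,
                            repeat_seq = rep28, seed = 6,
                            host_id = "h", virus_id = "v")
  sp <- detect_crispr_arrays(res$sequence, genome_id = "h")
  expect_equal(nrow(sp), 3)
  # boundary trimming by at most 2 bp is tolerated; the recovered spacer
  # must still sit inside the planted interval and match the source virus
  for (i in seq_len(3)) {
    expect_gte(sp$start[i], res$truth$start[i] - 2L)
    expect_lte(sp$end[i], res$truth$end[i] + 2L)
    expect_true(call_spacer_link(sp$sequence[i], virus))
  }

  # a genome without repeats yields nothing
  expect_equal(nrow(detect_crispr_arrays(host)), 0)
  # a single repeat copy is not an array (minimum two repeats)
  single <- paste0(host, rep28, substr(virus, 1, 32))
  expect_equal(nrow(detect_crispr_arrays(single)), 0)
})

test_that("spacer links require an exact full-length match on either strand", {
  set.seed(41)
  votu <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  spacer <- substr(votu, 1001, 1032)
  expect_true(call_spacer_link(spacer, votu))
  # one mismatch breaks the link
  mutated <- spacer
  substr(mutated, 16, 16) <- setdiff(c("A", "C", "G", "T"),
                                     substr(spacer, 16, 16))[1]
  expect_false(call_spacer_link(mutated, votu))
  # reverse-complement-only occurrence still links
  rc <- rumenvirome:::revcomp(spacer)
  expect_true(call_spacer_link(rc, votu))
  expect_error(call_spacer_link("", votu), "empty")
})

test_that("call_spacer_link equals the independent pattern-match oracle", {
  set.seed(51)
  for (trial in 1:200) {
    votu <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    spacer <- if (trial %% 3 == 0) {
      paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    } else {
      at <- sample(1:370, 1)
      sp <- substr(votu, at, at + 24)
      if (trial %% 3 == 1) sp else rumenvirome:::revcomp(sp)
    }
    expect_identical(call_spacer_link(spacer, votu),
                     oracle_spacer_match(spacer, votu),
                     label = paste("trial", trial))
  }
})

test_that("host range aggregation counts taxa sets and sets flags", {
  tax <- data.frame(genome_id = c("g1", "g2", "g3"),
                    species = c("s__A_1", "s__A_2", "s__B_1"),
                    genus = c("g__A", "g__A", "g__B"),
                    phylum = c("p__X", "p__X", "p__Y"),
                    stringsAsFactors = FALSE)
  link <- function(v, g) data.frame(votu_id = v, genome_id = g,
                                    evidence = "prophage", stringsAsFactors = FALSE)
  hr <- aggregate_host_range(rbind(link("v1", "g1"), link("v1", "g2")), tax)
  expect_true(hr$multi_species)
  expect_false(hr$cross_phylum)
  hr2 <- aggregate_host_range(rbind(link("v1", "g1"), link("v1", "g3")), tax)
  expect_true(hr2$multi_species && hr2$cross_phylum)
  # duplicated links change nothing
  hr3 <- aggregate_host_range(rbind(link("v1", "g1"), link("v1", "g3"),
                                    link("v1", "g3")), tax)
  expect_identical(hr2, hr3)
  expect_warning(
    hr4 <- aggregate_host_range(rbind(link("v1", "g1"), link("v1", "gX")), tax),
    "no taxonomy")
  expect_false(hr4$multi_species)
})

test_that("genus statistics: phages per genome and lysogeny rate", {
  genomes <- data.frame(genome_id = paste0("g", 1:4),
                        genus = rep("g__A", 4), stringsAsFactors = FALSE)
  links <- data.frame(votu_id = c("v1", "v2"), genome_id = c("g1", "g2"),
                      evidence = "prophage", stringsAsFactors = FALSE)
  gs <- genus_stats(links, genomes, c(v1 = TRUE, v2 = FALSE))
  expect_equal(gs$phages_per_genome, 0.5)
  expect_equal(gs$lysogeny_rate, 50)

  links10 <- data.frame(votu_id = paste0("v", 1:10),
                        genome_id = rep("g1", 10),
                        evidence = "spacer", stringsAsFactors = FALSE)
  lys <- setNames(c(rep(TRUE, 3), rep(FALSE, 7)), paste0("v", 1:10))
  expect_equal(genus_stats(links10, genomes, lys)$lysogeny_rate, 30)

  expect_error(genus_stats(links, genomes, c(v1 = TRUE)), "missing lysogeny")
})
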