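test_that("mutate_sequence applies exactly floor(d*L) substitutions, deterministically", {
  expect_identical(mutate_sequence("ACGTACGT", 0, seed = 123), "ACGTACGT")

  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  m <- mutate_sequence(s, 0.05, seed = 1)
  expect_equal(nchar(m), 1000)
  mism <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(mism, 50)

  expect_identical(mutate_sequence(s, 0.1, seed = 7),
                   mutate_sequence(s, 0.1, seed = 7))
  expect_error(mutate_sequence("", 0.1, seed = 1), "empty")
  expect_error(mutate_sequence("ACGT", 1.5, seed = 1), "\\[0,1\\]")
})

test_that("plant_prophage inserts at the recorded interval and feeds the link rule", {
  set.seed(9)
  host <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  virus <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  pl <- plant_prophage(host, virus, 0.05, position = 20000, seed = 3)
  expect_equal(nchar(pl$sequence), 60000)
  expect_equal(pl$truth$start, 20000)
  expect_equal(pl$truth$end, 30000)
  inserted <- substr(pl$sequence, 20001, 30000)
  mism <- sum(strsplit(virus, "")[[1]] != strsplit(inserted, "")[[1]])
  expect_equal(mism, 500)

  # ideal alignment block of a 2%-divergence plant satisfies the host-link rule
  pl2 <- plant_prophage(host, virus, 0.02, position = 1000, seed = 4)
  block <- data.frame(query_id = "v", subject_id = "h",
                      percent_identity = 98, alignment_length = 10000L,
                      mismatches = 200L, gap_opens = 0L,
                      query_start = 1L, query_end = 10000L,
                      subject_start = 1001L, subject_end = 11000L,
                      evalue = 0, bitscore = 1.9e4)
  expect_false(is.null(call_prophage_link(block, votu_length = 10000)))

  # a 2 kb fragment cannot satisfy the >2,500 bp block requirement
  block_short <- transform(block, alignment_length = 2000L, query_end = 2000L,
                           subject_end = 3000L, percent_identity = 100)
  expect_null(call_prophage_link(block_short, votu_length = 2000))

  expect_error(plant_prophage(host, virus, 0.05, position = -1, seed = 1),
               "negative")
})

test_that("plant_crispr_array plants exact protospacer copies", {
  set.seed(11)
  host <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  virus <- paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = "")
  res <- plant_crispr_array(host, virus, n_spacers = 3, spacer_length = 32,
                            seed = 2, host_id = "h", virus_id = "v")
  expect_equal(nrow(res$truth), 3)
  for (i in 1:3) {
    sp <- substr(res$sequence, res$truth$start[i] + 1, res$truth$end[i])
    expect_equal(nchar(sp), 32)
    expect_true(grepl(sp, virus, fixed = TRUE) ||
                  grepl(rumenvirome:::revcomp(sp), virus, fixed = TRUE))
  }
  expect_error(plant_crispr_array(host, virus, n_spacers = 1,
                                  spacer_length = 32, seed = 1), ">= 2")
  expect_error(plant_crispr_array(host, "ACGT", n_spacers = 3,
                                  spacer_length = 32, seed = 1), "exceeds")
})

test_that("generate_community is byte-deterministic under the seed", {
  cfg <- small_sim_config(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_community_bundle(generate_community(cfg), d1)
  write_community_bundle(generate_community(cfg), d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})

test_that("bundle cross-references resolve and intervals stay in range", {
  b <- generate_community(small_sim_config(seed = 3))
  seq_ids <- c(names(b$viruses), names(b$hosts))
  expect_true(all(b$genes$contig_id %in% seq_ids))
  expect_true(all(b$truth$virus_id %in% names(b$viruses)))
  hid <- b$truth$host_id[!is.na(b$truth$host_id)]
  expect_true(all(hid %in% names(b$hosts)))
  carrier_len <- nchar(c(b$viruses, b$hosts))[
    ifelse(is.na(b$truth$host_id), b$truth$virus_id, b$truth$host_id)]
  has_iv <- !is.na(b$truth$start)
  expect_true(all(b$truth$start[has_iv] >= 0))
  expect_true(all(b$truth$end[has_iv] <= carrier_len[has_iv]))
  # exactly one truth record per planted feature locus
  key <- with(b$truth[has_iv, ], paste(kind, virus_id, host_id, start))
  expect_false(anyDuplicated(key) > 0)
})

test_that("a prevalence profile of 1 forces a vOTU into the core truth", {
  cfg <- sim_config(seed = 5, n_viruses = 4,
                    virus_length_range = c(5000, 8000), n_hosts = 2,
                    host_length_range = c(20000, 30000),
                    samples_per_group = c(4, 4, 4),
                    prevalence_profile = matrix(1, nrow = 4, ncol = 3),
                    n_dup_co = 0, n_dup_far = 0, n_dup_part = 0)
  b <- generate_community(cfg)
  core <- b$truth$virus_id[b$truth$kind == "core_votu"]
  expect_true(all(c("v001", "v002", "v003", "v004") %in% core))
})

test_that("divergence controls planted prophage recall through the link rule", {
  for (s in 1:5) {
    b <- generate_community(small_sim_config(seed = 100 + s))
    hits <- b$virus_host_hits
    tr <- b$truth[b$truth$kind == "prophage", ]
    for (i in seq_len(nrow(tr))) {
      blocks <- hits[hits$query_id == tr$virus_id[i] &
                       hits$subject_id == tr$host_id[i], , drop = FALSE]
      link <- call_prophage_link(blocks, nchar(b$viruses[[tr$virus_id[i]]]))
      expect_identical(!is.null(link), tr$expected_decision[i] == "link",
                       label = sprintf("seed %d plant %s->%s", s,
                                       tr$virus_id[i], tr$host_id[i]))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_viruses = 0), "n_viruses")
  expect_error(sim_config(virus_length_range = c(10000, 5000)), "ordered")
  expect_error(sim_config(prophage_divergence = 1.2), "\\[0,1\\]")
  expect_error(sim_config(samples_per_group = 0), "sample")
})
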