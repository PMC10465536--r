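test_that("local_align recovers self, reverse-complement and mutated pairs", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 2500, TRUE), collapse = "")
  self <- local_align(s, s)
  expect_equal(nrow(self), 1)
  expect_equal(self$percent_identity, 100)
  expect_equal(self$alignment_length, 2500L)
  expect_equal(c(self$query_start, self$query_end), c(1L, 2500L))

  rc <- local_align(s, rumenvirome:::revcomp(s))
  expect_equal(rc$percent_identity[1], 100)
  expect_equal(rc$alignment_length[1], 2500L)
  expect_true(rc$subject_start[1] > rc$subject_end[1])  # minus strand

  m <- mutate_sequence(s, 0.03, seed = 8)
  blocks <- local_align(s, m, x_drop = 60)
  weighted <- sum(blocks$percent_identity * blocks$alignment_length) /
    sum(blocks$alignment_length)
  nw <- Biostrings::pid(Biostrings::pairwiseAlignment(s, m, type = "global"))
  expect_lt(abs(weighted - nw), 1.0)

  expect_error(local_align(s, s, k = 10), ">= 11")
})

test_that("compute_pairwise_ani matches hand-computed worked examples", {
  mk <- function(pid, len, q1, q2, s1, s2) {
    data.frame(query_id = "a", subject_id = "b", percent_identity = pid,
               alignment_length = len, mismatches = 0L, gap_opens = 0L,
               query_start = q1, query_end = q2, subject_start = s1,
               subject_end = s2, evalue = 0, bitscore = 0)
  }
  one <- compute_pairwise_ani(mk(96, 8000L, 1L, 8000L, 1L, 8000L),
                              10000, 10000)
  expect_equal(one$ani, 96)
  expect_equal(one$af_query, 80)
  expect_equal(one$af_subject, 80)

  two <- compute_pairwise_ani(rbind(mk(100, 4000L, 1L, 4000L, 1L, 4000L),
                                    mk(90, 1000L, 5001L, 6000L, 5001L, 6000L)),
                              10000, 10000)
  expect_equal(two$ani, 98)
  expect_equal(two$af_query, 50)

  overlap <- compute_pairwise_ani(rbind(mk(100, 1000L, 1L, 1000L, 1L, 1000L),
                                        mk(100, 1000L, 501L, 1500L, 2001L, 3000L)),
                                  10000, 10000)
  expect_equal(overlap$af_query, 15)   # union = 1,500 bp

  empty <- compute_pairwise_ani(rumenvirome:::empty_blast6(), 10000, 10000)
  expect_equal(empty$ani, 0)
  expect_equal(empty$af_query, 0)

  expect_error(compute_pairwise_ani(mk(100, 1000L, 1L, 1000L, 1L, 1000L),
                                    500, 10000), "exceeds")
})

test_that("cluster_votus follows the centroid-greedy contract", {
  contigs <- data.frame(id = c("A", "B", "C"),
                        length = c(30000L, 20000L, 10000L),
                        completeness = c(90, 80, 70), stringsAsFactors = FALSE)
  tab <- data.frame(query_id = "A", subject_id = "B", ani = 100,
                    af_query = 100, af_subject = 100, stringsAsFactors = FALSE)
  cl <- cluster_votus(contigs, tab)
  expect_equal(sort(unique(cl$representative_id)), c("A", "C"))
  expect_equal(cl$representative_id[cl$member_id == "B"], "A")

  # chained similarity: B joins centroid A; C fails against A and founds
  # its own vOTU (C is never compared to non-centroid B)
  tab2 <- data.frame(query_id = c("A", "B", "A"),
                     subject_id = c("B", "C", "C"),
                     ani = c(96, 96, 80),
                     af_query = c(90, 90, 90), af_subject = c(90, 90, 90),
                     stringsAsFactors = FALSE)
  cl2 <- cluster_votus(contigs, tab2)
  expect_equal(cl2$representative_id[cl2$member_id == "B"], "A")
  expect_equal(cl2$representative_id[cl2$member_id == "C"], "C")

  expect_error(cluster_votus(rbind(contigs, contigs[1, ]), tab), "duplicate")
})

test_that("cluster_votus equals the brute-force greedy oracle on random instances", {
  for (trial in 1:300) {
    inst <- random_ani_instance(n = sample(2:8, 1), seed = 5000 + trial)
    got <- cluster_votus(inst$contigs, inst$ani_table)
    want <- oracle_greedy_cluster(inst$contigs, inst$ani_table)
    got <- got[order(got$member_id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, label = paste("trial", trial))
  }
})

test_that("clustering invariants: partition, centroid separation, permutation stability, monotonicity", {
  for (trial in 1:40) {
    inst <- random_ani_instance(n = 8, seed = 9000 + trial)
    cl <- cluster_votus(inst$contigs, inst$ani_table)
    # partition
    expect_setequal(cl$member_id, inst$contigs$id)
    expect_false(anyDuplicated(cl$member_id) > 0)
    # centroid separation
    cents <- unique(cl$representative_id)
    lens <- setNames(inst$contigs$length, inst$contigs$id)
    for (i in seq_along(cents)) for (j in seq_len(i - 1)) {
      a <- cents[i]; b <- cents[j]
      row <- inst$ani_table[(inst$ani_table$query_id == a &
                               inst$ani_table$subject_id == b) |
                              (inst$ani_table$query_id == b &
                                 inst$ani_table$subject_id == a), ]
      if (nrow(row) > 0) {
        af_short <- if (lens[row$query_id[1]] <= lens[row$subject_id[1]])
          row$af_query[1] else row$af_subject[1]
        expect_false(row$ani[1] >= 95 && af_short >= 85)
      }
    }
    # permutation stability
    perm <- sample(nrow(inst$contigs))
    cl_perm <- cluster_votus(inst$contigs[perm, ], inst$ani_table)
    cl_perm <- cl_perm[order(cl_perm$member_id), ]
    cl_sorted <- cl[order(cl$member_id), ]
    rownames(cl_perm) <- rownames(cl_sorted) <- NULL
    expect_identical(cl_sorted, cl_perm)
    # monotonicity in thresholds
    n_base <- length(unique(cl$representative_id))
    for (ani_min in c(97, 99)) {
      n_hi <- length(unique(cluster_votus(inst$contigs, inst$ani_table,
                                          ani_min = ani_min)$representative_id))
      expect_gte(n_hi, n_base)
    }
    n_af <- length(unique(cluster_votus(inst$contigs, inst$ani_table,
                                        af_min = 95)$representative_id))
    expect_gte(n_af, n_base)
  }
})

test_that("representative selection ranks length, then completeness, then id", {
  contigs <- data.frame(id = c("x", "y"), length = c(12000L, 10000L),
                        completeness = c(50, 100), stringsAsFactors = FALSE)
  expect_equal(select_representative(c("x", "y"), contigs), "x")
  expect_equal(select_representative("y", contigs), "y")
  tie <- data.frame(id = c("b", "a"), length = c(1000L, 1000L),
                    completeness = c(80, 80), stringsAsFactors = FALSE)
  expect_equal(select_representative(c("b", "a"), tie), "a")
})

test_that("contig admission rejects the 5,000 bp boundary (strict >5 kb)", {
  d <- withr::local_tempdir()
  seqs <- c(short = strrep("ACGT", 1250),       # exactly 5,000 bp
            long = strrep("ACGT", 1300))        # 5,200 bp
  write_fasta(seqs, file.path(d, "v.fna"))
  contigs <- load_contigs(file.path(d, "v.fna"))
  expect_identical(contigs$id, "long")
})
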