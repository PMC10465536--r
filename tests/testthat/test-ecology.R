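test_that("read-alignment filter boundaries are inclusive", {
  al <- data.frame(percent_identity = c(96, 94.9, 99, 95, 96),
                   aligned_fraction_of_read = c(0.80, 0.99, 0.74, 0.75, 0.75))
  kept <- filter_read_alignments(al)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$percent_identity >= 95 &
                    kept$aligned_fraction_of_read >= 0.75))
})

test_that("trimmed-mean coverage follows the closed forms", {
  expect_equal(trimmed_mean_coverage(rep(7L, 100)), 7.0)
  # worked 20-position example: drop one highest (100) and one lowest (0)
  v <- c(rep(5L, 18), 100L, 0L)
  expect_equal(trimmed_mean_coverage(v), 5.0)
  # covered fraction below the 0.70 gate returns 0
  v2 <- c(rep(0L, 60), rep(10L, 40))
  expect_equal(trimmed_mean_coverage(v2), 0)
  expect_error(trimmed_mean_coverage(integer(0)), "empty")
  # translation equivariance and permutation invariance
  set.seed(61)
  for (i in 1:20) {
    d <- rpois(200, 6) + 1L     # fully covered
    base <- trimmed_mean_coverage(d)
    expect_equal(trimmed_mean_coverage(d + 3L), base + 3)
    expect_equal(trimmed_mean_coverage(sample(d)), base)
  }
})

test_that("richness per Gbp is simple normalized detection", {
  expect_equal(richness_per_gbp(500, 2e9), 250)
  expect_equal(richness_per_gbp(0, 2e9), 0)
  expect_equal(richness_per_gbp(120, 4e9), richness_per_gbp(120, 2e9) / 2)
  expect_error(richness_per_gbp(10, 0), "positive")
})

test_that("core classification: classes, strict threshold, monotonicity", {
  set.seed(71)
  groups <- rep(c("low", "medium", "high"), times = c(4, 4, 4))
  mat <- matrix(0L, nrow = 5, ncol = 12,
                dimnames = list(paste0("v", 1:5), paste0("s", 1:12)))
  mat[1, ] <- 1L                       # core everywhere
  mat[2, 3] <- 1L                      # individualized
  mat[3, groups == "low"] <- c(1L, 1L, 0L, 0L)   # 2/4 = 50%, not core (strict)
  mat[4, c(1, 5)] <- 1L                # two levels
  res <- classify_core(mat, groups)
  cls <- res$classification
  expect_true(cls$global_core[cls$votu_id == "v1"])
  expect_equal(cls$class[cls$votu_id == "v2"], "individualized")
  expect_false(res$classification$core_low[cls$votu_id == "v3"])
  expect_equal(cls$class[cls$votu_id == "v4"], "two_levels")
  expect_equal(res$global_core, "v1")
  # inclusive switch turns the exact-50% case into core
  res_inc <- classify_core(mat, groups, strict = FALSE)
  expect_true(res_inc$classification$core_low[cls$votu_id == "v3"])
  # lowering the threshold never shrinks a core set
  for (thr in c(0.5, 0.4, 0.3, 0.2)) {
    lo <- classify_core(mat, groups, core_threshold = thr)
    hi <- classify_core(mat, groups, core_threshold = thr + 0.1)
    for (g in names(lo$core_sets)) {
      expect_true(all(hi$core_sets[[g]] %in% lo$core_sets[[g]]))
    }
  }
  expect_error(classify_core(mat * 2L, groups), "binary")
})

test_that("shared vOTU counts equal brute-force set intersections", {
  set.seed(81)
  mat <- matrix(rbinom(100, 1, 0.4), nrow = 10,
                dimnames = list(paste0("v", 1:10), paste0("s", 1:10)))
  pairs <- t(combn(colnames(mat), 2))
  res <- shared_votus(mat, data.frame(sample_a = pairs[, 1],
                                      sample_b = pairs[, 2]))
  for (i in seq_len(nrow(res))) {
    a <- rownames(mat)[mat[, res$sample_a[i]] == 1]
    b <- rownames(mat)[mat[, res$sample_b[i]] == 1]
    expect_equal(res$shared[i], length(intersect(a, b)))
  }
  # symmetry
  rev_res <- shared_votus(mat, data.frame(sample_a = pairs[, 2],
                                          sample_b = pairs[, 1]))
  expect_equal(res$shared, rev_res$shared)
  # identical and disjoint rows
  m2 <- matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), nrow = 3,
               dimnames = list(paste0("v", 1:3), c("a", "b", "c")))
  r2 <- shared_votus(m2, data.frame(sample_a = c("a", "a"),
                                    sample_b = c("b", "c")))
  expect_equal(r2$shared, c(2L, 0L))
})

test_that("study clustering filters at >12 samples and matches the average-linkage oracle", {
  set.seed(91)
  # 4 studies with block-structured sharing + 1 small study to be excluded
  n_votu <- 60
  studies <- rep(c("A", "B", "C", "D", "E"), times = c(15, 15, 14, 13, 12))
  mat <- matrix(0L, nrow = n_votu, ncol = length(studies),
                dimnames = list(sprintf("v%02d", 1:n_votu),
                                sprintf("s%02d", seq_along(studies))))
  pools <- list(A = 1:30, B = 5:34, C = 30:55, D = 33:58, E = 1:15)
  for (j in seq_along(studies)) {
    pool <- pools[[studies[j]]]
    mat[sample(pool, 12), j] <- 1L
  }
  res <- cluster_studies(mat, studies)
  expect_setequal(res$retained_studies, c("A", "B", "C", "D"))  # E has 12
  # oracle comparison: same merge sets and heights
  d <- as.matrix(res$dissimilarity)
  merges <- oracle_average_linkage(d)
  hc <- res$hclust
  got_sets <- list()
  for (i in seq_len(nrow(hc$merge))) {
    members <- function(x) if (x < 0) hc$labels[-x] else got_sets[[x]]
    got_sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  for (i in seq_along(merges)) {
    expect_identical(got_sets[[i]], merges[[i]]$members)
    expect_equal(hc$height[i], merges[[i]]$height, tolerance = 1e-12)
  }
  # two studies with identical vOTU sets merge first
  mat2 <- mat
  mat2[, studies == "B"] <- mat2[, studies == "A"][, seq_len(sum(studies == "B"))]
  res2 <- cluster_studies(mat2, studies)
  first <- res2$hclust$labels[-res2$hclust$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  expect_error(cluster_studies(mat, rep("onlyone", ncol(mat))),
               "fewer than 2")
})

test_that("abundance_from_depth applies the trimmed mean per (vOTU, sample)", {
  depth <- rbind(
    data.frame(votu_id = "v1", sample_id = "s1", position = 1:20,
               depth = c(rep(5L, 18), 100L, 0L)),
    data.frame(votu_id = "v1", sample_id = "s2", position = 1:20,
               depth = rep(0L, 20)),
    data.frame(votu_id = "v2", sample_id = "s1", position = 1:10,
               depth = rep(3L, 10)))
  ab <- abundance_from_depth(depth)
  expect_equal(ab["v1", "s1"], 5)
  expect_equal(ab["v1", "s2"], 0)
  expect_equal(ab["v2", "s1"], 3)
  expect_equal(ab["v2", "s2"], 0)
})
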