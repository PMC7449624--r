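# Synthetic-data generator: references, planted truth, read simulation.

test_that("marker references are reproducible, seed-sensitive and validated", {
  r1 <- make_marker_reference(450, 0, seed = 1)
  r2 <- make_marker_reference(450, 0, seed = 1)
  r3 <- make_marker_reference(450, 0, seed = 2)
  expect_identical(r1$sequence, r2$sequence)
  expect_false(r1$sequence == r3$sequence)
  expect_equal(nchar(r1$sequence), 450)
  expect_false(grepl("[^ACGT]", r1$sequence))
  expect_error(make_marker_reference(29, 0, seed = 1), "length")
  expect_error(make_marker_reference(500, 0, seed = 1), "length")
  expect_error(make_marker_reference(100, 3, seed = 1), "frame_offset")
})

test_that("planted truth respects cluster geometry and abundance invariants", {
  truth <- small_truth(n_bees = 20, n_clusters = 6, strains_per_cluster = 4,
                       two_cluster_fraction = 0.1, seed = 3)
  for (m in names(truth$references)) {
    L <- nchar(truth$references[[m]]$sequence)
    for (ci in seq_along(truth$clusters[[m]])) {
      members <- truth$clusters[[m]][[ci]]
      expect_equal(length(members), 4)
      expect_true(all(nchar(members) == L))
      d <- outer(members, members, Vectorize(function(a, b) snp_distance(a, b)))
      expect_true(all(d[upper.tri(d)] >= 1))      # all strains distinct
      expect_true(all(d[upper.tri(d)] <= 2 * 1))  # within-cluster: <= 2x max SNPs
      expect_equal(sum(truth$abundance_profiles[[m]][[ci]]), 1, tolerance = 1e-9)
    }
    # every bee carries >= 1 cluster; two-cluster fraction as configured
    ncl <- lengths(truth$carried[[m]])
    expect_true(all(ncl >= 1))
    expect_equal(sum(ncl == 2), round(0.1 * 20))
  }
  expect_error(make_truth(truth$references, n_bees = 10,
                          locations = c(A = 4, B = 4), n_clusters = 2,
                          strains_per_cluster = 2),
               "sum to n_bees")
  expect_error(make_truth(truth$references, n_bees = 8,
                          locations = c(A = 4, B = 4), n_clusters = 2,
                          strains_per_cluster = 0),
               "strains_per_cluster")
})

test_that("degenerate truth: one cluster, one strain everywhere", {
  truth <- small_truth(n_clusters = 1, strains_per_cluster = 1,
                       markers = "m1", seed = 4)
  expect_equal(length(unique(unlist(truth$clusters$m1))), 1)
  comp <- vapply(truth$bee_assignments$bee_id, function(b) {
    names(mastkit:::truth_bee_composition(truth, "m1", b))
  }, character(1))
  expect_equal(length(unique(comp)), 1)
})

test_that("error-free reads copy planted strains exactly at planted frequencies", {
  truth <- small_truth(n_bees = 6, n_clusters = 2, strains_per_cluster = 3,
                       markers = "m1", error_rate = 0, coverage_mean = 3000,
                       seed = 5)
  sim <- simulate_reads(truth, read_sim_params(coverage_mean = 3000,
                                               error_rate = 0, seed = 6))
  planted <- unique(truth_strains(truth, "m1")$sequence)
  expect_true(all(sim$reads$seq %in% planted))
  # per-bee observed frequencies within 3 sigma binomial error of planted
  for (b in unique(sim$reads$sample_id)) {
    comp <- mastkit:::truth_bee_composition(truth, "m1", b)
    reads_b <- sim$reads$seq[sim$reads$sample_id == b]
    n <- length(reads_b)
    for (s in names(comp)) {
      p <- comp[[s]]
      expect_lt(abs(mean(reads_b == s) - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
    }
  }
})

test_that("read counts follow the abundance profile at binomial accuracy", {
  # two strains at 0.9/0.1: counts close to expectation
  ref <- make_marker_reference(60, 0, seed = 8, marker_name = "m1")
  truth <- make_truth(ref, n_bees = 1, locations = c(A = 1), n_clusters = 1,
                      strains_per_cluster = 2, two_cluster_fraction = 0,
                      profile_concentration = 1e9, error_rate = 0, seed = 9)
  # force an exact 0.9/0.1 profile
  truth$abundance_profiles$m1[[1]] <- c(0.9, 0.1)
  n <- 46000
  sim <- simulate_reads(truth, read_sim_params(coverage_mean = n,
                                               coverage_dispersion = 1e9,
                                               error_rate = 0, seed = 10))
  major <- truth$clusters$m1[[1]][1]
  cnt <- sum(sim$reads$seq == major)
  expect_lt(abs(cnt - 0.9 * nrow(sim$reads)),
            3 * sqrt(0.9 * 0.1 * nrow(sim$reads)))
})

test_that("sequencing errors appear at the configured rate with low quality", {
  truth <- small_truth(n_bees = 4, n_clusters = 1, strains_per_cluster = 1,
                       markers = "m1", error_rate = 0.01, coverage_mean = 500,
                       seed = 12)
  sim <- simulate_reads(truth, read_sim_params(coverage_mean = 500,
                                               error_rate = 0.01,
                                               phred_high = 40, phred_low = 15,
                                               seed = 13))
  strain <- truth$clusters$m1[[1]][1]
  L <- nchar(strain)
  n_err <- sum(vapply(sim$reads$seq, function(s) {
    sum(charToRaw(s) != charToRaw(strain))
  }, numeric(1)))
  n_low <- sum(vapply(sim$reads$qual, function(q) {
    sum((as.integer(charToRaw(q)) - 33L) == 15L)
  }, numeric(1)))
  expect_equal(n_err, n_low)  # every erroneous base flagged phred_low
  total_bases <- nrow(sim$reads) * L
  expect_lt(abs(n_err / total_bases - 0.01),
            4 * sqrt(0.01 * 0.99 / total_bases))
})

test_that("FASTQ output is byte-identical across runs with the same seed", {
  truth <- small_truth(n_bees = 3, n_clusters = 2, strains_per_cluster = 2,
                       markers = "m1", coverage_mean = 200, seed = 14)
  params <- read_sim_params(coverage_mean = 200, error_rate = 0.005, seed = 15)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_reads(truth, params, out_dir = d1)
  simulate_reads(truth, params, out_dir = d2)
  f1 <- sort(list.files(d1, pattern = "fastq$"))
  expect_identical(f1, sort(list.files(d2, pattern = "fastq$")))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e7),
                     readBin(file.path(d2, f), "raw", n = 1e7))
  }
  # and the reads round-trip through FASTQ unchanged
  mem <- simulate_reads(truth, params)
  disk <- read_fastq_dir(d1)
  mem_sorted <- mem$reads[order(mem$reads$read_id), c("read_id", "seq", "qual")]
  disk_sorted <- disk[order(disk$read_id), c("read_id", "seq", "qual")]
  rownames(mem_sorted) <- rownames(disk_sorted) <- NULL
  expect_equal(mem_sorted, disk_sorted)
})

test_that("location-exclusive clusters are rejected by the geography test downstream", {
  truth <- small_truth(n_bees = 30, n_clusters = 4, strains_per_cluster = 3,
                       markers = "m1", location_bias = 1,
                       locations = c(A = 15, B = 15), seed = 16)
  tab <- strain_table_from_truth(truth)
  meta <- truth$bee_assignments
  names(meta) <- c("sample_id", "location")
  res <- location_shuffle_test(tab, meta, "m1", n_reps = 499, seed = 17)
  expect_lt(res$p_bonferroni, 0.05)
})
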