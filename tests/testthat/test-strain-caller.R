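# Quality filtering, ungapped alignment, strain calling, SNP distances,
# cryptic rescue.

test_that("quality filter applies the mean-Phred rule with its exact boundary", {
  L <- 40
  mk <- function(quals) paste0(rawToChar(as.raw(quals + 33L)), collapse = "")
  reads <- data.frame(
    sample_id = "s1", marker = "m",
    read_id = c("hi", "low", "boundary", "ambig"),
    seq = c(strrep("A", L), strrep("A", L), strrep("A", L),
            paste0("N", strrep("A", L - 1))),
    qual = c(qual_string(L, 40), qual_string(L, 29),
             mk(rep(c(20L, 40L), each = L / 2)),  # mean exactly 30
             qual_string(L, 40)),
    stringsAsFactors = FALSE)
  fr <- filter_reads(reads, caller_params())
  expect_setequal(fr$retained$read_id, c("hi", "boundary"))
  expect_equal(fr$n_low_quality, 1)
  expect_equal(fr$n_ambiguous, 1)
  fr2 <- filter_reads(reads, caller_params(allow_n = TRUE))
  expect_true("ambig" %in% fr2$retained$read_id)
  # malformed record: seq/qual length mismatch is an error
  bad <- reads
  bad$qual[1] <- qual_string(L - 1, 40)
  expect_error(filter_reads(bad, caller_params()), "malformed")
})

test_that("ungapped alignment keeps exact-length reads and counts rejections", {
  ref <- make_marker_reference(50, 0, seed = 20, marker_name = "m")
  two_snp <- mutate_at(ref$sequence, c(5, 10))
  reads <- data.frame(
    sample_id = "s1", marker = "m", read_id = c("exact", "snp2", "short"),
    seq = c(ref$sequence, two_snp, substr(ref$sequence, 1, 49)),
    qual = c(qual_string(50), qual_string(50), qual_string(49)),
    stringsAsFactors = FALSE)
  al <- align_reads(reads, ref)
  expect_setequal(al$aligned$read_id, c("exact", "snp2"))
  expect_equal(al$n_rejected, 1)
  expect_equal(snp_distance(two_snp, ref$sequence), 2)
})

test_that("the 1% calling threshold is strictly greater-than", {
  ref <- make_marker_reference(40, 0, seed = 21, marker_name = "m")
  variant <- mutate_at(ref$sequence, 3)
  variant2 <- mutate_at(ref$sequence, 7)
  # 46,000 reads: a 460-read variant (exactly 1%) is NOT called; 461 is
  counts <- c(46000 - 460, 460)
  names(counts) <- c(ref$sequence, variant)
  tab <- call_strains(reads_from_counts(counts), ref)
  expect_equal(nrow(tab$registry), 1)
  counts2 <- c(46000 - 461, 461)
  names(counts2) <- c(ref$sequence, variant2)
  tab2 <- call_strains(reads_from_counts(counts2), ref)
  expect_equal(nrow(tab2$registry), 2)
})

test_that("registry admission needs one sample above threshold; presence is per sample", {
  ref <- make_marker_reference(40, 0, seed = 22, marker_name = "m")
  h <- mutate_at(ref$sequence, 3)
  # H at 5% in sample A and 0.2% in sample B
  a <- c(950, 50); names(a) <- c(ref$sequence, h)
  b <- c(998, 2); names(b) <- c(ref$sequence, h)
  reads <- rbind(reads_from_counts(a, "A"), reads_from_counts(b, "B"))
  tab <- call_strains(reads, ref)
  expect_equal(nrow(tab$registry), 2)
  hid <- tab$registry$strain_id[tab$registry$sequence == h]
  cc <- tab$counts
  expect_true(cc$present[cc$strain_id == hid & cc$sample_id == "A"])
  expect_false(cc$present[cc$strain_id == hid & cc$sample_id == "B"])
  # sub-threshold raw counts are retained alongside
  expect_equal(cc$count[cc$strain_id == hid & cc$sample_id == "B"], 2)
  # single sample all identical reads: one strain at frequency 1
  solo <- call_strains(reads_from_counts(stats::setNames(100, ref$sequence)), ref)
  expect_equal(nrow(solo$registry), 1)
  expect_equal(solo$counts$frequency, 1)
})

test_that("haplotype counts are conserved and order-invariant", {
  truth <- small_truth(n_bees = 4, n_clusters = 2, strains_per_cluster = 3,
                       markers = "m1", error_rate = 0.002,
                       coverage_mean = 800, seed = 23)
  sim <- simulate_reads(truth, read_sim_params(coverage_mean = 800,
                                               error_rate = 0.002, seed = 24))
  ref <- truth$references$m1
  tab <- call_strains(sim$reads, ref)
  # conservation: per sample, haplotype counts sum to retained aligned reads
  for (s in unique(tab$totals$sample_id)) {
    tot <- tab$totals[tab$totals$sample_id == s, ]
    fr <- filter_reads(sim$reads[sim$reads$sample_id == s, ], caller_params())
    al <- align_reads(fr$retained, ref)
    expect_equal(tot$n_aligned, nrow(al$aligned))
  }
  # permutation invariance: shuffle read order and sample order
  shuffled <- sim$reads[sample.int(nrow(sim$reads)), ]
  tab2 <- call_strains(shuffled, ref)
  expect_equal(tab$registry, tab2$registry)
  expect_equal(tab$counts[order(tab$counts$sample_id, tab$counts$strain_id), ],
               tab2$counts[order(tab2$counts$sample_id, tab2$counts$strain_id), ],
               ignore_attr = TRUE)
})

test_that("error-free calling recovers exactly the planted strains", {
  truth <- small_truth(n_bees = 8, n_clusters = 3, strains_per_cluster = 4,
                       markers = "m1", error_rate = 0, coverage_mean = 2000,
                       seed = 25)
  sim <- simulate_reads(truth, read_sim_params(coverage_mean = 2000,
                                               error_rate = 0, seed = 26))
  tab <- call_strains(sim$reads, truth$references$m1)
  planted <- unique(truth_strains(truth, "m1")$sequence)
  expect_setequal(tab$registry$sequence, planted)
})

test_that("raising the frequency threshold never enlarges the registry", {
  truth <- small_truth(n_bees = 6, n_clusters = 3, strains_per_cluster = 4,
                       markers = "m1", error_rate = 0.005,
                       coverage_mean = 1000, seed = 27)
  sim <- simulate_reads(truth, read_sim_params(coverage_mean = 1000,
                                               error_rate = 0.005, seed = 28))
  sizes <- vapply(c(0.005, 0.01, 0.02, 0.05, 0.2), function(thr) {
    nrow(call_strains(sim$reads, truth$references$m1,
                      caller_params(freq_threshold = thr))$registry)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("snp_distance is a metric on haplotypes and demands a shared marker", {
  ref <- make_marker_reference(60, 0, seed = 29, marker_name = "m")
  a <- ref$sequence
  b <- mutate_at(a, c(2, 9))
  c_ <- mutate_at(a, c(9, 30, 41))
  expect_equal(snp_distance(a, a), 0)
  expect_equal(snp_distance(a, b), snp_distance(b, a))
  for (pair in list(c(a, b), c(a, c_), c(b, c_))) {
    third <- setdiff(c(a, b, c_), pair)
    expect_lte(snp_distance(pair[1], pair[2]),
               snp_distance(pair[1], third) + snp_distance(third, pair[2]))
  }
  ra <- data.frame(marker = "m1", sequence = a, stringsAsFactors = FALSE)
  rb <- data.frame(marker = "m2", sequence = b, stringsAsFactors = FALSE)
  expect_error(snp_distance(ra, rb), "same marker")
})

test_that("cryptic rescue counts single-read support and reports fold change", {
  ref <- make_marker_reference(40, 0, seed = 30, marker_name = "m")
  h1 <- mutate_at(ref$sequence, 2)
  h2 <- mutate_at(ref$sequence, 5)
  # h1 above threshold in both samples; h2 above in A, single sub-threshold
  # read in B
  a <- c(850, 100, 50); names(a) <- c(ref$sequence, h1, h2)
  b <- c(900, 99, 1); names(b) <- c(ref$sequence, h1, h2)
  reads <- rbind(reads_from_counts(a, "A"), reads_from_counts(b, "B"))
  tab <- call_strains(reads, ref)
  rc <- rescue_cryptic(tab, reads)
  r1 <- rc[rc$strain_id == tab$registry$strain_id[tab$registry$sequence == h1], ]
  r2 <- rc[rc$strain_id == tab$registry$strain_id[tab$registry$sequence == h2], ]
  expect_equal(r1$fold_change, 1)         # already everywhere
  expect_equal(r2$strict_prevalence, 0.5) # strict: A only
  expect_equal(r2$relaxed_prevalence, 1)  # relaxed: the single read in B counts
  expect_equal(r2$fold_change, 2)
  expect_true(all(rc$relaxed_prevalence >= rc$strict_prevalence))
})
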