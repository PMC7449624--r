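# Shared fixtures: small planted-truth scenarios and helpers.

# Substitute the bases at 'pos' with a deterministic different base.
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
  paste0(ch, collapse = "")
}

# High-quality Phred+33 string of the given length.
qual_string <- function(len, phred = 40L) strrep(rawToChar(as.raw(phred + 33L)), len)

# A read data frame row-set built from explicit haplotype counts for one
# sample; all reads at the given quality.
reads_from_counts <- function(counts, sample_id = "s1", marker = "m",
                              phred = 40L) {
  seqs <- rep(names(counts), counts)
  data.frame(sample_id = sample_id, marker = marker,
             read_id = sprintf("%s|%06d", sample_id, seq_along(seqs)),
             seq = seqs, qual = qual_string(nchar(names(counts)[1]), phred),
             stringsAsFactors = FALSE)
}

# Small two-marker planted truth used across tests.
small_truth <- function(n_bees = 12, n_clusters = 5, strains_per_cluster = 4,
                        two_cluster_fraction = 0, error_rate = 0,
                        coverage_mean = 2000, seed = 11, markers = c("guaA", "gluS"),
                        location_bias = 0, locations = NULL) {
  refs <- lapply(markers, function(m) {
    make_marker_reference(450, 0, seed = derive_seed(seed, m), marker_name = m)
  })
  if (is.null(locations)) {
    locations <- c(A = ceiling(n_bees / 2), B = floor(n_bees / 2))
  }
  make_truth(refs, n_bees = n_bees, locations = locations,
             n_clusters = n_clusters, strains_per_cluster = strains_per_cluster,
             two_cluster_fraction = two_cluster_fraction,
             location_bias = location_bias,
             error_rate = error_rate, coverage_mean = coverage_mean,
             seed = seed)
}

# Adjusted Rand index between two labelings (same order).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Independent reference MCL (Python/numpy); returns 1-based membership.
oracle_mcl <- function(S, inflation, expansion = 2, prune = 1e-5,
                       tol = 1e-8, max_iter = 200, self_loops = 1) {
  script <- system.file("oracle", "mcl_reference.py", package = "mastkit")
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write.table(S, tf, sep = "\t", row.names = FALSE, col.names = FALSE)
  out <- system2("python", c(script, tf, inflation, expansion, prune, tol,
                             max_iter, self_loops), stdout = TRUE)
  as.integer(out) + 1L
}

# Do two labelings describe the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Random community-structured symmetric score matrix on n nodes.
random_community_graph <- function(n = 30, k = 4) {
  mem <- sample(k, n, replace = TRUE)
  S <- matrix(runif(n * n, 0, 0.15), n, n)
  same <- outer(mem, mem, "==")
  S[same] <- S[same] + runif(sum(same), 0.4, 0.6)
  S <- pmin((S + t(S)) / 2, 1)
  diag(S) <- 1
  S
}

# Random presence matrix generated by the reassortment null itself:
# per-host richness preserved, strains drawn by prevalence weights.
null_presence <- function(n_strains = 20, n_hosts = 30) {
  prev <- sample(3:12, n_strains, replace = TRUE)
  rich <- sample(2:6, n_hosts, replace = TRUE)
  P <- matrix(FALSE, n_strains, n_hosts,
              dimnames = list(sprintf("s%03d", seq_len(n_strains)),
                              sprintf("b%03d", seq_len(n_hosts))))
  for (b in seq_len(n_hosts)) {
    P[sample.int(n_strains, rich[b], prob = prev), b] <- TRUE
  }
  P
}

# Map called strain ids to planted cluster labels via registry sequences.
planted_labels <- function(table, truth, marker, strain_ids) {
  ts <- truth_strains(truth, marker)
  reg <- table$registry[table$registry$marker == marker, ]
  seqs <- reg$sequence[match(strain_ids, reg$strain_id)]
  ts$cluster[match(seqs, ts$sequence)]
}
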