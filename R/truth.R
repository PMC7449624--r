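#' Generate a synthetic truth set with planted strain clusters
#'
#' Builds the ground truth the read simulator and recovery tests consume:
#' per marker, `n_clusters` clusters of closely related strains (a founder
#' plus mutants a few substitutions away), a shared relative-abundance
#' profile per cluster, and per-bee cluster assignments. The defaults
#' emulate the structure the analysis assumes in real bee guts: clusters of
#' 3--4 strains typically one SNP apart, most bees carrying a single
#' cluster, clusters shared across geographic locations with conserved
#' within-cluster strain frequencies.
#'
#' @param references A `marker_reference` or list of them (one per marker).
#' @param n_bees Number of bees (samples).
#' @param locations Named integer vector of location sizes; must sum to
#'   `n_bees`. The study design this mirrors sampled 103/21/9/11 bees from
#'   four US states.
#' @param n_clusters Number of planted clusters per marker.
#' @param strains_per_cluster Strains per cluster (founder included).
#' @param within_cluster_snps Maximum substitutions separating a cluster
#'   member from its founder (default 1).
#' @param between_cluster_snps Substitutions separating each founder from
#'   the marker reference (default 8), so clusters are well separated.
#' @param two_cluster_fraction Fraction of bees carrying a second cluster
#'   (default 0.1); the secondary cluster receives 30% of the bee's
#'   community.
#' @param location_bias In `[0, 1]`: 0 distributes clusters independently
#'   of location; 1 makes each cluster exclusive to its home location.
#' @param profile_concentration Dirichlet-like concentration of the
#'   within-cluster abundance profile (larger = more even).
#' @param error_rate Per-base substitution error rate carried into read
#'   simulation (default 0.001, a typical post-merge Illumina error rate).
#' @param coverage_mean Expected reads per (bee, marker); the study design
#'   averaged ~46,000.
#' @param seed Integer seed.
#' @return An object of class `truth_set`.
#' @export
make_truth <- function(references, n_bees, locations,
                       n_clusters, strains_per_cluster,
                       within_cluster_snps = 1L,
                       between_cluster_snps = 8L,
                       two_cluster_fraction = 0.1,
                       location_bias = 0,
                       profile_concentration = 5,
                       error_rate = 0.001,
                       coverage_mean = 46000,
                       seed = 1L) {
  references <- as_reference_list(references)
  locations <- stats::setNames(as.integer(locations), names(locations))
  if (is.null(names(locations)) || any(!nzchar(names(locations)))) {
    stop("'locations' must be a named vector of sizes", call. = FALSE)
  }
  if (sum(locations) != n_bees) stop("location sizes must sum to n_bees", call. = FALSE)
  if (strains_per_cluster < 1) stop("strains_per_cluster must be >= 1", call. = FALSE)
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (location_bias < 0 || location_bias > 1) stop("location_bias must be in [0,1]", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]", call. = FALSE)

  local_seed(seed, {
    bee_ids <- sprintf("bee%03d", seq_len(n_bees))
    bee_loc <- rep(names(locations), locations)
    cluster_home <- rep(names(locations), length.out = n_clusters)

    clusters <- list(); profiles <- list(); carried <- list()
    for (marker in names(references)) {
      ref <- references[[marker]]
      L <- nchar(ref$sequence)
      # founders: distinct sequences a fixed number of substitutions from
      # the reference
      founders <- character(0)
      guard <- 0L
      while (length(founders) < n_clusters) {
        pos <- sample.int(L, between_cluster_snps)
        refb <- strsplit(ref$sequence, "")[[1]][pos]
        cand <- apply_snps(ref$sequence, pos, random_alt_bases(refb))
        if (!cand %in% founders && cand != ref$sequence) {
          founders <- c(founders, cand)
        }
        guard <- guard + 1L
        if (guard > 100L * n_clusters) stop("could not generate distinct founders")
      }
      marker_clusters <- vector("list", n_clusters)
      for (ci in seq_len(n_clusters)) {
        members <- founders[ci]
        if (strains_per_cluster > 1L) {
          # each mutant mutates its own positions so members stay distinct
          pool <- sample.int(L, (strains_per_cluster - 1L) * within_cluster_snps)
          for (si in seq_len(strains_per_cluster - 1L)) {
            k <- if (within_cluster_snps > 1L) sample.int(within_cluster_snps, 1L) else 1L
            take <- pool[seq_len(k)]; pool <- pool[-seq_len(k)]
            fb <- strsplit(founders[ci], "")[[1]][take]
            members <- c(members, apply_snps(founders[ci], take, random_alt_bases(fb)))
          }
        }
        marker_clusters[[ci]] <- members
      }
      clusters[[marker]] <- marker_clusters

      # shared relative-abundance profile per cluster, floored so every
      # member is comfortably above the 1% calling threshold
      floor_freq <- min(0.05, 0.5 / strains_per_cluster)
      profiles[[marker]] <- lapply(seq_len(n_clusters), function(ci) {
        for (try in 1:100) {
          w <- stats::rgamma(strains_per_cluster, shape = profile_concentration)
          p <- w / sum(w)
          if (min(p) >= floor_freq) return(p)
        }
        rep(1 / strains_per_cluster, strains_per_cluster)
      })

      # cluster assignment: balanced shuffled round-robin when unbiased
      # (guarantees every cluster is carried when n_bees >= n_clusters)
      if (location_bias == 0) {
        primary <- sample(rep_len(seq_len(n_clusters), n_bees))
      } else {
        primary <- vapply(seq_len(n_bees), function(b) {
          own <- which(cluster_home == bee_loc[b])
          if (length(own) && stats::runif(1) < location_bias) {
            own[sample.int(length(own), 1L)]
          } else {
            sample.int(n_clusters, 1L)
          }
        }, integer(1))
      }
      carried_m <- as.list(primary)
      n2 <- round(two_cluster_fraction * n_bees)
      if (n2 > 0 && n_clusters > 1L) {
        second_bees <- sample.int(n_bees, n2)
        for (b in second_bees) {
          alt <- sample(setdiff(seq_len(n_clusters), primary[b]), 1L)
          carried_m[[b]] <- c(primary[b], alt)
        }
      }
      names(carried_m) <- bee_ids
      carried[[marker]] <- carried_m
    }

    structure(
      list(references = references,
           clusters = clusters,
           abundance_profiles = profiles,
           bee_assignments = data.frame(bee_id = bee_ids, location = bee_loc,
                                        stringsAsFactors = FALSE),
           carried = carried,
           two_cluster_secondary_weight = 0.3,
           error_rate = error_rate,
           coverage_mean = coverage_mean,
           seed = as.integer(seed)),
      class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d bees (%s), %d marker(s)\n",
              nrow(x$bee_assignments),
              paste(sprintf("%s:%d", names(table(x$bee_assignments$location)),
                            table(x$bee_assignments$location)), collapse = ", "),
              length(x$references)))
  for (m in names(x$clusters)) {
    cat(sprintf("  %s: %d clusters, %d strains\n", m, length(x$clusters[[m]]),
                sum(lengths(x$clusters[[m]]))))
  }
  invisible(x)
}

# Per-bee strain composition for one marker: named numeric vector of
# frequencies over strain sequences. Primary cluster gets weight
# (1 - w2) when a secondary cluster is carried.
truth_bee_composition <- function(truth, marker, bee_id) {
  cl <- truth$carried[[marker]][[bee_id]]
  w2 <- truth$two_cluster_secondary_weight
  weights <- if (length(cl) == 2L) c(1 - w2, w2) else 1
  seqs <- character(0); freqs <- numeric(0)
  for (i in seq_along(cl)) {
    seqs <- c(seqs, truth$clusters[[marker]][[cl[i]]])
    freqs <- c(freqs, truth$abundance_profiles[[marker]][[cl[i]]] * weights[i])
  }
  # a strain could in principle appear in two clusters; pool
  tapply(freqs, seqs, sum)
}

#' All planted strains of a truth set for one marker
#'
#' @param truth A `truth_set`.
#' @param marker Marker name.
#' @return Data frame with columns `cluster`, `sequence`.
#' @export
truth_strains <- function(truth, marker) {
  cl <- truth$clusters[[marker]]
  data.frame(cluster = rep(seq_along(cl), lengths(cl)),
             sequence = unlist(cl, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Build a minimal strain table from a presence/absence matrix
#'
#' For calibration studies of the randomization machinery it is often
#' convenient to specify strain presence directly rather than simulate
#' reads. Registry sequences are unknown (`NA`), so sequence-based
#' operations (SNP distances, codon weights) do not apply to the result.
#'
#' @param P Logical matrix, strains x samples, with dimnames.
#' @param marker Marker name (default `"m"`).
#' @return A `strain_table` backing the given presence pattern.
#' @export
strain_table_from_presence <- function(P, marker = "m") {
  stopifnot(is.matrix(P), !is.null(rownames(P)), !is.null(colnames(P)))
  ref <- structure(list(marker_name = marker,
                        sequence = strrep("A", 40L), frame_offset = 0L),
                   class = "marker_reference")
  reg <- data.frame(strain_id = rownames(P), marker = marker,
                    sequence = NA_character_, n_snps = NA_integer_,
                    total_count = rowSums(P), stringsAsFactors = FALSE)
  idx <- which(P, arr.ind = TRUE)
  counts <- data.frame(sample_id = colnames(P)[idx[, 2]], marker = marker,
                       strain_id = rownames(P)[idx[, 1]], count = 1,
                       frequency = 0.5, present = TRUE,
                       stringsAsFactors = FALSE)
  totals <- data.frame(sample_id = colnames(P), marker = marker,
                       n_raw = ncol(P), n_qc = ncol(P), n_aligned = ncol(P),
                       missing = FALSE, stringsAsFactors = FALSE)
  new_strain_table(reg, counts, totals,
                   references = stats::setNames(list(ref), marker),
                   params = caller_params())
}

#' Build the strain table implied directly by a truth set
#'
#' Bypasses read simulation and calling: every planted strain is observed at
#' its exact planted frequency (infinite error-free coverage). Useful for
#' fast calibration studies of the randomization machinery.
#'
#' @param truth A `truth_set`.
#' @param freq_threshold Presence threshold (strict `>`), default 0.01.
#' @return A `strain_table`.
#' @export
strain_table_from_truth <- function(truth, freq_threshold = 0.01) {
  bee_ids <- truth$bee_assignments$bee_id
  counts_list <- list(); registry_list <- list(); totals_list <- list()
  for (marker in names(truth$references)) {
    comp <- lapply(bee_ids, function(b) truth_bee_composition(truth, marker, b))
    names(comp) <- bee_ids
    haps <- sort(unique(unlist(lapply(comp, names))))
    freq <- matrix(0, length(haps), length(bee_ids),
                   dimnames = list(haps, bee_ids))
    for (b in bee_ids) freq[names(comp[[b]]), b] <- comp[[b]]
    keep <- rowSums(freq > freq_threshold) > 0
    freq <- freq[keep, , drop = FALSE]
    cov <- truth$coverage_mean
    reg <- registry_from_counts(rownames(freq), rowSums(freq) * cov,
                                truth$references[[marker]])
    registry_list[[marker]] <- reg
    id_of <- stats::setNames(reg$strain_id, reg$sequence)
    cl <- expand.grid(strain_id = unname(id_of[rownames(freq)]),
                      sample_id = bee_ids, stringsAsFactors = FALSE)
    cl$marker <- marker
    cl$frequency <- as.vector(freq)
    cl$count <- round(cl$frequency * cov)
    cl$present <- cl$frequency > freq_threshold
    counts_list[[marker]] <- cl[cl$frequency > 0, ]
    totals_list[[marker]] <- data.frame(
      sample_id = bee_ids, marker = marker, n_raw = cov, n_qc = cov,
      n_aligned = cov, missing = FALSE, stringsAsFactors = FALSE)
  }
  new_strain_table(
    registry = do.call(rbind, registry_list),
    counts = do.call(rbind, counts_list),
    totals = do.call(rbind, totals_list),
    references = truth$references,
    params = caller_params(freq_threshold = freq_threshold))
}
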