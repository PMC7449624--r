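new_permutation_result <- function(test, observed, expected_mean, expected_sd,
                                   chi_square, df, p_raw, n_tests, n_reps,
                                   seed, applicable = TRUE, note = NULL) {
  structure(list(test = test, observed = observed,
                 expected_mean = expected_mean, expected_sd = expected_sd,
                 chi_square = chi_square, df = df, p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_tests), n_tests = n_tests,
                 n_reps = n_reps, seed = seed, applicable = applicable,
                 note = note),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s\n", x$test))
  if (!x$applicable) {
    cat("  not applicable:", x$note %||% "", "\n")
    return(invisible(x))
  }
  cat(sprintf("  chi-square = %.3f (df = %d), p = %.4g (Bonferroni x%d: %.4g)\n",
              x$chi_square, x$df, x$p_raw, x$n_tests, x$p_bonferroni))
  cat(sprintf("  %d randomizations, seed %d\n", x$n_reps, x$seed))
  invisible(x)
}

# chi-square statistic of observed counts against expected counts;
# categories with zero expectation are dropped.
chi_square_stat <- function(obs, expected) {
  keep <- expected > 0
  sum((obs[keep] - expected[keep])^2 / expected[keep])
}

# permutation p-value: fraction of null statistics >= observed (add-one).
perm_pvalue <- function(stat_obs, stat_null) {
  (1 + sum(stat_null >= stat_obs - 1e-12)) / (length(stat_null) + 1)
}

#' Geography randomization test of strain-location association
#'
#' Compares the number of distinct strains observed per location with the
#' expectation under random allocation of hosts to locations (location
#' sizes preserved). The chi-square statistic of the per-location strain
#' counts against the randomization mean is computed, and the p-value is
#' calibrated against the permutation distribution of the same statistic.
#'
#' @param table A `strain_table`.
#' @param metadata Data frame with `sample_id`-compatible first column
#'   (`bee_id` or `sample_id`) and `location`.
#' @param marker Marker name.
#' @param n_reps Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @param n_tests Bonferroni factor (number of markers tested; default 1).
#' @return A `permutation_result` with per-location observed counts.
#' @export
location_shuffle_test <- function(table, metadata, marker, n_reps = 1000L,
                                  seed = 1L, n_tests = 1L) {
  idcol <- if ("sample_id" %in% names(metadata)) "sample_id" else "bee_id"
  P <- presence_matrix(table, marker)
  meta <- metadata[match(colnames(P), metadata[[idcol]]), ]
  loc <- meta$location
  locs <- names(which(table(loc) > 0))
  if (length(locs) < 2L) stop("need >= 2 locations with hosts", call. = FALSE)
  dropped <- setdiff(unique(metadata$location), locs)
  if (length(dropped)) warning("locations without hosts excluded: ",
                               paste(dropped, collapse = ", "))
  count_by_loc <- function(lab) {
    vapply(locs, function(l) {
      sum(rowSums(P[, lab == l, drop = FALSE]) > 0)
    }, numeric(1))
  }
  observed <- count_by_loc(loc)
  null_counts <- local_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) count_by_loc(sample(loc)),
             numeric(length(locs))))
  })
  expected_mean <- colMeans(null_counts)
  expected_sd <- apply(null_counts, 2, stats::sd)
  chi_obs <- chi_square_stat(observed, expected_mean)
  chi_null <- apply(null_counts, 1, chi_square_stat, expected = expected_mean)
  new_permutation_result(
    test = sprintf("location_shuffle (%s)", marker),
    observed = observed, expected_mean = expected_mean,
    expected_sd = expected_sd, chi_square = chi_obs,
    df = length(locs) - 1L,
    p_raw = perm_pvalue(chi_obs, chi_null),
    n_tests = n_tests, n_reps = n_reps, seed = as.integer(seed))
}

# Redraw each host's strain set under the reassortment null: richness
# preserved, strains drawn without replacement weighted by observed
# prevalence.
reassort_presence <- function(P, richness, prevalence) {
  Pn <- matrix(FALSE, nrow(P), ncol(P), dimnames = dimnames(P))
  n <- nrow(P)
  for (b in seq_len(ncol(P))) {
    r <- richness[b]
    if (r > 0L) Pn[sample.int(n, r, prob = prevalence), b] <- TRUE
  }
  Pn
}

# Histogram of pairwise co-occurrence counts (upper triangle of P %*% t(P)),
# as counts over 0..n_hosts.
pair_count_hist <- function(P, cross = NULL) {
  n_hosts <- ncol(P)
  if (is.null(cross)) {
    C <- P %*% t(P)
    vals <- C[upper.tri(C)]
  } else {
    vals <- as.vector(P %*% t(cross))
  }
  tabulate(vals + 1L, nbins = n_hosts + 1L)
}

# Merge adjacent histogram categories until every group's expected count
# is >= min_expected (classical chi-square validity rule); returns a
# grouping index vector.
merge_bins <- function(expected, min_expected = 5) {
  n <- length(expected)
  g <- integer(n)
  gid <- 1L
  acc <- 0
  for (i in seq_len(n)) {
    g[i] <- gid
    acc <- acc + expected[i]
    if (acc >= min_expected && i < n) {
      gid <- gid + 1L
      acc <- 0
    }
  }
  if (acc < min_expected && acc > 0 && gid > 1L) g[g == gid] <- gid - 1L
  match(g, unique(g))
}

collapse_hist <- function(h, grouping) {
  as.vector(tapply(h, grouping, sum))
}

#' Strain reassortment null for within-marker co-occurrence
#'
#' Tests whether strains co-occur within hosts more (or less) than expected
#' if each host's strain set were assembled at random. The null reassorts
#' strains across hosts, preserving each host's strain richness and the
#' overall strain prevalences; the statistic is the chi-square distance
#' between the observed distribution of pairwise co-occurrence counts and
#' its null mean (categories merged until every expected count is >= 5),
#' calibrated against the permutation distribution.
#'
#' @param table A `strain_table`.
#' @param marker Marker name.
#' @param n_reps Number of reassortments (default 1000).
#' @param seed Integer seed.
#' @param n_tests Bonferroni factor (default 1).
#' @return A `permutation_result`.
#' @export
reassortment_null <- function(table, marker, n_reps = 1000L, seed = 1L,
                              n_tests = 1L) {
  P <- presence_matrix(table, marker)
  P <- P[rowSums(P) > 0, , drop = FALSE]
  if (nrow(P) < 2L || ncol(P) < 2L) {
    return(new_permutation_result(
      test = sprintf("reassortment (%s)", marker), observed = NULL,
      expected_mean = NULL, expected_sd = NULL, chi_square = NA_real_,
      df = NA_integer_, p_raw = NA_real_, n_tests = n_tests,
      n_reps = n_reps, seed = as.integer(seed), applicable = FALSE,
      note = "need >= 2 strains and >= 2 hosts"))
  }
  richness <- colSums(P)
  prevalence <- rowSums(P)
  obs_hist <- pair_count_hist(P)
  null_hists <- local_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      pair_count_hist(reassort_presence(P, richness, prevalence))
    }, numeric(length(obs_hist))))
  })
  expected <- colMeans(null_hists)
  grouping <- merge_bins(expected)
  null_m <- t(apply(null_hists, 1, collapse_hist, grouping = grouping))
  exp_m <- colMeans(null_m)
  obs_m <- collapse_hist(obs_hist, grouping)
  chi_obs <- chi_square_stat(obs_m, exp_m)
  chi_null <- apply(null_m, 1, chi_square_stat, expected = exp_m)
  new_permutation_result(
    test = sprintf("reassortment (%s)", marker),
    observed = obs_m, expected_mean = exp_m,
    expected_sd = apply(null_m, 2, stats::sd),
    chi_square = chi_obs, df = length(exp_m) - 1L,
    p_raw = perm_pvalue(chi_obs, chi_null),
    n_tests = n_tests, n_reps = n_reps, seed = as.integer(seed))
}

#' Interspecies (cross-marker) strain association test
#'
#' Tests whether strains of one marker (species) associate with strains of
#' another across hosts. Pairwise cross-marker co-occurrence counts over
#' the shared hosts are compared to a null that reassorts whole strain
#' compositions across hosts: each randomization permutes which host's
#' composition of the second marker accompanies which host's composition
#' of the first. This preserves each marker's internal co-occurrence
#' structure (its strain clusters) exactly and randomizes only the
#' cross-marker pairing, so the test is calibrated even when strains
#' travel in tight clusters within each marker.
#'
#' @param table_x,table_y `strain_table`s (may be the same object).
#' @param marker_x,marker_y Marker names in the respective tables.
#' @param n_reps Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @param n_tests Bonferroni factor (default 1).
#' @return A `permutation_result`.
#' @export
interspecies_association_test <- function(table_x, table_y, marker_x,
                                          marker_y, n_reps = 1000L,
                                          seed = 1L, n_tests = 1L) {
  Px <- presence_matrix(table_x, marker_x)
  Py <- presence_matrix(table_y, marker_y)
  shared <- intersect(colnames(Px), colnames(Py))
  if (length(shared) < 2L) stop("markers share fewer than 2 hosts", call. = FALSE)
  Px <- Px[rowSums(Px[, shared, drop = FALSE]) > 0, shared, drop = FALSE]
  Py <- Py[rowSums(Py[, shared, drop = FALSE]) > 0, shared, drop = FALSE]
  obs_hist <- pair_count_hist(Px, cross = Py)
  n <- length(shared)
  null_hists <- local_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      pair_count_hist(Px, cross = Py[, sample.int(n), drop = FALSE])
    }, numeric(length(obs_hist))))
  })
  expected <- colMeans(null_hists)
  grouping <- merge_bins(expected)
  null_m <- t(apply(null_hists, 1, collapse_hist, grouping = grouping))
  exp_m <- colMeans(null_m)
  obs_m <- collapse_hist(obs_hist, grouping)
  chi_obs <- chi_square_stat(obs_m, exp_m)
  chi_null <- apply(null_m, 1, chi_square_stat, expected = exp_m)
  new_permutation_result(
    test = sprintf("interspecies (%s x %s)", marker_x, marker_y),
    observed = obs_m, expected_mean = exp_m,
    expected_sd = apply(null_m, 2, stats::sd),
    chi_square = chi_obs, df = length(exp_m) - 1L,
    p_raw = perm_pvalue(chi_obs, chi_null),
    n_tests = n_tests, n_reps = n_reps, seed = as.integer(seed))
}

#' Strain saturation (accumulation) curve
#'
#' Average number of distinct strains recovered as a function of the
#' number of hosts sampled. Each of `n_combinations` replicates draws a
#' random permutation of the hosts and accumulates strains along its
#' prefixes, so every realized curve is monotone non-decreasing and the
#' size-`N` value equals the total strain count exactly. A plateau
#' indicates the sampled hosts have exhausted the strain diversity.
#'
#' @param table A `strain_table`.
#' @param marker Marker name.
#' @param n_combinations Number of random host orderings (default 100).
#' @param seed Integer seed.
#' @return Object of class `saturation_curve`: data frame `curve` with
#'   columns `k` and `mean_strains`, plus `n_combinations` and `marker`.
#' @export
saturation_curve <- function(table, marker, n_combinations = 100L, seed = 1L) {
  P <- presence_matrix(table, marker)
  N <- ncol(P)
  if (N < 1L) stop("need at least 1 host", call. = FALSE)
  acc <- local_seed(seed, {
    sapply(seq_len(n_combinations), function(r) {
      ord <- sample.int(N)
      seen <- rep(FALSE, nrow(P))
      out <- numeric(N)
      for (k in seq_len(N)) {
        seen <- seen | P[, ord[k]]
        out[k] <- sum(seen)
      }
      out
    })
  })
  acc <- matrix(acc, nrow = N)
  structure(list(curve = data.frame(k = seq_len(N),
                                    mean_strains = rowMeans(acc)),
                 n_combinations = n_combinations, marker = marker,
                 seed = as.integer(seed)),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  N <- nrow(x$curve)
  cat(sprintf(
    "<saturation_curve> %s: %d hosts, %.1f strains at k=1, %g at k=%d\n",
    x$marker, N, x$curve$mean_strains[1], x$curve$mean_strains[N], N))
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  plot(x$curve$k, x$curve$mean_strains, type = "b", pch = 16,
       xlab = "hosts sampled", ylab = "mean distinct strains",
       main = x$marker, ...)
  invisible(x)
}
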