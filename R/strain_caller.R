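#' Strain-calling parameters
#'
#' @param min_mean_phred Minimum arithmetic-mean Phred score a read must
#'   reach to be retained (default 30; a mean of exactly 30 is retained,
#'   only means strictly below are discarded).
#' @param freq_threshold Calling threshold on within-sample frequency
#'   (default 0.01, strict `>`): a haplotype becomes a strain if it exceeds
#'   this frequency in at least one sample. At a mean coverage of 46,000
#'   reads the default corresponds to 460 reads per strain per sample.
#' @param allow_n Keep reads containing ambiguous bases (default `FALSE`).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_mean_phred = 30, freq_threshold = 0.01,
                          allow_n = FALSE) {
  if (freq_threshold <= 0 || freq_threshold >= 1) {
    stop("freq_threshold must be in (0, 1)", call. = FALSE)
  }
  structure(list(min_mean_phred = min_mean_phred,
                 freq_threshold = freq_threshold,
                 allow_n = isTRUE(allow_n)),
            class = "caller_params")
}

#' Quality-filter reads
#'
#' Retains reads whose arithmetic-mean Phred score is at least
#' `min_mean_phred` (strictly lower means are discarded) and, unless
#' `allow_n`, discards reads containing N.
#'
#' @param reads Data frame with at least `seq` and `qual` columns
#'   (Phred+33), as returned by [simulate_reads()] or [read_fastq_dir()].
#' @param params A `caller_params`.
#' @return List with `retained` (the surviving rows), `n_low_quality` and
#'   `n_ambiguous`.
#' @export
filter_reads <- function(reads, params = caller_params()) {
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("malformed reads: sequence and quality lengths differ", call. = FALSE)
  }
  mq <- mean_phred(reads$qual)
  ok_q <- mq >= params$min_mean_phred
  has_n <- grepl("[^ACGT]", reads$seq)
  ok_n <- params$allow_n | !has_n
  list(retained = reads[ok_q & ok_n, , drop = FALSE],
       n_low_quality = sum(!ok_q),
       n_ambiguous = sum(ok_q & !ok_n))
}

#' Ungapped end-to-end alignment of merged amplicon reads
#'
#' Merged amplicons are fixed-length, so any indel forces a length change;
#' a read is therefore accepted as gap-free if and only if its length
#' equals the reference length. Accepted reads return their base string as
#' the haplotype; no mismatch limit is imposed. Length-mismatched reads
#' (which would require a gapped alignment) are rejected and counted.
#'
#' @param reads Data frame of reads (one marker).
#' @param ref The marker's `marker_reference`.
#' @return List with `aligned` (surviving rows) and `n_rejected`.
#' @export
align_reads <- function(reads, ref) {
  ok <- nchar(reads$seq) == nchar(ref$sequence)
  list(aligned = reads[ok, , drop = FALSE], n_rejected = sum(!ok))
}

# Deterministic strain ids: per marker, descending total read support,
# ties broken by haplotype lexicographic order.
registry_from_counts <- function(sequences, total_counts, ref) {
  if (!length(sequences)) {
    return(data.frame(strain_id = character(0), marker = character(0),
                      sequence = character(0), n_snps = integer(0),
                      total_count = numeric(0), stringsAsFactors = FALSE))
  }
  sequences <- as.character(sequences)
  ord <- order(-total_counts, sequences)
  sequences <- sequences[ord]
  n_snps <- vapply(sequences, hamming, integer(1), b = ref$sequence,
                   USE.NAMES = FALSE)
  data.frame(strain_id = sprintf("%s_s%03d", ref$marker_name,
                                 seq_along(sequences)),
             marker = ref$marker_name,
             sequence = sequences,
             n_snps = n_snps,
             total_count = unname(total_counts[ord]),
             stringsAsFactors = FALSE)
}

new_strain_table <- function(registry, counts, totals, references, params) {
  rownames(registry) <- NULL; rownames(counts) <- NULL; rownames(totals) <- NULL
  structure(list(registry = registry, counts = counts, totals = totals,
                 references = references, params = params),
            class = "strain_table")
}

#' Call strains from merged amplicon reads
#'
#' The central inference step: reads are quality-filtered (mean Phred),
#' aligned ungapped (exact length), pooled into identical-haplotype counts
#' per (sample, marker), and a haplotype is promoted to a strain if its
#' frequency exceeds `freq_threshold` (strict `>`) in at least one sample.
#' Frequencies are computed against the retained, aligned reads of that
#' (sample, marker). Registry strains are then reported in every sample
#' with their raw counts; the `present` flag applies the same strict
#' threshold per sample.
#'
#' @param reads Data frame with columns `sample_id`, `marker`, `seq`,
#'   `qual` (see [simulate_reads()]).
#' @param references A `marker_reference` or list of them.
#' @param params A `caller_params`.
#' @param samples Optional character vector of all expected sample ids;
#'   samples without reads for a marker are recorded as missing.
#' @return An object of class `strain_table` with elements `registry`
#'   (strain_id, marker, sequence, n_snps, total_count), `counts`
#'   (sample_id, marker, strain_id, count, frequency, present) and
#'   `totals` (per sample/marker read accounting).
#' @export
call_strains <- function(reads, references, params = caller_params(),
                         samples = NULL) {
  references <- as_reference_list(references)
  if (nrow(reads) == 0L) {
    warning("no reads supplied; returning empty strain table")
    empty_counts <- data.frame(sample_id = character(0), marker = character(0),
                               strain_id = character(0), count = numeric(0),
                               frequency = numeric(0), present = logical(0),
                               stringsAsFactors = FALSE)
    return(new_strain_table(
      registry = data.frame(strain_id = character(0), marker = character(0),
                            sequence = character(0), n_snps = integer(0),
                            total_count = numeric(0), stringsAsFactors = FALSE),
      counts = empty_counts,
      totals = data.frame(sample_id = character(0), marker = character(0),
                          n_raw = integer(0), n_qc = integer(0),
                          n_aligned = integer(0), missing = logical(0),
                          stringsAsFactors = FALSE),
      references = references, params = params))
  }
  samples <- sort(unique(c(samples, reads$sample_id)))

  registry_list <- list(); counts_list <- list(); totals_list <- list()
  for (marker in names(references)) {
    ref <- references[[marker]]
    mreads <- reads[reads$marker == marker, , drop = FALSE]
    n_raw <- table(factor(mreads$sample_id, levels = samples))
    fr <- filter_reads(mreads, params)
    n_qc <- table(factor(fr$retained$sample_id, levels = samples))
    al <- align_reads(fr$retained, ref)
    ar <- al$aligned
    n_aligned <- table(factor(ar$sample_id, levels = samples))

    # haplotype x sample count matrix
    haps <- sort(unique(ar$seq))
    cnt <- matrix(0, length(haps), length(samples),
                  dimnames = list(haps, samples))
    if (nrow(ar)) {
      tab <- table(ar$seq, factor(ar$sample_id, levels = samples))
      cnt[rownames(tab), colnames(tab)] <- tab
    }
    tot <- colSums(cnt)
    freq <- sweep(cnt, 2, pmax(tot, 1), "/")
    called <- rowSums(freq > params$freq_threshold) > 0
    cnt <- cnt[called, , drop = FALSE]
    freq <- freq[called, , drop = FALSE]

    reg <- registry_from_counts(rownames(cnt), rowSums(cnt), ref)
    registry_list[[marker]] <- reg
    if (nrow(reg)) {
      id_of <- stats::setNames(reg$strain_id, reg$sequence)
      cl <- expand.grid(strain_id = unname(id_of[rownames(cnt)]),
                        sample_id = samples, stringsAsFactors = FALSE)
      cl$marker <- marker
      cl$count <- as.vector(cnt)
      cl$frequency <- as.vector(freq)
      cl$present <- cl$frequency > params$freq_threshold
      counts_list[[marker]] <- cl[cl$count > 0, c("sample_id", "marker",
                                                  "strain_id", "count",
                                                  "frequency", "present")]
    }
    totals_list[[marker]] <- data.frame(
      sample_id = samples, marker = marker,
      n_raw = as.integer(n_raw), n_qc = as.integer(n_qc),
      n_aligned = as.integer(n_aligned),
      missing = as.integer(n_raw) == 0L, stringsAsFactors = FALSE)
  }
  new_strain_table(
    registry = do.call(rbind, registry_list),
    counts = do.call(rbind, counts_list) %||%
      data.frame(sample_id = character(0), marker = character(0),
                 strain_id = character(0), count = numeric(0),
                 frequency = numeric(0), present = logical(0)),
    totals = do.call(rbind, totals_list),
    references = references, params = params)
}

#' @export
print.strain_table <- function(x, ...) {
  cat(sprintf("<strain_table> %d strain(s), %d sample(s), %d marker(s)\n",
              nrow(x$registry), length(unique(x$totals$sample_id)),
              length(x$references)))
  for (m in names(x$references)) {
    cat(sprintf("  %s: %d strains\n", m, sum(x$registry$marker == m)))
  }
  invisible(x)
}

#' @export
summary.strain_table <- function(object, ...) {
  summarize_strain_diversity(object)
}

#' Strain presence/absence matrix for one marker
#'
#' @param table A `strain_table`.
#' @param marker Marker name.
#' @param samples Optional sample ids to include (default: all non-missing
#'   samples for the marker).
#' @return Logical matrix, strains x samples, `TRUE` where the strain's
#'   frequency exceeds the calling threshold in that sample.
#' @export
presence_matrix <- function(table, marker, samples = NULL) {
  stopifnot(inherits(table, "strain_table"))
  tot <- table$totals[table$totals$marker == marker, ]
  if (is.null(samples)) samples <- tot$sample_id[!tot$missing]
  strains <- table$registry$strain_id[table$registry$marker == marker]
  P <- matrix(FALSE, length(strains), length(samples),
              dimnames = list(strains, samples))
  cc <- table$counts[table$counts$marker == marker & table$counts$present &
                       table$counts$sample_id %in% samples, ]
  if (nrow(cc)) P[cbind(cc$strain_id, cc$sample_id)] <- TRUE
  P
}

#' Number of SNPs between two strains of the same marker
#'
#' Hamming distance between the full haplotypes; zero if and only if the
#' sequences are identical.
#'
#' @param a,b Either character sequences of equal length, or rows
#'   (one-row data frames) of a strain registry with `marker` and
#'   `sequence` fields.
#' @return Integer SNP count.
#' @export
snp_distance <- function(a, b) {
  if (is.data.frame(a)) {
    if (!is.data.frame(b) || a$marker != b$marker) {
      stop("strains must come from the same marker", call. = FALSE)
    }
    a <- a$sequence; b <- b$sequence
  }
  hamming(a, b)
}

# All pairwise SNP distances among a set of sequences.
snp_distance_matrix <- function(sequences) {
  n <- length(sequences)
  m <- matrix(0L, n, n)
  if (n < 2L) return(m)
  chars <- do.call(rbind, strsplit(sequences, ""))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(chars[i, ] != chars[j, ])
      m[i, j] <- d; m[j, i] <- d
    }
  }
  m
}

#' Cryptic-strain rescue: relaxed single-read prevalence
#'
#' Re-searches the complete read pool (including low-quality and
#' sub-threshold reads) for the exact haplotype of every called strain. A
#' strain is considered present in a sample under the relaxed rule if it is
#' supported by at least one read anywhere in that sample's pool, versus
#' the strict rule (frequency above the calling threshold). Prevalences are
#' fractions of samples with any reads for the marker.
#'
#' @param table A `strain_table`.
#' @param reads The full read pool data frame (`sample_id`, `marker`,
#'   `seq`), i.e. the unfiltered input to [call_strains()].
#' @return Data frame with `strain_id`, `marker`, `strict_prevalence`,
#'   `relaxed_prevalence`, `fold_change` (`Inf` when the strict prevalence
#'   is zero).
#' @export
rescue_cryptic <- function(table, reads) {
  stopifnot(inherits(table, "strain_table"))
  if (!nrow(table$registry)) stop("empty strain registry", call. = FALSE)
  out <- lapply(names(table$references), function(marker) {
    reg <- table$registry[table$registry$marker == marker, ]
    if (!nrow(reg)) return(NULL)
    mreads <- reads[reads$marker == marker, ]
    samples <- sort(unique(mreads$sample_id))
    n_samples <- length(samples)
    P <- presence_matrix(table, marker, samples = samples)
    strict <- rowSums(P) / n_samples
    # relaxed: exact haplotype supported by >=1 read in the sample's pool
    relaxed <- vapply(reg$sequence, function(s) {
      length(unique(mreads$sample_id[mreads$seq == s]))
    }, numeric(1), USE.NAMES = FALSE) / n_samples
  data.frame(strain_id = reg$strain_id, marker = marker,
             strict_prevalence = unname(strict[reg$strain_id]),
             relaxed_prevalence = relaxed,
             stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$fold_change <- ifelse(res$strict_prevalence > 0,
                            res$relaxed_prevalence / res$strict_prevalence,
                            ifelse(res$relaxed_prevalence > 0, Inf, NaN))
  rownames(res) <- NULL
  res
}
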