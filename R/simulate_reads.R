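#' Read-simulation parameters
#'
#' @param coverage_mean Expected reads per (bee, marker). The emulated study
#'   averaged ~46,000; tests use scaled-down coverages.
#' @param coverage_dispersion Negative-binomial size parameter for the
#'   per-sample coverage draw (smaller = more overdispersed). The emulated
#'   data show substantial coverage variability but no stated distribution.
#' @param error_rate Per-base substitution error probability in `[0, 0.05]`.
#' @param phred_high Quality value assigned to correctly copied bases.
#' @param phred_low Quality value assigned to erroneous bases, so that the
#'   downstream quality filter can be exercised deliberately.
#' @param seed Integer seed.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(coverage_mean = 46000, coverage_dispersion = 10,
                            error_rate = 0.001, phred_high = 40L,
                            phred_low = 15L, seed = 1L) {
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]", call. = FALSE)
  if (coverage_mean <= 0) stop("coverage_mean must be > 0", call. = FALSE)
  structure(list(coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate,
                 phred_high = as.integer(phred_high),
                 phred_low = as.integer(phred_low),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate merged amplicon reads from a truth set
#'
#' For each (bee, marker) a coverage is drawn from an overdispersed
#' (negative binomial) count law, reads are allocated to the bee's strains
#' by its planted abundance profile, and independent per-base substitution
#' errors are applied. Erroneous bases are flagged with `phred_low`
#' qualities, correct bases with `phred_high`. Output is deterministic
#' given `params$seed` byte for byte.
#'
#' @param truth A `truth_set` from [make_truth()].
#' @param params A `read_sim_params`. `error_rate`/`coverage_mean` default
#'   to the truth set's values when the params are built with the truth.
#' @param out_dir Optional output directory. When given, one Phred+33
#'   FASTQ per (bee, marker) is written (`<bee>_<marker>.fastq`) together
#'   with `metadata.tsv`, `references.fasta` (+ offsets sidecar) and
#'   `params.yaml`, and the file manifest is returned. When `NULL`, reads
#'   are returned in memory.
#' @return With `out_dir = NULL`, a list with `reads` (data frame:
#'   `sample_id`, `marker`, `read_id`, `seq`, `qual`) and `metadata`.
#'   Otherwise the manifest data frame, invisibly.
#' @export
simulate_reads <- function(truth, params = read_sim_params(), out_dir = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(params, "read_sim_params"))
  bee_ids <- truth$bee_assignments$bee_id
  markers <- names(truth$references)
  phred_chr_high <- rawToChar(as.raw(params$phred_high + 33L))
  phred_chr_low <- rawToChar(as.raw(params$phred_low + 33L))

  out <- local_seed(params$seed, {
    res <- vector("list", length(bee_ids) * length(markers))
    k <- 0L
    for (bee in bee_ids) {
      for (marker in markers) {
        k <- k + 1L
        L <- nchar(truth$references[[marker]]$sequence)
        comp <- truth_bee_composition(truth, marker, bee)
        cov <- stats::rnbinom(1L, size = params$coverage_dispersion,
                              mu = params$coverage_mean)
        if (cov == 0L) {
          res[[k]] <- data.frame(sample_id = character(0), marker = character(0),
                                 read_id = character(0), seq = character(0),
                                 qual = character(0), stringsAsFactors = FALSE)
          next
        }
        n_per <- stats::rmultinom(1L, cov, comp)[, 1L]
        seqs <- rep(names(comp), n_per)
        quals <- rep(strrep(phred_chr_high, L), cov)
        n_err <- stats::rbinom(cov, L, params$error_rate)
        for (i in which(n_err > 0L)) {
          pos <- sample.int(L, n_err[i])
          ch <- strsplit(seqs[i], "")[[1]]
          ch[pos] <- random_alt_bases(ch[pos])
          seqs[i] <- paste0(ch, collapse = "")
          qc <- strsplit(quals[i], "")[[1]]
          qc[pos] <- phred_chr_low
          quals[i] <- paste0(qc, collapse = "")
        }
        ord <- sample.int(cov)
        res[[k]] <- data.frame(
          sample_id = bee, marker = marker,
          read_id = sprintf("%s|%s|%06d", bee, marker, seq_len(cov)),
          seq = seqs[ord], qual = quals[ord], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  })
  rownames(out) <- NULL

  if (is.null(out_dir)) {
    return(list(reads = out, metadata = truth$bee_assignments))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- expand.grid(sample_id = bee_ids, marker = markers,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$sample_id, manifest$marker), ]
  manifest$file <- file.path(out_dir, sprintf("%s_%s.fastq", manifest$sample_id,
                                              manifest$marker))
  for (i in seq_len(nrow(manifest))) {
    sub <- out[out$sample_id == manifest$sample_id[i] &
                 out$marker == manifest$marker[i], ]
    dna <- Biostrings::DNAStringSet(sub$seq)
    names(dna) <- sub$read_id
    # writeXStringSet notes that the qualities are carried as metadata
    # columns; the notice is expected and harmless here
    withCallingHandlers(
      Biostrings::writeXStringSet(dna, manifest$file[i], format = "fastq",
                                  qualities = Biostrings::BStringSet(sub$qual)),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  utils::write.table(truth$bee_assignments, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_marker_references(truth$references, file.path(out_dir, "references.fasta"))
  yaml::write_yaml(unclass(params), file.path(out_dir, "params.yaml"))
  rownames(manifest) <- NULL
  invisible(manifest)
}

#' Read simulated (or real, pre-merged) FASTQ reads from a directory
#'
#' Expects one FASTQ per (sample, marker) named `<sample>_<marker>.fastq`
#' as written by [simulate_reads()].
#'
#' @param dir Directory of FASTQ files.
#' @return Data frame with columns `sample_id`, `marker`, `read_id`, `seq`,
#'   `qual`.
#' @export
read_fastq_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fastq$", full.names = TRUE))
  if (!length(files)) stop("no .fastq files found in ", dir, call. = FALSE)
  # reading and coercing the quality-scaled sets emits notices about
  # dropped quality metadata columns; those are expected here
  parts <- withCallingHandlers(
    lapply(files, function(fp) {
      base <- sub("\\.fastq$", "", basename(fp))
      us <- regexpr("_[^_]+$", base)
      sample_id <- substr(base, 1L, us - 1L)
      marker <- substr(base, us + 1L, nchar(base))
      dna <- Biostrings::readQualityScaledDNAStringSet(fp)
      if (!length(dna)) {
        return(data.frame(sample_id = character(0), marker = character(0),
                          read_id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE))
      }
      data.frame(sample_id = sample_id, marker = marker,
                 read_id = names(dna),
                 seq = as.character(dna),
                 qual = as.character(Biostrings::quality(dna)),
                 stringsAsFactors = FALSE)
    }),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
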