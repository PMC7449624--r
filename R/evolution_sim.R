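#' Codon position of marker coordinates
#'
#' Maps 1-based positions along a marker to codon positions 1--3 using the
#' reference's reading-frame offset. Positions before the first complete
#' codon are returned as `NA` (they belong to no codon class).
#'
#' @param pos Integer positions (1-based).
#' @param ref A `marker_reference`.
#' @return Integer vector of codon positions (1, 2, 3 or `NA`).
#' @export
codon_position <- function(pos, ref) {
  out <- ((pos - ref$frame_offset - 1L) %% 3L) + 1L
  out[pos <= ref$frame_offset] <- NA_integer_
  out
}

#' Empirical codon-position substitution weights from a strain registry
#'
#' The fraction of distinct observed SNPs falling at each codon position.
#' In protein-coding markers under purifying selection most SNPs fall at
#' the third position; these weights drive the selection-mode evolution
#' simulation. SNPs before the first complete codon are excluded.
#'
#' @param strains Character vector of full-length haplotypes, or a strain
#'   registry data frame with a `sequence` column (one marker).
#' @param ref The marker's `marker_reference`.
#' @return Numeric triple `(p1, p2, p3)` summing to 1.
#' @export
estimate_codon_weights <- function(strains, ref) {
  if (is.data.frame(strains)) strains <- strains$sequence
  snps <- unique(do.call(rbind, lapply(strains, snp_set, ref = ref$sequence)))
  if (is.null(snps) || !nrow(snps)) stop("no SNPs observed in the registry", call. = FALSE)
  cp <- codon_position(snps$pos, ref)
  cp <- cp[!is.na(cp)]
  if (!length(cp)) stop("no SNPs within complete codons", call. = FALSE)
  w <- tabulate(cp, nbins = 3L) / length(cp)
  stats::setNames(w, c("p1", "p2", "p3"))
}

#' Simulate sets of strain sequences by a Poisson substitution process
#'
#' Emulates two in-silico experiments about whether shared haplotypes
#' across hosts can arise artifactually. For every host (`n_bees`) and
#' every one of `strains_per_bee` strains, a SNP count is drawn from
#' `Poisson(mean_snps)` and that many distinct positions are mutated on
#' the reference: uniformly along the sequence (PCR-artifact mode,
#' `codon_weights = NULL`) or by first drawing a codon-position class from
#' `codon_weights` and then a uniform site within the class
#' (purifying-selection mode). Substituted bases are drawn uniformly among
#' the three alternatives; positions within one sequence are drawn without
#' replacement (no back-mutation).
#'
#' @param reference A `marker_reference`.
#' @param n_bees Number of simulated hosts (the emulated study used 144).
#' @param strains_per_bee Sequences per host (6 for three of the emulated
#'   markers, 16 for the fourth).
#' @param mean_snps Poisson mean of the SNP count per sequence.
#' @param codon_weights `NULL` for uniform placement, or a numeric triple
#'   `(p1, p2, p3)` summing to 1.
#' @param seed Integer seed.
#' @return Object of class `simulated_strain_sets`: `sequences` (list of
#'   character vectors, one per host), `provenance` (data frame of applied
#'   SNPs: `bee`, `strain`, `pos`, `ref`, `alt`), plus the parameters.
#' @export
simulate_strain_set <- function(reference, n_bees = 144L,
                                strains_per_bee = 6L, mean_snps,
                                codon_weights = NULL, seed = 1L) {
  stopifnot(inherits(reference, "marker_reference"), n_bees >= 1)
  L <- nchar(reference$sequence)
  if (mean_snps < 0 || mean_snps > L) {
    stop("mean_snps must be in [0, reference length]", call. = FALSE)
  }
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  class_sites <- NULL
  if (!is.null(codon_weights)) {
    if (length(codon_weights) != 3L || abs(sum(codon_weights) - 1) > 1e-9) {
      stop("codon_weights must be three probabilities summing to 1", call. = FALSE)
    }
    cp <- codon_position(seq_len(L), reference)
    class_sites <- lapply(1:3, function(k) which(!is.na(cp) & cp == k))
    if (any(codon_weights > 0 & lengths(class_sites) == 0)) {
      stop("a codon class with positive weight has no sites", call. = FALSE)
    }
  }

  local_seed(seed, {
    sequences <- vector("list", n_bees)
    p_bee <- list(); p_strain <- list(); p_pos <- list(); p_alt <- list()
    pi <- 0L
    for (b in seq_len(n_bees)) {
      ks <- stats::rpois(strains_per_bee, mean_snps)
      seqs <- character(strains_per_bee)
      for (s in seq_len(strains_per_bee)) {
        k <- ks[s]
        if (k == 0L) {
          seqs[s] <- reference$sequence
          next
        }
        if (is.null(class_sites)) {
          k <- min(k, L)
          pos <- sample.int(L, k)
        } else {
          avail <- lengths(class_sites)
          k <- min(k, sum(avail[codon_weights > 0]))
          draws <- integer(0)
          remaining <- class_sites
          w <- codon_weights
          while (length(draws) < k) {
            open <- lengths(remaining) > 0 & w > 0
            cls <- sample.int(3L, 1L, prob = ifelse(open, w, 0))
            i <- sample.int(length(remaining[[cls]]), 1L)
            draws <- c(draws, remaining[[cls]][i])
            remaining[[cls]] <- remaining[[cls]][-i]
          }
          pos <- draws
        }
        alt <- random_alt_bases(ref_chars[pos])
        ch <- ref_chars
        ch[pos] <- alt
        seqs[s] <- paste0(ch, collapse = "")
        pi <- pi + 1L
        p_bee[[pi]] <- rep.int(b, k); p_strain[[pi]] <- rep.int(s, k)
        p_pos[[pi]] <- pos; p_alt[[pi]] <- alt
      }
      sequences[[b]] <- seqs
    }
    pos_all <- unlist(p_pos) %||% integer(0)
    provenance <- data.frame(bee = unlist(p_bee) %||% integer(0),
                             strain = unlist(p_strain) %||% integer(0),
                             pos = pos_all,
                             ref = ref_chars[pos_all],
                             alt = unlist(p_alt) %||% character(0),
                             stringsAsFactors = FALSE)
    rownames(provenance) <- NULL
    structure(list(sequences = sequences, provenance = provenance,
                   reference = reference, n_bees = as.integer(n_bees),
                   strains_per_bee = as.integer(strains_per_bee),
                   mean_snps = mean_snps, codon_weights = codon_weights,
                   seed = as.integer(seed)),
              class = "simulated_strain_sets")
  })
}

#' @export
print.simulated_strain_sets <- function(x, ...) {
  cat(sprintf(
    "<simulated_strain_sets> %s: %d bees x %d strains (Poisson mean %.3g, %s)\n",
    x$reference$marker_name, x$n_bees, x$strains_per_bee, x$mean_snps,
    if (is.null(x$codon_weights)) "uniform placement"
    else sprintf("codon weights %.2f/%.2f/%.2f", x$codon_weights[1],
                 x$codon_weights[2], x$codon_weights[3])))
  invisible(x)
}

#' Count cross-host convergent sequences in a simulation
#'
#' A convergent sequence is a distinct non-reference sequence generated
#' independently in at least two different hosts; each such sequence is
#' counted once. Zero means no convergence, i.e. identical haplotypes in
#' different hosts cannot be explained by the simulated process.
#'
#' @param sets A `simulated_strain_sets`.
#' @return Integer count of convergent sequences.
#' @seealso [convergence_summary()] for distinct-sequence and within-host
#'   duplicate counts.
#' @export
count_convergence <- function(sets) {
  convergence_summary(sets)$n_convergent
}

#' Summary of a simulated strain set
#'
#' @param sets A `simulated_strain_sets`.
#' @return List with `n_sequences`, `n_distinct` (distinct generated
#'   sequences, reference-identical copies included as one), `n_convergent`
#'   (distinct non-reference sequences seen in >= 2 hosts) and
#'   `n_within_bee_duplicates` (distinct sequences duplicated inside a
#'   single host only).
#' @export
convergence_summary <- function(sets) {
  stopifnot(inherits(sets, "simulated_strain_sets"))
  seqs <- unlist(sets$sequences, use.names = FALSE)
  bees <- rep(seq_along(sets$sequences), lengths(sets$sequences))
  nonref <- seqs != sets$reference$sequence
  n_bees_per_seq <- tapply(bees, seqs, function(b) length(unique(b)))
  n_copies_per_seq <- table(seqs)
  convergent <- names(n_bees_per_seq)[n_bees_per_seq >= 2L &
                                        names(n_bees_per_seq) != sets$reference$sequence]
  within_dup <- names(n_copies_per_seq)[n_copies_per_seq >= 2L &
                                          n_bees_per_seq[names(n_copies_per_seq)] == 1L]
  list(n_sequences = length(seqs),
       n_distinct = length(unique(seqs)),
       n_convergent = length(convergent),
       n_within_bee_duplicates = length(within_dup))
}

#' Write simulated strain sets to FASTA
#'
#' Sequence ids encode host, strain index and placement mode.
#'
#' @param sets A `simulated_strain_sets`.
#' @param file Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_simulated_fasta <- function(sets, file) {
  seqs <- unlist(sets$sequences, use.names = FALSE)
  bees <- rep(seq_along(sets$sequences), lengths(sets$sequences))
  idx <- unlist(lapply(sets$sequences, seq_along), use.names = FALSE)
  mode <- if (is.null(sets$codon_weights)) "uniform" else "selection"
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("%s|bee%03d|strain%02d|%s",
                        sets$reference$marker_name, bees, idx, mode)
  Biostrings::writeXStringSet(dna, file)
  invisible(file)
}
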