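#' Per-marker strain diversity summary
#'
#' @param table A `strain_table`.
#' @return Data frame with one row per marker: `n_strains` (registry
#'   size), `mean_strains_per_bee`, `sd_strains_per_bee` (over samples
#'   with data) and `mean_pairwise_snps` (mean SNP distance over all
#'   strain pairs; `NA` with fewer than 2 strains).
#' @export
summarize_strain_diversity <- function(table) {
  stopifnot(inherits(table, "strain_table"))
  if (!nrow(table$registry)) stop("empty strain table", call. = FALSE)
  rows <- lapply(names(table$references), function(marker) {
    reg <- table$registry[table$registry$marker == marker, ]
    P <- presence_matrix(table, marker)
    per_bee <- if (ncol(P)) colSums(P) else numeric(0)
    mps <- if (nrow(reg) >= 2L) {
      d <- snp_distance_matrix(reg$sequence)
      mean(d[upper.tri(d)])
    } else NA_real_
    data.frame(marker = marker,
               n_strains = nrow(reg),
               mean_strains_per_bee = if (length(per_bee)) mean(per_bee) else NA_real_,
               sd_strains_per_bee = if (length(per_bee) > 1L) stats::sd(per_bee) else 0,
               mean_pairwise_snps = mps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read count corresponding to the calling threshold
#'
#' @param coverage Reads per (sample, marker).
#' @param freq_threshold Calling threshold (default 0.01). At the emulated
#'   study's mean coverage of 46,000 the default corresponds to 460 reads.
#' @return Number of reads at the threshold frequency.
#' @export
reads_at_threshold <- function(coverage, freq_threshold = 0.01) {
  coverage * freq_threshold
}

#' Theoretical single-read detection limit, as a percentage
#'
#' The frequency corresponding to one read among all reads of a marker
#' across the whole data set.
#'
#' @param n_samples Number of samples.
#' @param coverage_mean Mean reads per (sample, marker).
#' @return Percent frequency of a single read.
#' @export
detection_limit <- function(n_samples, coverage_mean) {
  100 / (n_samples * coverage_mean)
}

#' Write a strain table to a directory of TSV files
#'
#' Writes `registry.tsv`, `counts.tsv`, `totals.tsv`, a presence/absence
#' matrix per marker (`presence_<marker>.tsv`), the references FASTA and
#' the caller parameters, such that [read_strain_table()] restores an
#' identical object.
#'
#' @param table A `strain_table`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_strain_table <- function(table, dir) {
  stopifnot(inherits(table, "strain_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(table$registry, "registry.tsv")
  wt(table$counts, "counts.tsv")
  wt(table$totals, "totals.tsv")
  for (marker in names(table$references)) {
    P <- presence_matrix(table, marker)
    wt(data.frame(strain_id = rownames(P), P + 0, check.names = FALSE),
       sprintf("presence_%s.tsv", marker))
  }
  write_marker_references(table$references, file.path(dir, "references.fasta"))
  yaml::write_yaml(unclass(table$params), file.path(dir, "caller_params.yaml"))
  invisible(dir)
}

#' Read a strain table written by [write_strain_table()]
#'
#' @param dir Directory path.
#' @return A `strain_table`.
#' @export
read_strain_table <- function(dir) {
  rd <- function(name, colClasses = NA) {
    utils::read.delim(file.path(dir, name), stringsAsFactors = FALSE,
                      colClasses = colClasses)
  }
  params <- yaml::read_yaml(file.path(dir, "caller_params.yaml"))
  new_strain_table(
    registry = rd("registry.tsv"),
    counts = rd("counts.tsv"),
    totals = rd("totals.tsv"),
    references = read_marker_references(file.path(dir, "references.fasta")),
    params = structure(params, class = "caller_params"))
}

#' Default pipeline configuration
#'
#' A single flat key/value configuration covering every stage. Unknown
#' keys passed via `...` or present in a config file are errors.
#'
#' @param out_dir Output directory.
#' @param ... Overrides of the defaults (see the returned list for keys).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = 1L,
    # synthetic data
    n_bees = 12L, locations = c(loc1 = 6L, loc2 = 6L),
    markers = c("guaA", "gluS"), marker_length = 450L, frame_offset = 0L,
    n_clusters = 5L, strains_per_cluster = 4L, within_cluster_snps = 1L,
    between_cluster_snps = 8L, two_cluster_fraction = 0.1,
    location_bias = 0, coverage_mean = 2000, coverage_dispersion = 10,
    error_rate = 0.001, phred_high = 40L, phred_low = 15L,
    # calling
    min_mean_phred = 30, freq_threshold = 0.01,
    # clustering
    inflation = 2, inflation_sweep = NULL,
    # randomization
    n_reps = 1000L, n_combinations = 100L,
    # evolution simulation
    evolve_strains_per_bee = 6L, evolve_mean_snps = 8,
    evolve_codon_weights = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_run_config(structure(cfg, class = "run_config"))
}

validate_run_config <- function(cfg) {
  if (cfg$freq_threshold <= 0 || cfg$freq_threshold >= 1) {
    stop("freq_threshold must be in (0, 1)", call. = FALSE)
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]", call. = FALSE)
  }
  if (sum(cfg$locations) != cfg$n_bees) {
    stop("location sizes must sum to n_bees", call. = FALSE)
  }
  if (cfg$inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  cfg
}

#' Read a pipeline configuration from a YAML key/value file
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir)) stop("config must set out_dir", call. = FALSE)
  if (!is.null(raw$locations)) raw$locations <- unlist(raw$locations)
  do.call(run_config, raw)
}

stage_checksum <- function(cfg, stage, keys) {
  vals <- cfg[keys]
  digest_input <- paste(stage, paste(deparse(vals), collapse = ""), collapse = "|")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(digest_input, tf)
  unname(tools::md5sum(tf))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order: simulate reads from a planted
#' truth, call strains, build co-occurrence graphs and cluster them,
#' run the randomization tests and saturation curves, run the evolution
#' simulation, and write a run report. Each stage derives its own seed
#' from the global seed and its name; stages whose parameters are
#' unchanged since the previous run (checksum match) are skipped. All
#' stage outputs are written under `cfg$out_dir`.
#'
#' @param cfg A `run_config` (or path to a YAML config file).
#' @return Invisibly, the run report (also written to
#'   `run_report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state_file <- file.path(out, "stage_state.json")
  state <- if (file.exists(state_file)) {
    jsonlite::read_json(state_file, simplifyVector = TRUE)
  } else list()
  report <- list(package_version = as.character(utils::packageVersion("mastkit")),
                 seed = cfg$seed, config = cfg[setdiff(names(cfg), "out_dir")],
                 stages = list())

  sim_keys <- c("seed", "n_bees", "locations", "markers", "marker_length",
                "frame_offset", "n_clusters", "strains_per_cluster",
                "within_cluster_snps", "between_cluster_snps",
                "two_cluster_fraction", "location_bias", "coverage_mean",
                "coverage_dispersion", "error_rate", "phred_high", "phred_low")
  call_keys <- c(sim_keys, "min_mean_phred", "freq_threshold")

  # -- simulate ---------------------------------------------------------
  ck <- stage_checksum(cfg, "simulate", sim_keys)
  reads_dir <- file.path(out, "reads")
  if (!identical(state$simulate, ck) || !dir.exists(reads_dir)) {
    refs <- lapply(seq_along(cfg$markers), function(i) {
      make_marker_reference(cfg$marker_length, cfg$frame_offset,
                            seed = derive_seed(cfg$seed, paste0("ref_", cfg$markers[i])),
                            marker_name = cfg$markers[i])
    })
    truth <- make_truth(refs, n_bees = cfg$n_bees, locations = cfg$locations,
                        n_clusters = cfg$n_clusters,
                        strains_per_cluster = cfg$strains_per_cluster,
                        within_cluster_snps = cfg$within_cluster_snps,
                        between_cluster_snps = cfg$between_cluster_snps,
                        two_cluster_fraction = cfg$two_cluster_fraction,
                        location_bias = cfg$location_bias,
                        error_rate = cfg$error_rate,
                        coverage_mean = cfg$coverage_mean,
                        seed = derive_seed(cfg$seed, "truth"))
    params <- read_sim_params(coverage_mean = cfg$coverage_mean,
                              coverage_dispersion = cfg$coverage_dispersion,
                              error_rate = cfg$error_rate,
                              phred_high = cfg$phred_high,
                              phred_low = cfg$phred_low,
                              seed = derive_seed(cfg$seed, "reads"))
    simulate_reads(truth, params, out_dir = reads_dir)
    truth_df <- do.call(rbind, lapply(names(truth$references), function(m) {
      ts <- truth_strains(truth, m); ts$marker <- m; ts
    }))
    utils::write.table(truth_df, file.path(out, "truth_strains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$simulate <- ck
    report$stages$simulate <- list(status = "run", n_bees = cfg$n_bees,
                                   markers = cfg$markers)
  } else {
    report$stages$simulate <- list(status = "skipped (unchanged)")
  }

  # -- call -------------------------------------------------------------
  ck <- stage_checksum(cfg, "call", call_keys)
  table_dir <- file.path(out, "strain_table")
  if (!identical(state$call, ck) || !dir.exists(table_dir)) {
    reads <- read_fastq_dir(reads_dir)
    refs <- read_marker_references(file.path(reads_dir, "references.fasta"))
    meta <- utils::read.delim(file.path(reads_dir, "metadata.tsv"),
                              stringsAsFactors = FALSE)
    params <- caller_params(min_mean_phred = cfg$min_mean_phred,
                            freq_threshold = cfg$freq_threshold)
    table <- call_strains(reads, refs, params, samples = meta$bee_id)
    write_strain_table(table, table_dir)
    state$call <- ck
    report$stages$call <- list(status = "run",
                               n_strains = nrow(table$registry))
  } else {
    table <- read_strain_table(table_dir)
    report$stages$call <- list(status = "skipped (unchanged)",
                               n_strains = nrow(table$registry))
  }
  meta <- utils::read.delim(file.path(reads_dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)

  # -- cluster ----------------------------------------------------------
  clusters <- list()
  for (marker in names(table$references)) {
    if (sum(table$registry$marker == marker) < 2L) next
    g <- build_cooccurrence_graph(table, marker)
    utils::write.table(data.frame(strain_id = g$strains, g$S, check.names = FALSE),
                       file.path(out, sprintf("S_%s.tsv", marker)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- mcl_cluster(g, inflation = cfg$inflation)
    clusters[[marker]] <- cl
    utils::write.table(
      data.frame(strain_id = names(cl$membership), cluster = cl$membership),
      file.path(out, sprintf("clusters_%s.tsv", marker)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    bs <- bee_similarity_matrix(table, marker)
    utils::write.table(data.frame(sample_id = rownames(bs), bs, check.names = FALSE),
                       file.path(out, sprintf("bee_similarity_%s.tsv", marker)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$stages$cluster <- list(
    status = "run", inflation = cfg$inflation,
    n_clusters = vapply(clusters, function(x) length(x$clusters), integer(1)))

  # -- randomize --------------------------------------------------------
  rand <- list()
  for (marker in names(table$references)) {
    loc <- location_shuffle_test(table, meta, marker, n_reps = cfg$n_reps,
                                 seed = derive_seed(cfg$seed, paste0("loc_", marker)),
                                 n_tests = length(table$references))
    rea <- reassortment_null(table, marker, n_reps = cfg$n_reps,
                             seed = derive_seed(cfg$seed, paste0("rea_", marker)),
                             n_tests = length(table$references))
    sat <- saturation_curve(table, marker, n_combinations = cfg$n_combinations,
                            seed = derive_seed(cfg$seed, paste0("sat_", marker)))
    utils::write.table(sat$curve, file.path(out, sprintf("saturation_%s.tsv", marker)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rand[[marker]] <- list(
      location = list(chi_square = loc$chi_square, p_raw = loc$p_raw,
                      p_bonferroni = loc$p_bonferroni),
      reassortment = list(chi_square = rea$chi_square, p_raw = rea$p_raw,
                          p_bonferroni = rea$p_bonferroni,
                          applicable = rea$applicable))
  }
  report$stages$randomize <- list(status = "run", n_reps = cfg$n_reps,
                                  tests = rand)

  # -- evolve -----------------------------------------------------------
  refs <- read_marker_references(file.path(reads_dir, "references.fasta"))
  evolve <- list()
  for (marker in names(refs)) {
    sets <- simulate_strain_set(
      refs[[marker]], n_bees = cfg$n_bees,
      strains_per_bee = cfg$evolve_strains_per_bee,
      mean_snps = cfg$evolve_mean_snps,
      codon_weights = cfg$evolve_codon_weights,
      seed = derive_seed(cfg$seed, paste0("evolve_", marker)))
    write_simulated_fasta(sets, file.path(out, sprintf("simulated_%s.fasta", marker)))
    evolve[[marker]] <- convergence_summary(sets)
  }
  report$stages$evolve <- list(status = "run", summaries = evolve)

  # -- report -----------------------------------------------------------
  report$stages$summary <- summarize_strain_diversity(table)
  jsonlite::write_json(state, state_file, auto_unbox = TRUE)
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
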