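#' Co-occurrence score between two strains
#'
#' The Sorensen-Dice-type score used throughout the package:
#' `S = 2 * b_AB / (b_A + b_B)`, the number of hosts containing both
#' strains divided by the average number of hosts containing either. `S`
#' is 1 iff both strains occupy exactly the same non-empty host set and 0
#' iff they share no host.
#'
#' @param b_ab Number of hosts containing both strains.
#' @param b_a,b_b Number of hosts containing each strain (each >= 1).
#' @return The score, in `[0, 1]`.
#' @examples
#' cooccurrence_score(3, 4, 6)  # 0.6
#' @export
cooccurrence_score <- function(b_ab, b_a, b_b) {
  if (any(b_a < 1) || any(b_b < 1)) stop("b_a and b_b must be >= 1", call. = FALSE)
  if (any(b_ab > pmin(b_a, b_b)) || any(b_ab < 0)) {
    stop("inconsistent counts: need 0 <= b_ab <= min(b_a, b_b)", call. = FALSE)
  }
  2 * b_ab / (b_a + b_b)
}

#' Build the strain co-occurrence graph for one marker
#'
#' Computes the full symmetric matrix of pairwise scores
#' `S = 2 b_AB / (b_A + b_B)` from the presence/absence matrix. The
#' diagonal is defined as 1. Strains absent from every sample are
#' excluded.
#'
#' @param table A `strain_table`.
#' @param marker Marker name.
#' @return An object of class `cooccurrence_graph` with fields `strains`,
#'   `S` (symmetric score matrix) and `b` (per-strain host counts), or an
#'   empty graph (with a warning) when fewer than 2 strains are observed.
#' @export
build_cooccurrence_graph <- function(table, marker) {
  P <- presence_matrix(table, marker)
  P <- P[rowSums(P) > 0, , drop = FALSE]
  if (nrow(P) < 2L) {
    warning("fewer than 2 observed strains for marker ", marker,
            "; returning empty graph")
    return(structure(list(strains = rownames(P),
                          S = matrix(numeric(0), 0, 0), b = integer(0),
                          marker = marker),
                     class = "cooccurrence_graph"))
  }
  b <- rowSums(P)
  b_ab <- P %*% t(P)
  S <- 2 * b_ab / outer(b, b, "+")
  diag(S) <- 1
  structure(list(strains = rownames(P), S = S, b = b, marker = marker),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("<cooccurrence_graph> %s: %d strains\n", x$marker,
              length(x$strains)))
  invisible(x)
}

#' @export
plot.cooccurrence_graph <- function(x, ...) {
  if (!length(x$strains)) return(invisible(x))
  graphics::image(seq_along(x$strains), seq_along(x$strains),
                  t(x$S[rev(seq_along(x$strains)), , drop = FALSE]),
                  xlab = "strain", ylab = "strain", main = x$marker,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Host (bee) similarity matrix from shared strain composition
#'
#' For two hosts with strain sets `U` and `V`, the score is
#' `2 |U ∩ V| / (|U| + |V|)`: 1 when the hosts are composed of exactly the
#' same strains, 0 when they share none. Hosts with no called strain are
#' reported as missing (`NA` rows/columns).
#'
#' @param table A `strain_table`.
#' @param marker Marker name.
#' @return Symmetric numeric matrix, samples x samples.
#' @export
bee_similarity_matrix <- function(table, marker) {
  P <- presence_matrix(table, marker)
  if (ncol(P) < 2L) stop("need at least 2 samples with data", call. = FALSE)
  sizes <- colSums(P)
  shared <- t(P) %*% P
  S <- 2 * shared / outer(sizes, sizes, "+")
  diag(S) <- 1
  S[sizes == 0, ] <- NA_real_
  S[, sizes == 0] <- NA_real_
  S
}

#' Markov clustering (MCL) of a co-occurrence graph
#'
#' Standard MCL on the score matrix: self-loops are set to
#' `self_loops`, columns are normalized to stochastic form, and expansion
#' (matrix power) alternates with inflation (entrywise power followed by
#' column renormalization) and pruning of small entries until the matrix
#' change falls below `tol` or `max_iter` is reached. Clusters are read off
#' the attractor rows of the limit matrix; nodes claimed by several
#' clusters are resolved deterministically (largest cluster first, then
#' lexicographically smallest member id). Higher inflation produces more,
#' smaller clusters.
#'
#' @param graph A `cooccurrence_graph`, or a symmetric numeric matrix with
#'   dimnames.
#' @param inflation Inflation exponent (> 1), default 2.0.
#' @param expansion Expansion power (integer >= 2), default 2.
#' @param prune_below Entries below this value are set to 0 each
#'   iteration (default 1e-5).
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the max absolute matrix change.
#' @param self_loops Self-loop weight added before normalization.
#' @return An object of class `strain_clusters`: `membership` (named
#'   integer vector), `clusters` (list of member id vectors, ordered by
#'   decreasing size), `converged`, `iterations`, `inflation`.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2L,
                        prune_below = 1e-5, max_iter = 200L, tol = 1e-8,
                        self_loops = 1) {
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  S <- if (inherits(graph, "cooccurrence_graph")) graph$S else as.matrix(graph)
  if (!nrow(S)) stop("empty graph", call. = FALSE)
  ids <- rownames(S) %||% sprintf("n%03d", seq_len(nrow(S)))
  diag(S) <- self_loops
  M <- sweep(S, 2, colSums(S), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mx <- M
    for (e in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    Mx[Mx < prune_below] <- 0
    cs <- colSums(Mx)
    cs[cs == 0] <- 1
    Mx <- sweep(Mx, 2, cs, "/")
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")

  # attractors: rows with positive diagonal mass; each attractor row's
  # support is a (possibly shared) cluster
  attractors <- which(diag(M) > tol)
  supports <- lapply(attractors, function(i) which(M[i, ] > tol))
  supports <- unique(supports)
  # resolve overlaps: biggest cluster wins, ties by smallest member id
  ord <- order(-lengths(supports),
               vapply(supports, function(s) min(ids[s]), character(1)))
  supports <- supports[ord]
  membership <- rep(NA_integer_, length(ids))
  cid <- 0L
  for (s in supports) {
    free <- s[is.na(membership[s])]
    if (!length(free)) next
    cid <- cid + 1L
    membership[free] <- cid
  }
  # unclaimed nodes (mass fully drained to a pruned attractor): singletons
  for (i in which(is.na(membership))) {
    cid <- cid + 1L
    membership[i] <- cid
  }
  clusters <- unname(split(ids, membership))
  ord <- order(-lengths(clusters), vapply(clusters, min, character(1)))
  clusters <- clusters[ord]
  membership <- stats::setNames(integer(length(ids)), ids)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  structure(list(membership = membership, clusters = clusters,
                 converged = converged, iterations = it,
                 inflation = inflation),
            class = "strain_clusters")
}

#' @export
print.strain_clusters <- function(x, ...) {
  cat(sprintf("<strain_clusters> %d clusters over %d strains (I = %g%s)\n",
              length(x$clusters), length(x$membership), x$inflation,
              if (x$converged) "" else ", NOT converged"))
  cat("  sizes:", paste(lengths(x$clusters), collapse = " "), "\n")
  invisible(x)
}

#' Run MCL across an inflation sweep
#'
#' @param graph A `cooccurrence_graph` or score matrix.
#' @param inflations Numeric vector of inflation values (default the
#'   canonical sweep 1.2, 2, 4, 6).
#' @param ... Further arguments to [mcl_cluster()].
#' @return Named list of `strain_clusters`, one per inflation.
#' @export
mcl_sweep <- function(graph, inflations = c(1.2, 2, 4, 6), ...) {
  res <- lapply(inflations, function(I) mcl_cluster(graph, inflation = I, ...))
  names(res) <- sprintf("I=%g", inflations)
  res
}

#' Cluster summary statistics
#'
#' Reports the three distributions used to characterize strain clusters:
#' strains per cluster, clusters per host (a cluster counts as present in a
#' host iff at least one member strain is present there), and the mean
#' within-cluster SNP distance per cluster.
#'
#' @param clusters A `strain_clusters`.
#' @param table The `strain_table` the clustering was built from.
#' @param marker Marker name.
#' @return List with `sizes`, `clusters_per_bee` (named integer vector) and
#'   `within_cluster_snp_means` (NA for singleton clusters).
#' @export
cluster_stats <- function(clusters, table, marker) {
  P <- presence_matrix(table, marker)
  reg <- table$registry[table$registry$marker == marker, ]
  seq_of <- stats::setNames(reg$sequence, reg$strain_id)
  sizes <- lengths(clusters$clusters)
  cpb <- vapply(colnames(P), function(b) {
    present <- rownames(P)[P[, b]]
    length(unique(clusters$membership[present]))
  }, integer(1))
  wmeans <- vapply(clusters$clusters, function(cl) {
    if (length(cl) < 2L) return(NA_real_)
    d <- snp_distance_matrix(unname(seq_of[cl]))
    mean(d[upper.tri(d)])
  }, numeric(1))
  list(sizes = sizes, clusters_per_bee = cpb,
       within_cluster_snp_means = wmeans)
}

#' Two-sample Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with the standard tie-corrected variance and no
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (rank-sum of `x`), `z` and `p_value`.
#' @export
ranksum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = W, z = 0, p_value = 1))
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = W, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Within- versus between-cluster SNP distances
#'
#' Splits all pairwise SNP distances among clustered strains by whether
#' the pair shares a cluster and compares the two sets with a two-sided
#' Wilcoxon rank-sum test. In well-formed clusterings the within-cluster
#' distances are much smaller.
#'
#' @param clusters A `strain_clusters`.
#' @param table The source `strain_table`.
#' @param marker Marker name.
#' @return List with `within`, `between` (distance vectors), `within_mean`,
#'   `between_mean`, `statistic`, `p_value` and `applicable` (`FALSE` when
#'   either set is empty, e.g. a single cluster).
#' @export
within_vs_between_snps <- function(clusters, table, marker) {
  reg <- table$registry[table$registry$marker == marker, ]
  ids <- names(clusters$membership)
  ids <- ids[ids %in% reg$strain_id]
  seqs <- reg$sequence[match(ids, reg$strain_id)]
  d <- snp_distance_matrix(seqs)
  same <- outer(clusters$membership[ids], clusters$membership[ids], "==")
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  if (!length(within) || !length(between)) {
    return(list(within = within, between = between,
                within_mean = mean(within), between_mean = mean(between),
                statistic = NA_real_, p_value = NA_real_, applicable = FALSE))
  }
  rs <- ranksum_test(within, between)
  list(within = within, between = between,
       within_mean = mean(within), between_mean = mean(between),
       statistic = rs$statistic, p_value = rs$p_value, applicable = TRUE)
}
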