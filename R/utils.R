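# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' All stochastic operations in the package funnel through this helper so
#' that a user-supplied seed fully determines the output without clobbering
#' the caller's RNG stream.
#' @noRd
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed and a stage name
#'
#' Deterministic, stays within the 32-bit integer range. Used by the
#' pipeline so that each stage has its own reproducible stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}

DNA_BASES <- c("A", "C", "G", "T")

# Hamming distance between two equal-length DNA strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(charToRaw(a) != charToRaw(b))
}

# Decode a Phred+33 quality string to integer scores.
decode_phred <- function(qual) as.integer(charToRaw(qual)) - 33L

# Mean Phred score per read, vectorised over a character vector.
mean_phred <- function(quals) {
  vapply(quals, function(q) mean(as.integer(charToRaw(q)) - 33L), numeric(1),
         USE.NAMES = FALSE)
}

# 1-based SNP list of a haplotype relative to a reference (same length).
snp_set <- function(seq, ref) {
  a <- charToRaw(seq); b <- charToRaw(ref)
  pos <- which(a != b)
  if (!length(pos)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(pos = pos,
             ref = strsplit(rawToChar(b[pos]), "")[[1]],
             alt = strsplit(rawToChar(a[pos]), "")[[1]],
             stringsAsFactors = FALSE)
}

# Apply substitutions (positions, bases) to a sequence string.
apply_snps <- function(ref, pos, alt) {
  ch <- strsplit(ref, "")[[1]]
  ch[pos] <- alt
  paste0(ch, collapse = "")
}

# Draw, for each reference base, a uniformly random alternative base
# (uniform over the 3 non-reference bases, vectorised).
random_alt_bases <- function(ref_bases) {
  idx <- match(ref_bases, DNA_BASES)
  shift <- sample.int(3L, length(ref_bases), replace = TRUE)
  DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
}
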