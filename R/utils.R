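#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.latsplice_env <- new.env(parent = emptyenv())

#' Enumerate the k-mer sequence space
#'
#' All DNA k-mers of a given length, in lexicographic order (A < C < G < T).
#'
#' @param k k-mer length (positive integer; the full table has `4^k` entries,
#'   so `k` must be small enough to enumerate).
#' @return Character vector of length `4^k`.
#' @export
#' @examples
#' kmer_space(2)
kmer_space <- function(k) {
  stopifnot(length(k) == 1, k >= 1, k <= 12)
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  g <- g[, rev(seq_len(k)), drop = FALSE]
  do.call(paste0, g)
}

# character matrix (n x k) from equal-length sequences
kmer_matrix <- function(seqs, k) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = k, byrow = TRUE)
}

# validate a training set of k-mers; returns k
validate_kmers <- function(seqs, what = "training_seqs") {
  if (length(seqs) == 0) abort(paste0(what, " is empty"))
  k <- unique(nchar(seqs))
  if (length(k) != 1) abort(paste0(what, " contains sequences of unequal length"))
  if (any(grepl("[^ACGT]", seqs))) {
    abort(paste0(what, " contains non-ACGT characters"))
  }
  as.integer(k)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based genomic subsequence [start, end) as a character string
genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(genome[[chrom]], start = start + 1, end = end))
  if (strand == "-") s <- revcomp(s) else s
}

# deterministic local RNG scope: run code under a fixed seed and restore state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
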