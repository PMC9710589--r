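#' Reverse complement of DNA sequences
#'
#' Strict Watson-Crick reverse complement over the ACGT alphabet. Ambiguity
#' codes are rejected: k-mer space in this package is strictly 2-bit
#' encodable, and reads containing other characters are split upstream
#' rather than complemented.
#'
#' @param seq Character vector of DNA sequences over ACGT.
#' @return Character vector of the same length with each sequence reverse
#'   complemented.
#' @examples
#' reverse_complement(c("ACGT", "GATTA"))
#' @export
reverse_complement <- function(seq) {
  cpp_revcomp(as.character(seq))
}

#' Canonical representation of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement (under A < C < G < T). Counting canonical
#' k-mers makes all downstream statistics independent of read strand.
#'
#' @param seq Character vector of DNA sequences over ACGT.
#' @return Character vector of canonical sequences. Idempotent and
#'   strand-symmetric: `canonical_kmer(x) == canonical_kmer(reverse_complement(x))`.
#' @examples
#' canonical_kmer("TTTT")   # "AAAA"
#' canonical_kmer("GATTA")  # already canonical
#' @export
canonical_kmer <- function(seq) {
  cpp_canonical(as.character(seq))
}

#' Define a partitioned hash space
#'
#' A Bloom filter of `bits` bits split into `P` sub-filters with exclusive,
#' consecutive hash ranges. Each sub-filter owns `s = ceiling(bits / P)` bits,
#' rounded up to the next multiple of 8 (and at least 8) so sub-filters are
#' byte-aligned and their concatenation is a plain byte concatenation.
#' Partition `p` (0-based) owns exactly the index range `[p*s, p*s + s - 1]`.
#'
#' A single hash function is used throughout; a membership test is one bit
#' probe. The 64-bit `seed` selects the hash function and travels with every
#' output file header so artifacts from different runs are never mixed.
#'
#' @param bits Requested total filter size in bits (>= 8).
#' @param P Number of partitions (>= 1).
#' @param seed Hash seed (non-negative integer-valued scalar).
#' @return An object of class `hash_space` with fields `bits`, `P`, `s`
#'   (per-partition size in bits) and `seed`.
#' @examples
#' hs <- hash_space(bits = 2^20, P = 16, seed = 0)
#' hs$s  # 65536
#' @export
hash_space <- function(bits, P, seed = 0) {
  stopifnot(length(bits) == 1, length(P) == 1, length(seed) == 1)
  if (bits < 8) stop("bits must be >= 8")
  if (P < 1) stop("P must be >= 1")
  if (seed < 0 || seed != floor(seed)) stop("seed must be a non-negative integer")
  s <- ceiling(bits / P)
  s <- 8 * ceiling(s / 8)
  s <- max(s, 8)
  if (P * s >= 2^53) stop("total hash space too large for exact indexing")
  structure(
    list(bits = as.numeric(bits), P = as.integer(P), s = as.numeric(s),
         seed = as.numeric(seed)),
    class = "hash_space"
  )
}

#' @export
print.hash_space <- function(x, ...) {
  cat(sprintf("<hash_space> bits=%s P=%d s=%s (total %s bits) seed=%s\n",
              format(x$bits, big.mark = ","), x$P, format(x$s, big.mark = ","),
              format(x$P * x$s, big.mark = ","), format(x$seed)))
  invisible(x)
}

#' Hash a k-mer into its partition's exclusive range
#'
#' Computes `p*s + (H(kmer, seed) mod s)` where `H` is a 64-bit avalanche
#' hash (the MurmurHash3 finalizer) of the 2-bit packed canonical k-mer.
#' Input k-mers are canonicalized first, so a k-mer and its reverse
#' complement always receive the same index. The result always lies in
#' partition `p`'s range `[p*s, p*s + s - 1]`.
#'
#' @param kmer Character vector of k-mers (length <= 32 bases each).
#' @param p 0-based partition id, `0 <= p < hs$P`.
#' @param hs A [hash_space()].
#' @return Numeric vector of hash indices (exact integers below 2^53).
#' @export
hash_into_partition <- function(kmer, p, hs) {
  stopifnot(inherits(hs, "hash_space"), length(p) == 1)
  if (p < 0 || p >= hs$P) stop("partition id p out of range [0, P-1]")
  cpp_hash_indices(as.character(kmer), as.integer(p), hs$s, hs$seed)
}
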