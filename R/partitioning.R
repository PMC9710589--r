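#' Minimizer of a k-mer
#'
#' The minimizer is the lexicographically smallest m-mer (A < C < G < T)
#' over the union of the m-mers of the k-mer and of its reverse complement.
#' Computing it over both strands makes the minimizer -- and therefore the
#' partition assignment of every k-mer occurrence -- strand-symmetric.
#'
#' @param kmer Character vector of k-mers over ACGT.
#' @param m Minimizer length, `1 <= m < k`.
#' @return Character vector of minimizers (length-m strings).
#' @examples
#' minimizer_of("ACGTACG", 3)  # "ACG"
#' @export
minimizer_of <- function(kmer, m) {
  kmer <- as.character(kmer)
  if (m < 1) stop("m must be >= 1")
  if (any(nchar(kmer) <= m)) stop("m must be < k")
  cpp_minimizers(kmer, as.integer(m))
}

#' Decompose reads into super-k-mers
#'
#' A super-k-mer is a maximal stretch of a read whose consecutive k-mers all
#' share the same minimizer; spilling super-k-mers instead of k-mers avoids
#' writing each overlapping k-mer separately. Reads are first split at any
#' non-ACGT character (k-mers never span such characters); fragments shorter
#' than k yield nothing. Concatenating the k-mer sets of the returned
#' super-k-mers reproduces exactly the k-mer multiset of the read's ACGT
#' fragments.
#'
#' @param reads Character vector of reads (may contain non-ACGT characters).
#' @param k K-mer length.
#' @param m Minimizer length, `m < k`.
#' @return A tibble with columns `read` (1-based index into `reads`),
#'   `sequence` (the super-k-mer, length >= k) and `minimizer`.
#' @export
super_kmers_of <- function(reads, k, m) {
  if (m >= k) stop("m must be < k")
  df <- cpp_super_kmers(as.character(reads), as.integer(k), as.integer(m))
  out <- tibble::as_tibble(df)
  attr(out, "k") <- as.integer(k)
  attr(out, "m") <- as.integer(m)
  out
}

#' Build a balanced minimizer-to-partition map
#'
#' Estimates the k-mer mass carried by each minimizer from a subsample of
#' reads, then assigns minimizers to partitions greedily: largest estimated
#' mass first, each into the currently lightest partition (ties: lowest
#' partition index). Minimizers never seen in the subsample are assigned
#' round-robin by their numeric 2-bit rank so the map is total over all 4^m
#' possible minimizers. The aim is that all partitions carry a roughly equal
#' total number of k-mers, so downstream per-partition work is balanced.
#'
#' @param samples Read sources: a character vector / list of FASTA/FASTQ file
#'   paths (gzip allowed), or a list of character vectors of reads.
#' @param P Number of partitions (>= 1).
#' @param k K-mer length.
#' @param m Minimizer length (`m < k`, `m <= 12`).
#' @param subsample Maximum number of reads taken from the head of each
#'   sample for mass estimation (default 10^4). Deterministic.
#' @param seed Recorded in the map for provenance (the construction itself is
#'   deterministic).
#' @return An object of class `partition_map`: list with `m`, `P`,
#'   `assignment` (integer vector of length 4^m, 0-based partition ids indexed
#'   by 2-bit minimizer code + 1), `estimated_mass`, `subsample`, `seed`, and
#'   `balance` (max estimated partition load / mean load on the subsample).
#' @export
build_partition_map <- function(samples, P, k, m, subsample = 1e4, seed = 0) {
  if (P < 1) stop("P must be >= 1")
  if (m >= k) stop("m must be < k")
  if (m > 12) stop("m must be <= 12 (assignment table holds all 4^m minimizers)")
  if (!is.list(samples)) samples <- as.list(samples)
  if (length(samples) == 0) stop("no samples given")

  n_mini <- 4^m
  mass <- numeric(n_mini)
  total_reads <- 0L
  for (src in samples) {
    reads <- read_sequences(src, n_max = subsample)
    total_reads <- total_reads + length(reads)
    if (length(reads) == 0) next
    sk <- cpp_super_kmers(reads, as.integer(k), as.integer(m))
    if (nrow(sk) == 0) next
    code <- cpp_encode2bit(sk$minimizer)
    kmass <- nchar(sk$sequence) - k + 1
    agg <- rowsum(kmass, group = code)
    mass[as.numeric(rownames(agg)) + 1] <- mass[as.numeric(rownames(agg)) + 1] + agg[, 1]
  }

  if (sum(mass) == 0) {
    warning("empty subsample: falling back to uniform round-robin partition map")
  }
  g <- greedy_assign(mass, P)
  assignment <- g$assignment
  loads <- g$loads

  structure(
    list(m = as.integer(m), P = as.integer(P),
         assignment = as.integer(assignment),
         estimated_mass = mass,
         subsample = as.numeric(subsample),
         n_subsampled_reads = total_reads,
         seed = as.numeric(seed),
         balance = if (mean(loads) > 0) max(loads) / mean(loads) else 1),
    class = "partition_map"
  )
}

# Greedy largest-first bin packing of minimizer masses into P partitions.
# Minimizers with positive estimated mass go largest-first into the currently
# lightest partition (ties: lowest partition index, lower numeric rank first
# among equal masses); zero-mass minimizers are spread round-robin by numeric
# rank. Returns the full 0-based assignment and the per-partition loads.
greedy_assign <- function(mass, P) {
  assignment <- integer(length(mass))
  loads <- numeric(P)
  nz <- which(mass > 0)
  if (length(nz) > 0) {
    nz <- nz[order(-mass[nz], nz)]
    for (i in nz) {
      p <- which.min(loads)  # ties: lowest index
      assignment[i] <- p - 1L
      loads[p] <- loads[p] + mass[i]
    }
  }
  z <- which(mass == 0)
  if (length(z) > 0) assignment[z] <- as.integer((seq_along(z) - 1) %% P)
  list(assignment = assignment, loads = loads)
}

#' @export
print.partition_map <- function(x, ...) {
  cat(sprintf("<partition_map> m=%d P=%d minimizers=%d balance=%.3f seed=%s\n",
              x$m, x$P, length(x$assignment), x$balance, format(x$seed)))
  invisible(x)
}

#' Partition of a minimizer
#'
#' Total, deterministic lookup of the partition owning a minimizer. Because
#' minimizers are computed over both strands, every occurrence of a given
#' k-mer (on either strand) resolves to the same partition.
#'
#' @param mini Character vector of minimizers of length `pm$m`.
#' @param pm A [build_partition_map()] result.
#' @return Integer vector of 0-based partition ids in `[0, P-1]`.
#' @export
partition_of <- function(mini, pm) {
  stopifnot(inherits(pm, "partition_map"))
  mini <- as.character(mini)
  if (any(nchar(mini) != pm$m)) stop("minimizer length does not match pm$m")
  pm$assignment[cpp_encode2bit(mini) + 1]
}

#' Digest of a partition map
#'
#' FNV-1a fingerprint of the assignment table plus (m, P); stored in Bloom
#' filter headers so that a filter is never queried with the wrong map.
#'
#' @param pm A `partition_map`.
#' @return A numeric scalar (exact integer below 2^53).
#' @export
partition_map_digest <- function(pm) {
  stopifnot(inherits(pm, "partition_map"))
  cpp_digest_ints(c(pm$m, pm$P, pm$assignment))
}

#' Write / read a partition map sidecar file
#'
#' Binary format: magic "KFPM", version, m, P, seed, subsample size, then the
#' run-length encoded 4^m assignment. Written once per run and read back by
#' the counting and query stages.
#'
#' @param pm A `partition_map`.
#' @param path Output file path.
#' @return `write_partition_map` returns `path` invisibly;
#'   `read_partition_map` returns a `partition_map` (without the estimated
#'   mass vector, which is not needed downstream).
#' @export
write_partition_map <- function(pm, path) {
  stopifnot(inherits(pm, "partition_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KFPM"), con)
  writeBin(c(1L, pm$m, pm$P), con, size = 4, endian = "little")
  writeBin(c(pm$seed, pm$subsample, pm$balance), con, endian = "little")
  r <- rle(pm$assignment)
  writeBin(length(r$lengths), con, size = 4, endian = "little")
  writeBin(as.integer(r$lengths), con, size = 4, endian = "little")
  writeBin(as.integer(r$values), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_partition_map
#' @export
read_partition_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "KFPM") stop("not a partition map file: ", path)
  hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
  dbl <- readBin(con, "double", 3, endian = "little")
  nrle <- readBin(con, "integer", 1, size = 4, endian = "little")
  lens <- readBin(con, "integer", nrle, size = 4, endian = "little")
  vals <- readBin(con, "integer", nrle, size = 4, endian = "little")
  structure(
    list(m = hdr[2], P = hdr[3],
         assignment = inverse.rle(list(lengths = lens, values = vals)),
         estimated_mass = NULL, subsample = dbl[2], n_subsampled_reads = NA,
         seed = dbl[1], balance = dbl[3]),
    class = "partition_map"
  )
}
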