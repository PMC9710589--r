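#' Partitioned Bloom filter for one sample
#'
#' The concatenation of P sub-filters of s bits each, with exclusive
#' consecutive hash spaces: bit `p*s + o` of the filter is bit `o` of
#' sub-filter p. One hash function is used, so membership is a single bit
#' probe -- but the probe index depends on the k-mer's minimizer, which
#' selects the partition and hence the hash range. The filter therefore
#' carries the partition map (and its digest) alongside the payload.
#'
#' @param payload Raw vector of `P*s/8` bytes, LSB-first within bytes.
#' @param sample_id Sample identifier.
#' @param hs The run's [hash_space()].
#' @param k,m K-mer and minimizer lengths.
#' @param pm The run's [build_partition_map()] (or `NULL` if attached later).
#' @return An object of class `partitioned_bloom_filter`.
#' @export
partitioned_bloom_filter <- function(payload, sample_id, hs, k, m, pm = NULL) {
  stopifnot(inherits(hs, "hash_space"))
  if (length(payload) != hs$P * hs$s / 8) {
    stop("payload length does not match P*s/8 bytes")
  }
  structure(
    list(sample = sample_id, payload = payload, hs = hs,
         k = as.integer(k), m = as.integer(m), pm = pm,
         pm_digest = if (!is.null(pm)) partition_map_digest(pm) else NA_real_),
    class = "partitioned_bloom_filter"
  )
}

#' @export
print.partitioned_bloom_filter <- function(x, ...) {
  occ <- cpp_popcount(x$payload) / (x$hs$P * x$hs$s)
  cat(sprintf("<partitioned_bloom_filter> sample=%s k=%d m=%d P=%d s=%s occupancy=%.4f\n",
              x$sample, x$k, x$m, x$hs$P, format(x$hs$s), occ))
  invisible(x)
}

#' Assemble per-sample Bloom filters from transposed sub-matrices
#'
#' After transposition each partition yields a sample-major bit matrix of C
#' rows by s columns. The Bloom filter of sample i is the horizontal
#' concatenation, over partitions p = 0..P-1, of row i of matrix p. Because s
#' is a multiple of 8 and rows are byte-aligned, the concatenation is a plain
#' byte concatenation and probing bit `p*s + o` of the filter equals probing
#' matrix p, row i, bit o.
#'
#' @param submatrices List of P sample-major [bit_matrix()] objects, in
#'   partition order, each of dimension C x s.
#' @param sample_ids Character vector of C sample ids (column order of the
#'   run manifest).
#' @param hs,k,m,pm Run parameters; see [partitioned_bloom_filter()].
#' @return List of C `partitioned_bloom_filter` objects.
#' @export
assemble_filters <- function(submatrices, sample_ids, hs, k, m, pm = NULL) {
  stopifnot(length(submatrices) == hs$P)
  C <- length(sample_ids)
  stride <- hs$s / 8
  for (bm in submatrices) {
    stopifnot(inherits(bm, "bit_matrix"))
    if (bm$orientation != "sample-major") stop("sub-matrices must be sample-major (transposed)")
    if (bm$rows != C || bm$cols != hs$s) stop("sub-matrix shape mismatch")
  }
  lapply(seq_len(C), function(i) {
    rows <- lapply(submatrices, function(bm) {
      bm$payload[((i - 1) * stride + 1):(i * stride)]
    })
    partitioned_bloom_filter(do.call(c, rows), sample_ids[i], hs, k, m, pm)
  })
}

#' Direct partitioned-Bloom-filter fast path (rescue disabled)
#'
#' When no cross-sample rescue is needed, the bit vector of a partition can
#' be emitted straight from that sample's hash counts, skipping the merge and
#' transpose stages entirely: bit `key - p*s` is set for every counted key.
#' Bit-identical to binarizing and transposing the single-sample pipeline.
#'
#' @param pc A hash-mode `partition_counts` (already hard-min filtered).
#' @return Raw vector of `s/8` bytes.
#' @export
direct_pbf <- function(pc) {
  stopifnot(inherits(pc, "partition_counts"))
  if (pc$mode != "hash") stop("direct_pbf requires hash-mode counts")
  hs <- pc$hs
  offsets <- pc$entries$key - pc$partition * hs$s
  if (length(offsets) && (min(offsets) < 0 || max(offsets) >= hs$s)) {
    stop("hash key outside partition range")
  }
  cpp_set_bits(raw(hs$s / 8), offsets)
}

#' Query a single k-mer against a partitioned Bloom filter
#'
#' The k-mer is canonicalized; its minimizer selects the partition (and
#' hence the hash function); the partition hash gives the single bit to
#' probe. K-mers inserted during construction always query `TRUE` (no false
#' negatives); never-inserted k-mers query `TRUE` with probability roughly
#' equal to the occupancy of the probed partition (false positives).
#'
#' @param bf A `partitioned_bloom_filter` (with its partition map attached).
#' @param kmer Character vector of k-mers of length `bf$k`. K-mers containing
#'   non-ACGT characters return `FALSE` (they cannot have been indexed).
#' @return Logical vector.
#' @export
query_kmer <- function(bf, kmer) {
  stopifnot(inherits(bf, "partitioned_bloom_filter"))
  if (is.null(bf$pm)) stop("filter has no partition map attached")
  kmer <- as.character(kmer)
  if (any(nchar(kmer) != bf$k)) stop("query k-mer length differs from filter k")
  valid <- !grepl("[^ACGT]", kmer)
  out <- logical(length(kmer))
  if (any(valid)) {
    out[valid] <- cpp_get_bits(bf$payload, query_indices(kmer[valid], bf$pm, bf$hs))
  }
  out
}

# hash index of each k-mer under the run's partition scheme
query_indices <- function(kmers, pm, hs) {
  mini <- cpp_minimizers(kmers, pm$m)
  p <- partition_of(mini, pm)
  idx <- numeric(length(kmers))
  for (pp in unique(p)) {
    sel <- p == pp
    idx[sel] <- cpp_hash_indices(kmers[sel], as.integer(pp), hs$s, hs$seed)
  }
  idx
}

#' Query a sequence against a collection of filters
#'
#' Reports, for each sample's filter, the fraction of the sequence's valid
#' k-mers found in the filter. K-mers spanning non-ACGT characters are
#' excluded from both numerator and denominator. Thresholding the fraction
#' (e.g. "present if >= 0.7") is left to the caller.
#'
#' @param filters List of `partitioned_bloom_filter` objects (same run).
#' @param seq A single sequence of length >= k.
#' @return A tibble with columns `sample`, `fraction` and `n_kmers` (number
#'   of valid k-mers tested; `fraction` is `NaN` when there are none).
#' @export
query_sequence <- function(filters, seq) {
  stopifnot(length(filters) >= 1, length(seq) == 1)
  k <- filters[[1]]$k
  if (nchar(seq) < k) stop("query sequence shorter than k")
  kmers <- cpp_extract_kmers(toupper(as.character(seq)), k)
  ids <- vapply(filters, function(f) f$sample, "")
  if (length(kmers) == 0) {
    return(tibble::tibble(sample = ids, fraction = NaN, n_kmers = 0L))
  }
  idx <- query_indices(kmers, filters[[1]]$pm, filters[[1]]$hs)
  frac <- vapply(filters, function(f) mean(cpp_get_bits(f$payload, idx)), 1)
  tibble::tibble(sample = ids, fraction = frac, n_kmers = length(kmers))
}

#' Write / read a Bloom filter file
#'
#' Self-describing binary format: magic "KFBF", version, sample id, k, m, P,
#' s, seed and the partition map digest, followed by the `P*s/8` payload
#' bytes (LSB-first within bytes). The digest ties the filter to the
#' partition map required for correct queries; [read_bloom_filter()] verifies
#' it when a map is supplied.
#'
#' @param bf A `partitioned_bloom_filter`.
#' @param path File path.
#' @param pm Optional partition map to attach (and verify) on read.
#' @return `write_bloom_filter` returns `path` invisibly; `read_bloom_filter`
#'   returns a `partitioned_bloom_filter`.
#' @export
write_bloom_filter <- function(bf, path) {
  stopifnot(inherits(bf, "partitioned_bloom_filter"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KFBF"), con)
  writeBin(c(1L, bf$k, bf$m, bf$hs$P), con, size = 4, endian = "little")
  writeBin(c(bf$hs$s, bf$hs$seed, bf$pm_digest), con, endian = "little")
  write_str(con, bf$sample)
  writeBin(bf$payload, con)
  invisible(path)
}

#' @rdname write_bloom_filter
#' @export
read_bloom_filter <- function(path, pm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "KFBF") stop("not a Bloom filter file: ", path)
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  dbl <- readBin(con, "double", 3, endian = "little")
  sample_id <- read_str(con)
  payload <- readBin(con, "raw", hdr[4] * dbl[1] / 8)
  hs <- hash_space(bits = dbl[1] * hdr[4], P = hdr[4], seed = dbl[2])
  hs$s <- dbl[1]
  if (!is.null(pm) && !is.na(dbl[3]) && partition_map_digest(pm) != dbl[3]) {
    stop("partition map digest mismatch: filter was built with a different map")
  }
  bf <- partitioned_bloom_filter(payload, sample_id, hs, hdr[2], hdr[3], pm)
  bf$pm_digest <- dbl[3]
  bf
}
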