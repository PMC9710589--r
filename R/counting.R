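#' Count canonical k-mers or hash values within one partition
#'
#' Takes the super-k-mer stream of one sample restricted to one partition,
#' canonicalizes every constituent k-mer and tallies either the k-mers
#' themselves (`mode = "kmer"`) or their partition hash indices
#' (`mode = "hash"`). Keys are de-duplicated, sorted ascending, and keys
#' whose abundance falls below `hard_min` are discarded at this stage --
#' such k-mers can never be rescued later.
#'
#' A consistency guard verifies that every super-k-mer's minimizer actually
#' maps to partition `p` under `pm`; a violation indicates an upstream bug,
#' not bad data.
#'
#' @param sk Tibble of super-k-mers (columns `sequence`, `minimizer`) as
#'   produced by [super_kmers_of()], already restricted to partition `p`.
#' @param p 0-based partition id.
#' @param pm The run's [build_partition_map()].
#' @param k K-mer length.
#' @param mode `"hash"` or `"kmer"`.
#' @param hs [hash_space()]; required in hash mode.
#' @param hard_min Minimum abundance kept (counts below are dropped).
#' @param sample_id Sample identifier recorded in the result.
#' @return An object of class `partition_counts`: list with `sample`,
#'   `partition`, `mode`, `k`, `hard_min` and `entries`, a tibble of
#'   (`key`, `count`) sorted strictly ascending by key. In hash mode keys are
#'   numeric hash indices within `[p*s, p*s + s - 1]`; in k-mer mode they are
#'   canonical k-mer strings in lexicographic order.
#' @export
count_partition <- function(sk, p, pm, k, mode = c("hash", "kmer"),
                            hs = NULL, hard_min = 1, sample_id = "sample") {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "partition_map"))
  if (nrow(sk) > 0) {
    owner <- partition_of(sk$minimizer, pm)
    if (any(owner != p)) {
      stop(sprintf("super-k-mer assigned to partition %d found in stream for partition %d",
                   owner[which(owner != p)[1]], p))
    }
  }
  if (mode == "hash") {
    stopifnot(inherits(hs, "hash_space"))
    df <- cpp_count_hashes(if (nrow(sk)) sk$sequence else character(0),
                           as.integer(k), as.integer(p), hs$s, hs$seed)
  } else {
    df <- cpp_count_kmers(if (nrow(sk)) sk$sequence else character(0),
                          as.integer(k))
  }
  entries <- tibble::as_tibble(df)
  if (hard_min > 1) entries <- entries[entries$count >= hard_min, ]
  structure(
    list(sample = sample_id, partition = as.integer(p), mode = mode,
         k = as.integer(k), hard_min = as.integer(hard_min),
         hs = hs, entries = entries),
    class = "partition_counts"
  )
}

#' @export
print.partition_counts <- function(x, ...) {
  cat(sprintf("<partition_counts> sample=%s partition=%d mode=%s k=%d hard_min=%d keys=%d\n",
              x$sample, x$partition, x$mode, x$k, x$hard_min, nrow(x$entries)))
  invisible(x)
}

#' Count a whole sample across all partitions
#'
#' Convenience wrapper: decomposes reads into super-k-mers, routes them to
#' partitions via `pm`, and counts each partition. Partitions with no
#' super-k-mers yield empty count sets.
#'
#' @inheritParams count_partition
#' @param reads Character vector of reads (or a file path accepted by
#'   [read_sequences()]).
#' @return List of `partition_counts`, one per partition `0..P-1`.
#' @export
count_sample <- function(reads, pm, k, mode = c("hash", "kmer"), hs = NULL,
                         hard_min = 1, sample_id = "sample") {
  mode <- match.arg(mode)
  reads <- read_sequences(reads)
  sk <- super_kmers_of(reads, k, pm$m)
  part <- if (nrow(sk)) partition_of(sk$minimizer, pm) else integer(0)
  lapply(seq_len(pm$P) - 1L, function(p) {
    count_partition(sk[part == p, , drop = FALSE], p, pm, k, mode = mode,
                    hs = hs, hard_min = hard_min, sample_id = sample_id)
  })
}

#' Abundance histogram of a sample
#'
#' Tallies, over all partitions of one sample, how many distinct keys have
#' each abundance value. Because every canonical k-mer lands in exactly one
#' partition, summing per-partition tables gives the exact per-sample
#' histogram. For a faithful histogram the counts must have been taken with
#' `hard_min = 1`; a warning is emitted otherwise.
#'
#' @param pcs List of `partition_counts` for one sample (all partitions).
#' @return An object of class `abundance_histogram`: tibble with columns
#'   `abundance` and `n_keys`, with attributes `total_distinct` (number of
#'   distinct keys) and `total_mass` (sum of abundance x multiplicity).
#' @export
histogram_of <- function(pcs) {
  if (inherits(pcs, "partition_counts")) pcs <- list(pcs)
  if (any(vapply(pcs, function(x) x$hard_min, 1L) > 1)) {
    warning("histogram computed from counts with hard_min > 1; low-abundance bins are truncated")
  }
  counts <- unlist(lapply(pcs, function(x) x$entries$count))
  if (length(counts) == 0) {
    h <- tibble::tibble(abundance = integer(0), n_keys = integer(0))
  } else {
    t <- table(counts)
    h <- tibble::tibble(abundance = as.integer(names(t)),
                        n_keys = as.integer(t))
  }
  attr(h, "total_distinct") <- sum(h$n_keys)
  attr(h, "total_mass") <- sum(as.numeric(h$abundance) * h$n_keys)
  class(h) <- c("abundance_histogram", class(h))
  h
}

#' Automatic soft-min threshold from an abundance histogram
#'
#' Returns the smallest abundance `t >= 1` such that the number of distinct
#' k-mers occurring exactly `t` times is smaller than `percentage`% of the
#' total number of distinct k-mers in the sample. If no abundance in the
#' histogram's support qualifies, returns the maximum abundance + 1 (an
#' absent abundance has zero k-mers, which always qualifies).
#'
#' "Total number of k-mers" is read as the number of distinct k-mers: the
#' bin it is compared against counts distinct keys, so comparing against
#' total occurrences would mix units.
#'
#' @param h An [histogram_of()] result.
#' @param percentage Threshold percentage in (0, 100]; default 0.1. The
#'   loosest setting, 100, yields 1 whenever no single abundance holds every
#'   distinct k-mer.
#' @return Integer soft-min threshold (>= 1).
#' @examples
#' h <- structure(tibble::tibble(abundance = 1:3, n_keys = c(90L, 5L, 5L)),
#'                total_distinct = 100L, class = c("abundance_histogram", "tbl_df",
#'                                                 "tbl", "data.frame"))
#' auto_soft_min(h, 10)  # 2
#' @export
auto_soft_min <- function(h, percentage = 0.1) {
  if (percentage <= 0 || percentage > 100) stop("percentage must be in (0, 100]")
  total <- attr(h, "total_distinct")
  if (is.null(total)) total <- sum(h$n_keys)
  if (nrow(h) == 0 || total == 0) {
    warning("empty abundance histogram; soft-min defaults to 1")
    return(1L)
  }
  thr <- percentage / 100 * total
  maxa <- max(h$abundance)
  full <- integer(maxa)
  full[h$abundance] <- h$n_keys
  for (t in seq_len(maxa)) {
    if (full[t] < thr) return(as.integer(t))
  }
  as.integer(maxa + 1L)
}

#' Write / read a partition count file
#'
#' Binary format: header (magic "KFPC", version, mode, k, m, P, p, s, seed,
#' sample id, hard_min, number of records) followed by sorted (key, count)
#' records; the key is an 8-byte little-endian integer (hash index in hash
#' mode, 2-bit packed k-mer in k-mer mode) and the count a 4-byte
#' little-endian integer. Use [dump_partition_counts()] for a plain-text
#' debugging view.
#'
#' @param pc A `partition_counts`.
#' @param path Output file.
#' @param m,P Minimizer length and partition count of the run (recorded so
#'   that merging can refuse inconsistent inputs).
#' @return `write_partition_counts` returns `path` invisibly;
#'   `read_partition_counts` returns a `partition_counts`.
#' @export
write_partition_counts <- function(pc, path, m = NA_integer_, P = NA_integer_) {
  stopifnot(inherits(pc, "partition_counts"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KFPC"), con)
  mode_flag <- if (pc$mode == "hash") 0L else 1L
  s <- if (!is.null(pc$hs)) pc$hs$s else 0
  seed <- if (!is.null(pc$hs)) pc$hs$seed else 0
  writeBin(c(1L, mode_flag, pc$k, as.integer(m), as.integer(P), pc$partition,
             pc$hard_min, nrow(pc$entries)), con, size = 4, endian = "little")
  writeBin(c(s, seed), con, endian = "little")
  write_str(con, pc$sample)
  if (nrow(pc$entries) > 0) {
    keys <- if (pc$mode == "hash") pc$entries$key else cpp_encode2bit(pc$entries$key)
    write_u64(con, keys)
    writeBin(as.integer(pc$entries$count), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_partition_counts
#' @export
read_partition_counts <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "KFPC") stop("not a partition counts file: ", path)
  hdr <- readBin(con, "integer", 8, size = 4, endian = "little")
  dbl <- readBin(con, "double", 2, endian = "little")
  sample_id <- read_str(con)
  n <- hdr[8]
  keys <- read_u64(con, n)
  counts <- readBin(con, "integer", n, size = 4, endian = "little")
  mode <- if (hdr[2] == 0L) "hash" else "kmer"
  k <- hdr[3]
  if (mode == "kmer") keys <- cpp_decode2bit(keys, k)
  hs <- NULL
  if (mode == "hash") {
    hs <- hash_space(bits = dbl[1] * hdr[5], P = hdr[5], seed = dbl[2])
    hs$s <- dbl[1]  # preserve the exact per-partition size
  }
  structure(
    list(sample = sample_id, partition = hdr[6], mode = mode, k = k,
         hard_min = hdr[7], hs = hs,
         entries = tibble::tibble(key = keys, count = counts),
         m = hdr[4], P = hdr[5]),
    class = "partition_counts"
  )
}

#' @rdname write_partition_counts
#' @param sep Field separator for the text dump.
#' @export
dump_partition_counts <- function(pc, path, sep = "\t") {
  utils::write.table(pc$entries, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
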