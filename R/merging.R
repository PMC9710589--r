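#' Rescue thresholds
#'
#' Per-sample hard-min and soft-min vectors plus the sample-independent
#' share-min. A k-mer with abundance below hard-min in a sample was already
#' discarded at the counting stage and can never be rescued; abundance at or
#' above soft-min makes the k-mer "solid" in that sample and it is always
#' conserved; an abundance in `[hard_min, soft_min)` is conserved only if the
#' k-mer is solid in at least `share_min` *other* samples. The rescuable band
#' is half-open at the top: a count equal to soft-min is solid by definition,
#' so only counts strictly below soft-min ever need rescuing.
#'
#' @param hard_min Positive integer, scalar or one per sample.
#' @param soft_min Positive integer, scalar or one per sample; must satisfy
#'   `soft_min >= hard_min` elementwise.
#' @param share_min Non-negative integer, shared by all samples.
#' @param C Number of samples (used to recycle scalars).
#' @return An object of class `rescue_params`.
#' @export
rescue_params <- function(hard_min, soft_min, share_min, C) {
  hard_min <- rep_len(as.integer(hard_min), C)
  soft_min <- rep_len(as.integer(soft_min), C)
  if (any(hard_min < 1)) stop("hard_min must be >= 1")
  if (any(soft_min < hard_min)) stop("soft_min must be >= hard_min for every sample")
  if (share_min < 0) stop("share_min must be >= 0")
  structure(list(hard_min = hard_min, soft_min = soft_min,
                 share_min = as.numeric(share_min), C = as.integer(C)),
            class = "rescue_params")
}

#' n-way merge of equivalent partitions across samples
#'
#' Merges the sorted count streams of one partition from C samples into rows
#' of a count matrix: one row per key present in at least one stream, in
#' ascending key order, with 0 for samples where the key is absent. The total
#' count mass is conserved (no counts are created or dropped here; filtering
#' happens in [rescue_counts()]).
#'
#' @param streams List of `partition_counts`, one per sample, all from the
#'   same partition and counted in the same mode (and, in hash mode, the same
#'   hash space).
#' @return An object of class `merged_partition`: list with `partition`,
#'   `mode`, `k`, `samples` (ids in column order), `keys` (ascending) and
#'   `counts` (integer matrix, one column per sample).
#' @export
nway_merge <- function(streams) {
  stopifnot(length(streams) >= 1)
  lapply(streams, function(x) stopifnot(inherits(x, "partition_counts")))
  p <- unique(vapply(streams, function(x) x$partition, 1L))
  mode <- unique(vapply(streams, function(x) x$mode, ""))
  k <- unique(vapply(streams, function(x) x$k, 1L))
  if (length(p) != 1) stop("streams come from different partitions: ",
                           paste(p, collapse = ", "))
  if (length(mode) != 1) stop("streams mix counting modes")
  if (length(k) != 1) stop("streams mix k-mer sizes")
  if (mode == "hash") {
    seeds <- unique(vapply(streams, function(x) x$hs$seed, 1))
    if (length(seeds) != 1) {
      stop("refusing to merge partitions counted with different hash seeds: ",
           paste(format(seeds), collapse = " vs "))
    }
  }
  for (st in streams) {
    kk <- st$entries$key
    srt <- if (is.character(kk)) !is.unsorted(cpp_encode2bit(kk), strictly = TRUE)
           else !is.unsorted(kk, strictly = TRUE)
    if (!srt) stop("merge error: input stream for sample '", st$sample,
                   "' is not strictly sorted")
  }
  all_keys <- unlist(lapply(streams, function(x) x$entries$key))
  keys <- if (is.character(all_keys)) {
    u <- unique(all_keys)
    u[order(cpp_encode2bit(u))]
  } else {
    sort(unique(all_keys))
  }
  counts <- matrix(0L, nrow = length(keys), ncol = length(streams))
  for (i in seq_along(streams)) {
    idx <- match(streams[[i]]$entries$key, keys)
    counts[idx, i] <- streams[[i]]$entries$count
  }
  structure(
    list(partition = p, mode = mode, k = k,
         samples = vapply(streams, function(x) x$sample, ""),
         hs = streams[[1]]$hs, keys = keys, counts = counts),
    class = "merged_partition"
  )
}

#' @export
print.merged_partition <- function(x, ...) {
  cat(sprintf("<merged_partition> partition=%d mode=%s samples=%d keys=%d\n",
              x$partition, x$mode, ncol(x$counts), length(x$keys)))
  invisible(x)
}

#' Apply the rare-but-shared rescue rule to a count matrix
#'
#' Row-independent, deterministic filter. For each row (one k-mer or hash
#' value) and each sample i: a count at or above `soft_min[i]` is solid and
#' kept; a count in `[hard_min[i], soft_min[i])` is kept iff the number of
#' *other* samples j in which the row is solid (`counts[j] >= soft_min[j]`)
#' is at least `share_min`; anything else is set to 0. With `share_min = 0`
#' every count at or above hard-min survives; with `soft_min = hard_min`
#' nothing is sub-soft and the filter is plain thresholding.
#'
#' @param counts Integer matrix (rows x C samples), entries 0 or
#'   `>= hard_min` (sub-hard-min counts were dropped at the counting stage).
#' @param rp A [rescue_params()] with `rp$C == ncol(counts)`.
#' @return Filtered integer matrix of the same shape.
#' @export
rescue_counts <- function(counts, rp) {
  stopifnot(inherits(rp, "rescue_params"))
  if (ncol(counts) != rp$C) stop("counts has ", ncol(counts),
                                 " columns but rescue_params expects ", rp$C)
  if (nrow(counts) == 0) return(counts)
  solid <- sweep(counts, 2, rp$soft_min, ">=")
  hard_ok <- sweep(counts, 2, rp$hard_min, ">=")
  n_solid <- rowSums(solid)
  # for a sub-soft cell, n_solid already excludes the cell's own sample
  keep <- solid | (hard_ok & (n_solid >= rp$share_min))
  out <- counts
  out[!keep] <- 0L
  out
}

#' @rdname rescue_counts
#' @param counts_row Integer vector of C counts (a single matrix row).
#' @return `rescue_row` returns the filtered vector of length C.
#' @export
rescue_row <- function(counts_row, rp) {
  if (length(counts_row) != rp$C) stop("counts length differs from rp$C")
  drop(rescue_counts(matrix(as.integer(counts_row), nrow = 1), rp))
}

#' Binarize counts to presence/absence
#'
#' @param counts Integer vector or matrix (after rescue, or raw if rescue is
#'   disabled).
#' @return Logical vector/matrix: `TRUE` where the count is positive.
#' @export
binarize <- function(counts) {
  counts > 0
}

#' Build the dense hash-major presence/absence sub-matrix of one partition
#'
#' Returns an s-row [bit_matrix()] whose row r (1-based) corresponds to hash
#' index `p*s + r - 1`. Rows for hash values absent from every sample are
#' all-zero: all s possible hashes of the partition are represented
#' implicitly by row position, and no hash values are stored. Present rows
#' hold `binarize(rescue_counts(...))` of the merged counts.
#'
#' @param merged A hash-mode [nway_merge()] result.
#' @param rp A [rescue_params()], or `NULL` to skip rescue.
#' @return A `bit_matrix` of dimension s x C, orientation `"hash-major"`.
#' @export
build_submatrix <- function(merged, rp = NULL) {
  stopifnot(inherits(merged, "merged_partition"))
  if (merged$mode != "hash") stop("build_submatrix requires hash-mode counts")
  hs <- merged$hs
  offsets <- merged$keys - merged$partition * hs$s
  if (length(offsets) && (min(offsets) < 0 || max(offsets) >= hs$s)) {
    stop("hash key outside partition range")
  }
  counts <- if (is.null(rp)) merged$counts else rescue_counts(merged$counts, rp)
  payload <- cpp_build_submatrix(offsets, binarize(counts) & TRUE, hs$s)
  bit_matrix(payload, hs$s, ncol(counts), "hash-major")
}

#' Emit a joint k-mer count matrix
#'
#' Combines k-mer-mode merged partitions (after optional rescue) into a
#' single table of canonical k-mers with one count column per sample. Rows
#' whose counts are all zero after rescue are omitted; rows are ordered by
#' partition, then key. When `file` is given the matrix is written as TSV
#' with a `#`-prefixed header line of sample ids.
#'
#' @param merged_list List of k-mer-mode [nway_merge()] results (one per
#'   partition).
#' @param rp A [rescue_params()] or `NULL`.
#' @param file Optional output TSV path.
#' @return A tibble with column `kmer` followed by one integer column per
#'   sample.
#' @export
emit_count_matrix <- function(merged_list, rp = NULL, file = NULL) {
  stopifnot(length(merged_list) >= 1)
  modes <- unique(vapply(merged_list, function(x) x$mode, ""))
  if (!identical(modes, "kmer")) stop("emit_count_matrix requires k-mer-mode counts")
  samples <- merged_list[[1]]$samples
  ord <- order(vapply(merged_list, function(x) x$partition, 1L))
  pieces <- lapply(merged_list[ord], function(mg) {
    if (!identical(mg$samples, samples)) stop("merged partitions disagree on sample order")
    counts <- if (is.null(rp)) mg$counts else rescue_counts(mg$counts, rp)
    keep <- rowSums(counts) > 0
    list(kmer = mg$keys[keep], counts = counts[keep, , drop = FALSE])
  })
  out <- tibble::tibble(kmer = unlist(lapply(pieces, `[[`, "kmer")))
  cm <- do.call(rbind, lapply(pieces, `[[`, "counts"))
  if (is.null(cm)) cm <- matrix(0L, 0, length(samples))
  for (i in seq_along(samples)) out[[samples[i]]] <- cm[, i]
  if (!is.null(file)) {
    header <- paste0("#kmer\t", paste(samples, collapse = "\t"))
    writeLines(header, file)
    if (nrow(out) > 0) {
      utils::write.table(out, file, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, append = TRUE)
    }
  }
  out
}

#' Read a TSV count matrix written by [emit_count_matrix()]
#' @param file Path to the TSV matrix.
#' @return A tibble with column `kmer` plus one column per sample.
#' @export
read_count_matrix <- function(file) {
  header <- sub("^#", "", readLines(file, n = 1))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  lines <- readLines(file)
  if (length(lines) <= 1) {  # header-only: no rows survived
    out <- tibble::tibble(kmer = character(0))
    for (s in cols[-1]) out[[s]] <- integer(0)
    return(out)
  }
  df <- utils::read.table(file, sep = "\t", skip = 1,
                          col.names = cols,
                          colClasses = c("character", rep("integer", length(cols) - 1)))
  tibble::as_tibble(df)
}
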