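#' Packed bit matrix
#'
#' A rectangular bit array stored row-major with LSB-first bit order within
#' each byte (bit j of a row lives in byte `j %/% 8`, bit position `j %% 8`).
#' Rows are indexed by hash (orientation `"hash-major"`, the color-aggregative
#' layout: one row per hash value, one bit column per sample) or by sample
#' (`"sample-major"`, the k-mer-aggregative layout produced by transposition).
#'
#' @param payload Raw vector of length `rows * ceiling(cols / 8)`.
#' @param rows,cols Dimensions in bits.
#' @param orientation `"hash-major"` or `"sample-major"`.
#' @return An object of class `bit_matrix`.
#' @export
bit_matrix <- function(payload, rows, cols,
                       orientation = c("hash-major", "sample-major")) {
  orientation <- match.arg(orientation)
  stride <- ceiling(cols / 8)
  if (length(payload) != rows * stride) {
    stop("payload length does not match rows * ceiling(cols/8)")
  }
  structure(list(rows = as.numeric(rows), cols = as.numeric(cols),
                 payload = payload, orientation = orientation),
            class = "bit_matrix")
}

#' @export
print.bit_matrix <- function(x, ...) {
  cat(sprintf("<bit_matrix> %s x %s (%s), %d set bits\n",
              format(x$rows), format(x$cols), x$orientation,
              cpp_popcount(x$payload)))
  invisible(x)
}

#' Read one bit of a bit matrix
#'
#' @param bm A [bit_matrix()].
#' @param i,j 1-based row and column indices (vectorized, recycled).
#' @return Logical vector.
#' @export
bm_get <- function(bm, i, j) {
  stopifnot(inherits(bm, "bit_matrix"))
  n <- max(length(i), length(j))
  i <- rep_len(as.numeric(i), n); j <- rep_len(as.numeric(j), n)
  if (any(i < 1 | i > bm$rows | j < 1 | j > bm$cols)) stop("index out of range")
  stride <- ceiling(bm$cols / 8)
  cpp_get_bits(bm$payload, (i - 1) * stride * 8 + (j - 1))
}

#' Dense logical view of a bit matrix (small matrices only)
#' @param bm A `bit_matrix`.
#' @return Logical matrix of dimension rows x cols.
#' @export
bm_as_matrix <- function(bm) {
  cpp_unpack_rows(bm$payload, bm$rows, bm$cols)
}

#' Build a bit matrix from a logical matrix
#' @param x Logical matrix.
#' @inheritParams bit_matrix
#' @return A `bit_matrix`.
#' @export
bm_from_matrix <- function(x, orientation = "hash-major") {
  bit_matrix(cpp_pack_rows(x), nrow(x), ncol(x), orientation)
}

#' Transpose a packed bit matrix
#'
#' Output bit (j, i) equals input bit (i, j); the orientation tag is flipped.
#' This is the step that converts a color-aggregative sub-matrix (hash rows,
#' sample columns) into the sample-major layout from which per-sample Bloom
#' filters are concatenated.
#'
#' @param bm A [bit_matrix()].
#' @return The transposed `bit_matrix` (involution: transposing twice gives
#'   back the original).
#' @export
transpose_bits <- function(bm) {
  stopifnot(inherits(bm, "bit_matrix"))
  flipped <- if (bm$orientation == "hash-major") "sample-major" else "hash-major"
  bit_matrix(cpp_transpose_bits(bm$payload, bm$rows, bm$cols),
             bm$cols, bm$rows, flipped)
}

#' Write / read a packed bit matrix file
#'
#' Binary format: magic "KFBM", version, partition id, s, number of samples
#' C, rows, cols, orientation flag, seed, k, m, P, then the row-major
#' payload (LSB-first within each byte).
#'
#' @param bm A `bit_matrix`.
#' @param path File path.
#' @param meta Named list with fields `p`, `s`, `C`, `seed`, `k`, `m`, `P`
#'   recorded in the header.
#' @return `write_bit_matrix` returns `path` invisibly; `read_bit_matrix`
#'   returns the `bit_matrix` with a `meta` attribute.
#' @export
write_bit_matrix <- function(bm, path, meta) {
  stopifnot(inherits(bm, "bit_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KFBM"), con)
  orient <- if (bm$orientation == "hash-major") 0L else 1L
  writeBin(c(1L, as.integer(meta$p), as.integer(meta$C), orient,
             as.integer(meta$k), as.integer(meta$m), as.integer(meta$P)),
           con, size = 4, endian = "little")
  writeBin(c(meta$s, meta$seed, bm$rows, bm$cols), con, endian = "little")
  writeBin(bm$payload, con)
  invisible(path)
}

#' @rdname write_bit_matrix
#' @export
read_bit_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "KFBM") stop("not a bit matrix file: ", path)
  hdr <- readBin(con, "integer", 7, size = 4, endian = "little")
  dbl <- readBin(con, "double", 4, endian = "little")
  rows <- dbl[3]; cols <- dbl[4]
  payload <- readBin(con, "raw", rows * ceiling(cols / 8))
  bm <- bit_matrix(payload, rows, cols,
                   if (hdr[4] == 0L) "hash-major" else "sample-major")
  attr(bm, "meta") <- list(p = hdr[2], C = hdr[3], k = hdr[5], m = hdr[6],
                           P = hdr[7], s = dbl[1], seed = dbl[2])
  bm
}
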