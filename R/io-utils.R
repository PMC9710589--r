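# Internal I/O helpers: sequence input via Biostrings, and primitives for the
# package's binary sidecar formats (little-endian u64 stored as exact doubles,
# length-prefixed strings).

#' Read sequences from a FASTA/FASTQ file or pass reads through
#'
#' Accepts a single file path (FASTA or FASTQ, optionally gzipped; format
#' sniffed from the first record) or a character vector that is already a set
#' of reads. Multiple paths may be given separated by `;` and are
#' concatenated as one sample.
#'
#' @param src File path(s) or a character vector of reads.
#' @param n_max Maximum number of reads to return (head of the file);
#'   `Inf` for all.
#' @return Character vector of upper-case reads.
#' @keywords internal
#' @export
read_sequences <- function(src, n_max = Inf) {
  if (length(src) == 1 && is.character(src) && grepl(";", src, fixed = TRUE)) {
    src <- strsplit(src, ";", fixed = TRUE)[[1]]
  }
  looks_like_file <- is.character(src) && length(src) >= 1 &&
    all(nchar(src) < 500) && all(file.exists(src))
  if (!looks_like_file) {
    reads <- toupper(as.character(src))
    if (is.finite(n_max)) reads <- utils::head(reads, n_max)
    return(reads)
  }
  out <- character(0)
  for (f in src) {
    fmt <- sniff_format(f)
    n_left <- if (is.finite(n_max)) n_max - length(out) else -1L
    if (n_left == 0) break
    x <- Biostrings::readDNAStringSet(f, format = fmt,
                                      nrec = if (is.finite(n_max)) n_left else -1L)
    out <- c(out, toupper(as.character(x)))
  }
  unname(out)
}

sniff_format <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0) stop("empty sequence file: ", path)
  if (startsWith(first, "@")) "fastq" else "fasta"
}

# little-endian unsigned 64-bit integers carried as exact doubles (< 2^53)
write_u64 <- function(con, x) {
  lo <- x %% 4294967296
  hi <- x %/% 4294967296
  to_i32 <- function(v) as.integer(ifelse(v >= 2147483648, v - 4294967296, v))
  v <- as.vector(rbind(to_i32(lo), to_i32(hi)))
  writeBin(v, con, size = 4, endian = "little")
}

read_u64 <- function(con, n) {
  v <- readBin(con, "integer", n * 2, size = 4, endian = "little")
  v <- ifelse(v < 0, v + 4294967296, v)
  if (n == 0) return(numeric(0))
  lo <- v[seq(1, by = 2, length.out = n)]
  hi <- v[seq(2, by = 2, length.out = n)]
  hi * 4294967296 + lo
}

write_str <- function(con, s) {
  r <- charToRaw(s)
  writeBin(length(r), con, size = 4, endian = "little")
  writeBin(r, con)
}

read_str <- function(con) {
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rawToChar(readBin(con, "raw", n))
}
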