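# Independent reference implementations used as oracles. They deliberately
# avoid the package's C++ kernels: reverse complement goes through
# Biostrings, k-mer extraction through substring(), and ordering through a
# digit remapping (A->0 ... T->3) so string comparisons are locale-proof.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

okey <- function(s) chartr("ACGT", "0123", s)

oracle_canonical <- function(s) {
  r <- oracle_revcomp(s)
  ifelse(okey(s) <= okey(r), s, r)
}

# all k-mers of the ACGT fragments of each read (forward spelling)
oracle_kmers <- function(reads, k) {
  out <- character(0)
  for (read in reads) {
    for (frag in strsplit(read, "[^ACGT]+")[[1]]) {
      n <- nchar(frag)
      if (!is.na(n) && n >= k) {
        out <- c(out, substring(frag, 1:(n - k + 1), k:n))
      }
    }
  }
  out
}

# flat single-table sliding-window canonical k-mer counter
oracle_count <- function(reads, k) {
  km <- oracle_kmers(reads, k)
  if (length(km) == 0) {
    return(tibble::tibble(key = character(0), count = integer(0)))
  }
  tab <- table(oracle_canonical(km))
  keys <- names(tab)
  ord <- order(okey(keys))
  tibble::tibble(key = keys[ord], count = as.integer(tab)[ord])
}

oracle_minimizer <- function(kmer, m) {
  n <- nchar(kmer)
  mm <- c(substring(kmer, 1:(n - m + 1), m:n),
          substring(oracle_revcomp(kmer), 1:(n - m + 1), m:n))
  mm[order(okey(mm))][1]
}

# group maximal runs of consecutive k-mers sharing a minimizer
oracle_superkmers <- function(read, k, m) {
  out <- list()
  for (frag in strsplit(read, "[^ACGT]+")[[1]]) {
    n <- nchar(frag)
    if (is.na(n) || n < k) next
    kms <- substring(frag, 1:(n - k + 1), k:n)
    mins <- vapply(kms, oracle_minimizer, "", m = m, USE.NAMES = FALSE)
    r <- rle(mins)
    stops <- cumsum(r$lengths)
    starts <- c(1, head(stops, -1) + 1)
    for (i in seq_along(r$values)) {
      out[[length(out) + 1]] <- list(
        sequence = substr(frag, starts[i], stops[i] + k - 1),
        minimizer = r$values[i])
    }
  }
  tibble::tibble(
    sequence = vapply(out, `[[`, "", "sequence"),
    minimizer = vapply(out, `[[`, "", "minimizer"))
}

# literal transcription of the three-case rescue rule: k-mers under hard-min
# were discarded at counting; counts at or above soft-min are solid and kept;
# counts in [hard-min, soft-min) are kept iff solid in >= share_min OTHER
# samples.
oracle_rescue_row <- function(counts, hard_min, soft_min, share_min) {
  C <- length(counts)
  out <- counts
  for (i in seq_len(C)) {
    a <- counts[i]
    if (a == 0) next
    if (a < hard_min[i]) {
      out[i] <- 0
      next
    }
    if (a >= soft_min[i]) next
    n_support <- 0
    for (j in seq_len(C)) {
      if (j != i && counts[j] >= soft_min[j]) n_support <- n_support + 1
    }
    if (n_support < share_min) out[i] <- 0
  }
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}
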