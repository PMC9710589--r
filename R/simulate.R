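#' Specify a synthetic sequencing community
#'
#' Describes a multi-sample community with known ground truth: one or more
#' genomes (generated i.i.d. uniform over ACGT, or user-supplied), a
#' per-genome per-sample coverage matrix, a read length and an i.i.d.
#' per-base substitution error rate. Substitution-only errors keep the truth
#' computation exact while still producing the erroneous k-mers that the
#' filtering stages are meant to remove.
#'
#' @param coverage Numeric matrix of coverages, genomes in rows and samples
#'   in columns (a vector is taken as one genome across samples).
#' @param genome_length Integer vector, one length per genome (ignored for
#'   genomes supplied via `genomes`).
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability `0 <= e < 1`.
#' @param k K-mer length used for the truth sets.
#' @param seed RNG seed; the whole collection is deterministic given the spec.
#' @param genomes Optional character vector of genome sequences (overrides
#'   `genome_length`).
#' @param sample_ids Optional sample names (default `S1..Sn`).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(coverage, genome_length = 10000, read_length = 100,
                           error_rate = 0.005, k = 20, seed = 1,
                           genomes = NULL, sample_ids = NULL) {
  if (is.vector(coverage)) coverage <- matrix(coverage, nrow = 1)
  if (any(coverage < 0)) stop("coverages must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  G <- nrow(coverage)
  if (is.null(genomes)) genome_length <- rep_len(as.integer(genome_length), G)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(coverage)))
  structure(
    list(coverage = coverage, genome_length = genome_length,
         read_length = as.integer(read_length), error_rate = error_rate,
         k = as.integer(k), seed = as.integer(seed), genomes = genomes,
         sample_ids = sample_ids),
    class = "community_spec"
  )
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a read collection with known ground truth
#'
#' For each sample and genome, draws `round(coverage * genome_length /
#' read_length)` reads uniformly from the circularized genome, flips each
#' read to the reverse strand with probability 1/2 (exercising
#' canonicalization), then applies i.i.d. substitutions at the spec's error
#' rate (a substituted base always changes). Reads are written as FASTQ with
#' constant `I` qualities, which the construction pipeline ignores. The
#' returned truth is computed from the genomes and the pre-error reads.
#'
#' @param spec A [community_spec()].
#' @param dir Output directory for the FASTQ files (created if needed).
#' @param gzip Compress the FASTQ files.
#' @return A list with `files` (named FASTQ paths), `genomes`,
#'   `genome_kmers` (canonical k-mer set of all genomes combined),
#'   `true_counts` (per sample, tibble of canonical k-mer / error-free
#'   abundance), `erroneous` (per sample, character vector of distinct
#'   canonical read k-mers absent from every genome) and `spec`.
#' @export
simulate_collection <- function(spec, dir, gzip = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- spec$k
  L <- spec$read_length
  with_seed(spec$seed, {
    genomes <- spec$genomes
    if (is.null(genomes)) {
      genomes <- vapply(spec$genome_length, random_genome, "")
    }
    gkm <- cpp_count_kmers(genomes_wrapped(genomes, k), k)$key

    n_samples <- ncol(spec$coverage)
    files <- character(n_samples)
    true_counts <- vector("list", n_samples)
    erroneous <- vector("list", n_samples)
    for (j in seq_len(n_samples)) {
      pre <- character(0)
      for (g in seq_len(nrow(spec$coverage))) {
        cov <- spec$coverage[g, j]
        if (cov == 0) next
        Glen <- nchar(genomes[g])
        n <- round(cov * Glen / L)
        if (n == 0) {
          warning(sprintf("coverage %.3g of genome %d yields zero reads in sample %s; skipped",
                          cov, g, spec$sample_ids[j]))
          next
        }
        doubled <- paste0(genomes[g], substr(genomes[g], 1, L - 1))
        pos <- sample.int(Glen, n, replace = TRUE)
        rds <- substring(doubled, pos, pos + L - 1)
        flip <- stats::runif(n) < 0.5
        if (any(flip)) rds[flip] <- cpp_revcomp(rds[flip])
        pre <- c(pre, rds)
      }
      reads <- inject_substitutions(pre, spec$error_rate)
      f <- file.path(dir, paste0(spec$sample_ids[j], ".fastq",
                                 if (gzip) ".gz" else ""))
      write_fastq(reads, f, prefix = spec$sample_ids[j])
      files[j] <- f
      true_counts[[j]] <- tibble::as_tibble(cpp_count_kmers(pre, k))
      obs <- cpp_count_kmers(reads, k)$key
      erroneous[[j]] <- setdiff(obs, gkm)
    }
    names(files) <- spec$sample_ids
    names(true_counts) <- spec$sample_ids
    names(erroneous) <- spec$sample_ids
    list(files = files, genomes = genomes, genome_kmers = gkm,
         true_counts = true_counts, erroneous = erroneous, spec = spec)
  })
}

# circular genomes: append k-1 leading bases so wrap-around k-mers count
genomes_wrapped <- function(genomes, k) {
  vapply(genomes, function(g) paste0(g, substr(g, 1, k - 1)), "",
         USE.NAMES = FALSE)
}

inject_substitutions <- function(reads, e) {
  if (e == 0 || length(reads) == 0) return(reads)
  L <- nchar(reads)
  n_err <- stats::rbinom(length(reads), L, e)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(L[i], n_err[i])  # without replacement: one hit per base
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

write_fastq <- function(reads, path, prefix = "read") {
  ids <- sprintf("%s_%d", prefix, seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Count erroneous k-mers in a sample
#'
#' Number of distinct canonical k-mers of the reads that are absent from the
#' canonical k-mer set of every source genome. With a zero error rate this is
#' zero by construction.
#'
#' @param reads Character vector of reads or a FASTA/FASTQ path.
#' @param genomes Character vector of genome sequences (treated as circular).
#' @param k K-mer length.
#' @return Integer count.
#' @export
erroneous_kmer_count <- function(reads, genomes, k) {
  reads <- read_sequences(reads)
  gkm <- cpp_count_kmers(genomes_wrapped(genomes, k), k)$key
  obs <- cpp_count_kmers(reads, k)$key
  length(setdiff(obs, gkm))
}

#' Filtering ratio
#'
#' Number of filtered k-mers divided by the expected number of erroneous
#' k-mers; a perfect filter removes exactly the erroneous k-mers and scores
#' 1. Values above 1 indicate over-filtering (true k-mers lost), below 1
#' under-filtering (errors kept).
#'
#' @param n_filtered Number of k-mers removed by the filter.
#' @param n_expected_err Expected number of erroneous k-mers (> 0).
#' @return `n_filtered / n_expected_err`; `NaN` with a warning when
#'   `n_expected_err` is zero.
#' @export
filtering_ratio <- function(n_filtered, n_expected_err) {
  if (any(n_expected_err == 0)) {
    warning("zero expected erroneous k-mers: filtering ratio undefined (NaN)")
  }
  ifelse(n_expected_err == 0, NaN, n_filtered / n_expected_err)
}

#' Compare rescue filtering against plain abundance filtering
#'
#' Runs the k-mer-mode construction pipeline three times on a simulated
#' collection -- (a) rescue enabled with the given thresholds, (b) the
#' classical baseline that simply discards k-mers below `baseline_hard_min`,
#' and (c) an unfiltered reference run (hard-min 1, no rescue) -- and
#' computes each sample's filtering ratio for (a) and (b): distinct k-mers
#' removed divided by the number of truly erroneous k-mers in that sample.
#'
#' @param sim A [simulate_collection()] result.
#' @param hard_min,soft_min,share_min Rescue thresholds for run (a).
#' @param baseline_hard_min Solidity threshold of the baseline run (default
#'   2: drop k-mers seen once).
#' @param P,bits Partitioning and hash-space parameters for the runs.
#' @param dir Working directory for the three runs (default tempdir).
#' @return A tibble with one row per sample: `id`, `distinct` (distinct
#'   k-mers at hard-min 1), `expected_err`, `filtered_rescue`,
#'   `ratio_rescue`, `filtered_baseline`, `ratio_baseline`. Attributes
#'   `matrix_rescue` and `matrix_raw` carry the post-rescue and unfiltered
#'   joint count matrices for downstream retention analyses.
#' @export
rescue_benchmark <- function(sim, hard_min = 1, soft_min = 3, share_min = 3,
                             baseline_hard_min = 2, P = 8, bits = 2^20,
                             dir = tempfile("bench")) {
  k <- sim$spec$k
  man <- tibble::tibble(id = names(sim$files), path = unname(sim$files))
  run1 <- function(sub, rescue, hm, sm) {
    cfg <- run_config(man, file.path(dir, sub), k = k, m = min(8, k - 1),
                      P = P, bits = bits, mode = "kmer", rescue = rescue,
                      hard_min = hm, soft_min = sm, share_min = share_min,
                      seed = sim$spec$seed)
    run_pipeline(cfg)
  }
  res_rescue <- run1("rescue", TRUE, hard_min, soft_min)
  res_base <- run1("baseline", FALSE, baseline_hard_min, baseline_hard_min)
  res_raw <- run1("raw", FALSE, 1, 1)

  ids <- man$id
  distinct <- vapply(res_raw$report$samples, function(x) x$distinct_keys, 1)
  surv_rescue <- vapply(seq_along(ids), function(i)
    sum(res_rescue$matrix[[ids[i]]] > 0), 1)
  surv_base <- vapply(seq_along(ids), function(i)
    sum(res_base$matrix[[ids[i]]] > 0), 1)
  expected <- vapply(ids, function(id) length(sim$erroneous[[id]]), 1)
  out <- tibble::tibble(
    id = ids, distinct = distinct, expected_err = expected,
    filtered_rescue = distinct - surv_rescue,
    ratio_rescue = filtering_ratio(distinct - surv_rescue, expected),
    filtered_baseline = distinct - surv_base,
    ratio_baseline = filtering_ratio(distinct - surv_base, expected)
  )
  attr(out, "matrix_rescue") <- res_rescue$matrix
  attr(out, "matrix_raw") <- res_raw$matrix
  attr(out, "params") <- list(hard_min = hard_min, soft_min = soft_min,
                              share_min = share_min,
                              baseline_hard_min = baseline_hard_min)
  out
}
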