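#' Configure a construction run
#'
#' Collects every knob of the construction pipeline into a validated config.
#' Defaults follow common practice for short-read indexing: k = 20, m = 10,
#' 16 partitions, a 2^26-bit filter, hash-mode counting with rescue enabled.
#' When rescue is on the default hard-min is 1 (so low-abundance k-mers reach
#' the merge stage and can be rescued); when rescue is off it is 2 (the
#' classical "drop k-mers seen once" filter).
#'
#' @param manifest Samples: a data.frame/tibble with columns `id` and `path`,
#'   a named character vector (names = ids), or a character vector of paths
#'   (ids default to the basename). A `path` may contain several files
#'   separated by `;`, concatenated as one sample. Paths may also be in-memory
#'   character vectors of reads when `manifest` is a list of such vectors.
#' @param output Output directory (created if missing).
#' @param k K-mer length (`m < k <= 26`).
#' @param m Minimizer length (`1 <= m < k`, `m <= 12`).
#' @param P Number of partitions (>= 1).
#' @param bits Requested total Bloom filter size in bits (>= 8).
#' @param mode `"hash"` (count hash values; Bloom filter output) or `"kmer"`
#'   (count canonical k-mers; count-matrix output).
#' @param rescue Logical; apply the rare-but-shared rescue rule at merge.
#' @param hard_min Scalar or per-sample vector; `NULL` picks the default
#'   described above.
#' @param soft_min `"auto"` (resolved per sample from the abundance histogram
#'   with `soft_min_pct`), or a scalar / per-sample vector.
#' @param soft_min_pct Percentage for the automatic soft-min rule
#'   (default 0.1, i.e. 0.1%).
#' @param share_min Number of other samples in which a sub-soft k-mer must be
#'   solid to be rescued (default 1).
#' @param seed Hash seed; recorded in every output header.
#' @param subsample Reads per sample used to balance the partition map.
#' @param threads Accepted for interface compatibility; partitions are
#'   processed sequentially in a fixed order, so results never depend on it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest, output,
                       k = 20, m = 10, P = 16, bits = 2^26,
                       mode = c("hash", "kmer"),
                       rescue = TRUE, hard_min = NULL,
                       soft_min = "auto", soft_min_pct = 0.1,
                       share_min = 1, seed = 0, subsample = 1e4,
                       threads = 1) {
  mode <- match.arg(mode)
  man <- normalize_manifest(manifest)
  if (k <= m || m < 1) stop("require 1 <= m < k")
  if (k > 26) stop("k must be <= 26")
  if (m > 12) stop("m must be <= 12")
  if (P < 1) stop("P must be >= 1")
  if (bits < 8) stop("bits must be >= 8")
  if (is.null(hard_min)) hard_min <- if (rescue) 1L else 2L
  C <- nrow(man)
  hard_min <- rep_len(as.integer(hard_min), C)
  if (!identical(soft_min, "auto")) {
    soft_min <- rep_len(as.integer(soft_min), C)
    if (any(soft_min < hard_min)) stop("soft_min must be >= hard_min")
  }
  structure(
    list(manifest = man, output = output, k = as.integer(k),
         m = as.integer(m), P = as.integer(P), bits = as.numeric(bits),
         mode = mode, rescue = isTRUE(rescue), hard_min = hard_min,
         soft_min = soft_min, soft_min_pct = soft_min_pct,
         share_min = as.numeric(share_min), seed = as.numeric(seed),
         subsample = subsample, threads = as.integer(threads),
         hs = hash_space(bits, P, seed)),
    class = "run_config"
  )
}

normalize_manifest <- function(manifest) {
  if (is.data.frame(manifest)) {
    stopifnot(all(c("id", "path") %in% names(manifest)))
    man <- tibble::tibble(id = as.character(manifest$id),
                          path = manifest$path)
  } else if (is.list(manifest)) {
    ids <- names(manifest)
    if (is.null(ids)) ids <- paste0("S", seq_along(manifest))
    man <- tibble::tibble(id = ids, path = manifest)
  } else {
    ids <- names(manifest)
    if (is.null(ids)) ids <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                                 basename(manifest))
    man <- tibble::tibble(id = ids, path = as.character(manifest))
  }
  if (anyDuplicated(man$id)) stop("duplicate sample ids in manifest")
  man
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d samples k=%d m=%d P=%d bits=%s mode=%s rescue=%s seed=%s\n",
              nrow(x$manifest), x$k, x$m, x$P, format(x$bits), x$mode,
              x$rescue, format(x$seed)))
  invisible(x)
}

#' Read a sample manifest TSV
#'
#' Two tab-separated columns: sample id and file path(s); several paths for
#' one sample are separated by `;`. Lines starting with `#` are ignored.
#'
#' @param path Manifest file.
#' @return Tibble with columns `id`, `path`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("id", "path"),
                          colClasses = "character")
  tibble::as_tibble(df)
}

out_path <- function(cfg, ...) file.path(cfg$output, ...)

#' Pipeline stages
#'
#' The pipeline is a chain of individually invokable stages writing
#' intermediate files under the run's output directory, so a run can be
#' resumed after any completed stage:
#'
#' * `stage_partition()`: builds the balanced minimizer-to-partition map from
#'   a subsample of reads and writes `partition_map.kfpm`.
#' * `stage_count()`: per sample, spills super-k-mers to
#'   `superkmers/<id>/p<p>.tsv`, counts each partition (hash or k-mer mode),
#'   resolves soft-min thresholds from the abundance histogram, applies
#'   hard-min, and writes `counts/<id>/p<p>.kfpc` plus `sample_stats.json`.
#' * `stage_merge()`: n-way merges equivalent partitions across samples,
#'   applies the rescue rule, and writes hash-major sub-matrices
#'   `matrices/p<p>.kfbm` (hash mode) or the joint count matrix `matrix.tsv`
#'   (k-mer mode). Refuses to merge count files with inconsistent k or seed.
#' * `stage_assemble()`: transposes sub-matrices and concatenates them into
#'   per-sample filters `filters/<id>.kfbf`. With rescue disabled (hash mode)
#'   the merge stage is unnecessary and filters are assembled directly from
#'   each sample's counted hashes ([direct_pbf()]).
#'
#' @param cfg A [run_config()].
#' @return Each stage returns its main products invisibly; see
#'   [run_pipeline()] for the one-call wrapper.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_partition <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  check_inputs(cfg)
  pm <- build_partition_map(cfg$manifest$path, cfg$P, cfg$k, cfg$m,
                            subsample = cfg$subsample, seed = cfg$seed)
  write_partition_map(pm, out_path(cfg, "partition_map.kfpm"))
  invisible(pm)
}

check_inputs <- function(cfg) {
  for (p in cfg$manifest$path) {
    if (!is.character(p) || length(p) != 1) next  # in-memory reads
    for (f in strsplit(p, ";", fixed = TRUE)[[1]]) {
      if (!file.exists(f) && nchar(f) < 500) {
        stop("missing input file: ", f)
      }
    }
  }
}

#' @rdname stages
#' @export
stage_count <- function(cfg) {
  pm <- read_partition_map(out_path(cfg, "partition_map.kfpm"))
  stats <- vector("list", nrow(cfg$manifest))
  for (i in seq_len(nrow(cfg$manifest))) {
    id <- cfg$manifest$id[i]
    reads <- read_sequences(cfg$manifest$path[[i]])
    sk <- super_kmers_of(reads, cfg$k, cfg$m)
    part <- if (nrow(sk)) partition_of(sk$minimizer, pm) else integer(0)

    skdir <- out_path(cfg, "superkmers", id)
    cntdir <- out_path(cfg, "counts", id)
    dir.create(skdir, showWarnings = FALSE, recursive = TRUE)
    dir.create(cntdir, showWarnings = FALSE, recursive = TRUE)

    pcs <- vector("list", cfg$P)
    for (p in seq_len(cfg$P) - 1L) {
      skp <- sk[part == p, c("sequence", "minimizer"), drop = FALSE]
      utils::write.table(skp, file.path(skdir, sprintf("p%d.tsv", p)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      pcs[[p + 1]] <- count_partition(skp, p, pm, cfg$k, mode = cfg$mode,
                                      hs = cfg$hs, hard_min = 1,
                                      sample_id = id)
    }
    h <- histogram_of(pcs)
    soft <- if (identical(cfg$soft_min, "auto")) {
      if (cfg$rescue) auto_soft_min(h, cfg$soft_min_pct) else cfg$hard_min[i]
    } else cfg$soft_min[i]
    soft <- max(soft, cfg$hard_min[i])
    for (p in seq_len(cfg$P) - 1L) {
      pc <- pcs[[p + 1]]
      pc$entries <- pc$entries[pc$entries$count >= cfg$hard_min[i], ]
      pc$hard_min <- cfg$hard_min[i]
      write_partition_counts(pc, file.path(cntdir, sprintf("p%d.kfpc", p)),
                             m = cfg$m, P = cfg$P)
    }
    stats[[i]] <- list(
      id = id, n_reads = length(reads),
      distinct_keys = attr(h, "total_distinct"),
      kmer_mass = attr(h, "total_mass"),
      distinct_after_hard_min = sum(vapply(pcs, function(x)
        sum(x$entries$count >= cfg$hard_min[i]), 1)),
      hard_min = cfg$hard_min[i], soft_min = as.integer(soft),
      partition_distinct = vapply(pcs, function(x) nrow(x$entries), 1)
    )
  }
  jsonlite::write_json(stats, out_path(cfg, "sample_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stats)
}

read_sample_stats <- function(cfg) {
  jsonlite::read_json(out_path(cfg, "sample_stats.json"), simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

resolve_rescue_params <- function(cfg, stats) {
  hard <- vapply(stats, function(x) as.integer(x$hard_min), 1L)
  soft <- vapply(stats, function(x) as.integer(x$soft_min), 1L)
  rescue_params(hard, soft, cfg$share_min, length(stats))
}

#' @rdname stages
#' @export
stage_merge <- function(cfg) {
  stats <- read_sample_stats(cfg)
  rp <- if (cfg$rescue) resolve_rescue_params(cfg, stats) else NULL
  ids <- cfg$manifest$id
  merged_all <- if (cfg$mode == "kmer") vector("list", cfg$P) else NULL
  if (cfg$mode == "hash") {
    dir.create(out_path(cfg, "matrices"), showWarnings = FALSE, recursive = TRUE)
  }
  for (p in seq_len(cfg$P) - 1L) {
    streams <- lapply(ids, function(id) {
      pc <- read_partition_counts(out_path(cfg, "counts", id,
                                           sprintf("p%d.kfpc", p)))
      if (pc$k != cfg$k) stop("count file for sample '", id,
                              "' was produced with k=", pc$k,
                              " but this run uses k=", cfg$k)
      if (pc$mode != cfg$mode) stop("count file mode mismatch for sample '", id, "'")
      if (pc$mode == "hash" && pc$hs$seed != cfg$seed) {
        stop("refusing to merge: sample '", id, "' counted with seed ",
             format(pc$hs$seed), " but this run uses seed ", format(cfg$seed))
      }
      pc
    })
    mg <- nway_merge(streams)
    if (cfg$mode == "hash") {
      bm <- build_submatrix(mg, rp)
      write_bit_matrix(bm, out_path(cfg, "matrices", sprintf("p%d.kfbm", p)),
                       meta = list(p = p, s = cfg$hs$s, C = length(ids),
                                   seed = cfg$seed, k = cfg$k, m = cfg$m,
                                   P = cfg$P))
    } else {
      merged_all[[p + 1]] <- mg
    }
  }
  if (cfg$mode == "kmer") {
    mat <- emit_count_matrix(merged_all, rp, file = out_path(cfg, "matrix.tsv"))
    return(invisible(mat))
  }
  invisible(NULL)
}

#' @rdname stages
#' @export
stage_assemble <- function(cfg) {
  if (cfg$mode != "hash") return(invisible(NULL))
  pm <- read_partition_map(out_path(cfg, "partition_map.kfpm"))
  ids <- cfg$manifest$id
  dir.create(out_path(cfg, "filters"), showWarnings = FALSE, recursive = TRUE)
  use_merge <- cfg$rescue &&
    file.exists(out_path(cfg, "matrices", "p0.kfbm"))
  if (use_merge) {
    subs <- lapply(seq_len(cfg$P) - 1L, function(p) {
      bm <- read_bit_matrix(out_path(cfg, "matrices", sprintf("p%d.kfbm", p)))
      transpose_bits(bm)
    })
    filters <- assemble_filters(subs, ids, cfg$hs, cfg$k, cfg$m, pm)
  } else {
    # no-rescue fast path: pBF bit-vectors straight from per-sample counts
    filters <- lapply(ids, function(id) {
      rows <- lapply(seq_len(cfg$P) - 1L, function(p) {
        pc <- read_partition_counts(out_path(cfg, "counts", id,
                                             sprintf("p%d.kfpc", p)))
        direct_pbf(pc)
      })
      partitioned_bloom_filter(do.call(c, rows), id, cfg$hs, cfg$k, cfg$m, pm)
    })
  }
  for (bf in filters) {
    write_bloom_filter(bf, out_path(cfg, "filters", paste0(bf$sample, ".kfbf")))
  }
  invisible(filters)
}

#' Run the full construction pipeline
#'
#' Executes partition map construction, per-sample counting, cross-sample
#' merging with optional rescue, and Bloom filter assembly, writing all
#' intermediate and final artifacts under `cfg$output` together with a JSON
#' run report. With rescue disabled in hash mode the merge stage is skipped
#' and filters are emitted directly from per-sample counts. Stage-wise
#' execution (calling the `stage_*` functions in order) produces bit-identical
#' artifacts, and so does re-running the same config and seed.
#'
#' @param cfg A [run_config()].
#' @param stages Character vector of stages to run, in order; default all.
#' @return Invisibly, a list with the run `report` (also written to
#'   `report.json`), `filters` (hash mode) and/or `matrix` (k-mer mode).
#' @export
run_pipeline <- function(cfg, stages = c("partition", "count", "merge",
                                         "assemble")) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  res <- list()
  if ("partition" %in% stages) stage_partition(cfg)
  if ("count" %in% stages) stage_count(cfg)
  do_merge <- "merge" %in% stages && (cfg$rescue || cfg$mode == "kmer")
  if (do_merge) res$matrix <- stage_merge(cfg)
  if ("assemble" %in% stages) res$filters <- stage_assemble(cfg)

  stats <- read_sample_stats(cfg)
  loads <- Reduce(`+`, lapply(stats, function(x) as.numeric(x$partition_distinct)))
  report <- list(
    tool = "kmforge", version = as.character(utils::packageVersion("kmforge")),
    config = list(k = cfg$k, m = cfg$m, P = cfg$P, bits = cfg$bits,
                  s = cfg$hs$s, seed = cfg$seed, mode = cfg$mode,
                  rescue = cfg$rescue, share_min = cfg$share_min,
                  soft_min = if (identical(cfg$soft_min, "auto"))
                    paste0("auto(", cfg$soft_min_pct, "%)") else cfg$soft_min),
    samples = lapply(stats, function(x)
      x[c("id", "n_reads", "distinct_keys", "distinct_after_hard_min",
          "hard_min", "soft_min")]),
    partition_loads = loads,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, out_path(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  res$report <- report
  invisible(res)
}

#' Load the filters of a finished run and query sequences
#'
#' @param output Output directory of a hash-mode run.
#' @return `load_run` returns a list with `pm` (partition map) and `filters`.
#' @export
load_run <- function(output) {
  pm <- read_partition_map(file.path(output, "partition_map.kfpm"))
  files <- sort(list.files(file.path(output, "filters"), pattern = "\\.kfbf$",
                           full.names = TRUE))
  filters <- lapply(files, read_bloom_filter, pm = pm)
  list(pm = pm, filters = filters)
}

#' @rdname load_run
#' @param queries FASTA/FASTQ file (or character vector) of query sequences.
#' @return `query_run` returns a tibble with columns `query`, `sample`,
#'   `fraction`, `n_kmers`.
#' @export
query_run <- function(output, queries) {
  run <- load_run(output)
  seqs <- read_sequences(queries)
  qid <- names(seqs)
  if (is.null(qid)) qid <- paste0("q", seq_along(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    r <- query_sequence(run$filters, seqs[i])
    r$query <- qid[i]
    r[, c("query", "sample", "fraction", "n_kmers")]
  })
  do.call(rbind, out)
}
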