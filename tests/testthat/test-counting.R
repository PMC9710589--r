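make_map <- function(reads, P, k, m, seed = 0) {
  build_partition_map(list(reads), P = P, k = k, m = m, seed = seed)
}

test_that("count_partition handles empty input, singletons and hard-min", {
  set.seed(60)
  reads <- random_dna(20, 50)
  pm <- make_map(reads, 2, 11, 4)
  hs <- hash_space(2^16, 2, seed = 0)

  empty <- super_kmers_of(character(0), 11, 4)
  pc <- count_partition(empty, 0, pm, 11, mode = "kmer")
  expect_equal(nrow(pc$entries), 0L)

  one <- "ACGTACGTACG"  # a single 11-mer
  sk <- super_kmers_of(one, 11, 4)
  p <- partition_of(sk$minimizer, pm)[1]
  pc <- count_partition(sk, p, pm, 11, mode = "kmer", hard_min = 1)
  expect_equal(pc$entries$count, 1L)
  expect_equal(pc$entries$key, canonical_kmer(one))

  # hard-min drops low-abundance keys at this stage
  sk3 <- super_kmers_of(rep(one, 3), 11, 4)
  pc3 <- count_partition(sk3, p, pm, 11, mode = "kmer", hard_min = 2)
  expect_equal(pc3$entries$count, 3L)
  pc4 <- count_partition(sk3, p, pm, 11, mode = "kmer", hard_min = 4)
  expect_equal(nrow(pc4$entries), 0L)

  # routing a super-k-mer to the wrong partition is a programming-bug guard
  expect_error(count_partition(sk, 1 - p, pm, 11, mode = "kmer"),
               "partition")
  expect_error(count_partition(sk, p, pm, 11, mode = "hash", hs = NULL))
})

test_that("k-mer mode counting equals the flat sliding-window oracle", {
  set.seed(61)
  reads <- random_dna(200, 80)
  k <- 20
  pm <- make_map(reads, 4, k, 6)
  pcs <- count_sample(reads, pm, k, mode = "kmer")
  merged <- do.call(rbind, lapply(pcs, function(x) x$entries))
  merged <- merged[order(okey(merged$key)), ]
  want <- oracle_count(reads, k)
  expect_equal(merged$key, want$key)
  expect_equal(merged$count, want$count)

  # partition additivity: each canonical k-mer lands in exactly one partition
  expect_equal(sum(vapply(pcs, function(x) nrow(x$entries), 1L)), nrow(want))
  # keys strictly sorted within each partition
  for (pc in pcs) {
    if (nrow(pc$entries) > 1) {
      expect_false(is.unsorted(okey(pc$entries$key), strictly = TRUE))
    }
  }
})

test_that("hash-mode counts equal k-mer-mode counts modulo collisions", {
  set.seed(62)
  reads <- random_dna(60, 80)  # ~3.6e3 distinct k-mers
  k <- 20
  pm <- make_map(reads, 4, k, 6)
  hs <- hash_space(2^24, 4, seed = 5)
  kc <- count_sample(reads, pm, k, mode = "kmer")
  hc <- count_sample(reads, pm, k, mode = "hash", hs = hs)
  for (p in 0:3) {
    kmer_tab <- kc[[p + 1]]$entries
    if (nrow(kmer_tab) == 0) next
    idx <- hash_into_partition(kmer_tab$key, p, hs)
    want <- rowsum(kmer_tab$count, idx)
    got <- hc[[p + 1]]$entries
    expect_equal(got$key, as.numeric(rownames(want)))
    expect_equal(got$count, as.integer(want[, 1]))
    expect_true(all(got$key >= p * hs$s & got$key < (p + 1) * hs$s))
  }
})

test_that("abundance histograms tally distinct keys per abundance", {
  set.seed(63)
  reads <- random_dna(40, 60)
  pm <- make_map(reads, 2, 13, 5)
  pcs <- count_sample(reads, pm, 13, mode = "kmer")
  h <- histogram_of(pcs)
  counts <- unlist(lapply(pcs, function(x) x$entries$count))
  direct <- table(counts)
  expect_equal(h$abundance, as.integer(names(direct)))
  expect_equal(h$n_keys, as.integer(direct))
  expect_equal(attr(h, "total_distinct"), length(counts))
  expect_equal(attr(h, "total_mass"), sum(counts))

  empty <- histogram_of(list(count_partition(super_kmers_of(character(0), 13, 5),
                                             0, pm, 13, mode = "kmer")))
  expect_equal(nrow(empty), 0L)

  expect_warning(histogram_of(count_sample(reads, pm, 13, mode = "kmer",
                                           hard_min = 2)), "hard_min")
})

test_that("automatic soft-min follows the histogram rule", {
  mkhist <- function(ab, n) {
    h <- tibble::tibble(abundance = as.integer(ab), n_keys = as.integer(n))
    attr(h, "total_distinct") <- sum(n)
    class(h) <- c("abundance_histogram", class(h))
    h
  }
  expect_equal(auto_soft_min(mkhist(1:3, c(90, 5, 5)), 10), 2L)
  expect_equal(auto_soft_min(mkhist(1, 1), 50), 2L)  # max abundance + 1
  expect_equal(auto_soft_min(mkhist(1:3, c(30, 40, 30)), 100), 1L)
  # gaps in the support count as zero k-mers
  expect_equal(auto_soft_min(mkhist(c(1, 5), c(99, 1)), 2), 2L)
  expect_error(auto_soft_min(mkhist(1, 1), 0))
  expect_error(auto_soft_min(mkhist(1, 1), 101))
  expect_warning(s <- auto_soft_min(mkhist(integer(0), integer(0)), 10), "empty")
  expect_equal(s, 1L)
})

test_that("partition count files round-trip bit-exactly in both modes", {
  set.seed(64)
  reads <- random_dna(50, 60)
  k <- 15
  pm <- make_map(reads, 3, k, 5)
  hs <- hash_space(2^20, 3, seed = 7)
  for (mode in c("kmer", "hash")) {
    pcs <- count_sample(reads, pm, k, mode = mode, hs = hs, sample_id = "sm")
    for (pc in pcs) {
      f <- tempfile(fileext = ".kfpc")
      write_partition_counts(pc, f, m = 5, P = 3)
      back <- read_partition_counts(f)
      expect_equal(back$entries$key, pc$entries$key)
      expect_equal(back$entries$count, pc$entries$count)
      expect_equal(back$mode, mode)
      expect_equal(back$sample, "sm")
      expect_equal(back$partition, pc$partition)
      expect_equal(back$k, k)
      if (mode == "hash") expect_equal(back$hs$seed, 7)
    }
  }
  # text dump for debugging
  pc <- count_sample(reads, pm, k, mode = "kmer")[[1]]
  f <- tempfile(fileext = ".tsv")
  dump_partition_counts(pc, f)
  txt <- utils::read.table(f, sep = "\t", colClasses = c("character", "integer"))
  expect_equal(txt[[1]], pc$entries$key)
  expect_equal(txt[[2]], pc$entries$count)
})
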