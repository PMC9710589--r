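test_that("bit-matrix transposition swaps indices and is an involution", {
  # 3x2 matrix with bits {(0,1),(2,0)} (0-based) -> {(1,0),(0,2)}
  m <- matrix(FALSE, 3, 2)
  m[1, 2] <- TRUE  # (0,1)
  m[3, 1] <- TRUE  # (2,0)
  bm <- bm_from_matrix(m, "hash-major")
  tm <- transpose_bits(bm)
  expect_equal(tm$orientation, "sample-major")
  expect_equal(bm_as_matrix(tm), t(m))

  z <- bm_from_matrix(matrix(FALSE, 5, 9))
  expect_equal(sum(bm_as_matrix(transpose_bits(z))), 0)

  set.seed(80)
  for (rep in 1:10) {
    dims <- sample(1:40, 2)
    m <- matrix(stats::runif(prod(dims)) < 0.3, dims[1], dims[2])
    bm <- bm_from_matrix(m)
    expect_equal(bm_as_matrix(transpose_bits(bm)), t(m))
    back <- transpose_bits(transpose_bits(bm))
    expect_identical(back$payload, bm$payload)
    expect_equal(back$orientation, bm$orientation)
  }
})

test_that("bm_get probes individual bits", {
  m <- matrix(stats::runif(15 * 11) < 0.4, 15, 11)
  bm <- bm_from_matrix(m)
  ij <- expand.grid(i = 1:15, j = 1:11)
  expect_equal(bm_get(bm, ij$i, ij$j), m[as.matrix(ij)])
  expect_error(bm_get(bm, 16, 1), "range")
})

test_that("assembled filters concatenate transposed sub-matrix rows", {
  set.seed(81)
  hs <- hash_space(64 * 4, 4)  # s = 64, 4 partitions
  C <- 3
  subs <- lapply(1:4, function(p) {
    bm_from_matrix(matrix(stats::runif(C * hs$s) < 0.2, C, hs$s), "sample-major")
  })
  filters <- assemble_filters(subs, c("x", "y", "z"), hs, k = 11, m = 4)
  expect_equal(length(filters), C)
  expect_equal(vapply(filters, function(f) f$sample, ""), c("x", "y", "z"))
  # probing bit p*s + o equals sub-matrix p, row i, bit o
  probes <- data.frame(p = sample(0:3, 1000, replace = TRUE),
                       o = sample(0:(hs$s - 1), 1000, replace = TRUE),
                       i = sample(1:C, 1000, replace = TRUE))
  for (t in seq_len(nrow(probes))) {
    with(probes[t, ], {
      got <- kmforge:::cpp_get_bits(filters[[i]]$payload, p * hs$s + o)
      want <- bm_get(subs[[p + 1]], i, o + 1)
      expect_equal(got, want)
    })
  }

  # P=1: the filter equals the single matrix row
  hs1 <- hash_space(64, 1)
  one <- bm_from_matrix(matrix(stats::runif(64) < 0.5, 1, 64), "sample-major")
  f1 <- assemble_filters(list(one), "only", hs1, 11, 4)
  expect_identical(f1[[1]]$payload, one$payload)

  expect_error(assemble_filters(subs[1:3], c("x", "y", "z"), hs, 11, 4))
  expect_error(assemble_filters(lapply(subs, transpose_bits),
                                c("x", "y", "z"), hs, 11, 4), "sample-major")
})

test_that("the direct pBF fast path equals the merge-and-transpose path", {
  hs <- hash_space(128 * 2, 2)  # s = 128
  mk <- function(keys, counts, p) {
    structure(list(sample = "s", partition = as.integer(p), mode = "hash",
                   k = 11L, hard_min = 1L, hs = hs,
                   entries = tibble::tibble(key = keys, count = as.integer(counts))),
              class = "partition_counts")
  }
  expect_equal(direct_pbf(mk(numeric(0), integer(0), 1)), raw(hs$s / 8))
  pb <- direct_pbf(mk(1 * hs$s + c(0, 7), c(1, 2), 1))
  expect_equal(which(as.logical(rawToBits(pb))) - 1, c(0, 7))

  set.seed(82)
  for (p in 0:1) {
    keys <- p * hs$s + sort(sample(0:(hs$s - 1), 30))
    pc <- mk(keys, sample(1:5, 30, replace = TRUE), p)
    via_merge <- transpose_bits(build_submatrix(nway_merge(list(pc))))
    expect_identical(direct_pbf(pc), via_merge$payload)
  }
  expect_error(direct_pbf(mk(5, 1, 1)), "range")
})

test_that("queries have no false negatives and respect the partition scheme", {
  set.seed(83)
  reads <- random_dna(80, 90)
  k <- 17
  pm <- build_partition_map(list(reads), P = 4, k = k, m = 5)
  hs <- hash_space(2^18, 4, seed = 3)
  pcs <- count_sample(reads, pm, k, mode = "hash", hs = hs, sample_id = "s1")
  payload <- do.call(c, lapply(pcs, direct_pbf))
  bf <- partitioned_bloom_filter(payload, "s1", hs, k, 5, pm)

  inserted <- unique(canonical_kmer(oracle_kmers(reads, k)))
  expect_true(all(query_kmer(bf, inserted)))  # no false negatives
  expect_false(query_kmer(bf, paste0("N", strrep("A", k - 1))))
  expect_error(query_kmer(bf, "ACGT"), "length")

  zero <- partitioned_bloom_filter(raw(hs$P * hs$s / 8), "z", hs, k, 5, pm)
  probes <- random_dna(200, k)
  expect_false(any(query_kmer(zero, probes)))

  # sequence-level aggregation: a sequence fully drawn from the sample -> 1.0
  res <- query_sequence(list(bf, zero), reads[1])
  expect_equal(res$fraction, c(1, 0))
  expect_equal(res$n_kmers, rep(nchar(reads[1]) - k + 1L, 2))
  expect_error(query_sequence(list(bf), substr(reads[1], 1, k - 1)), "shorter")

  # non-ACGT k-mers are excluded from numerator and denominator
  gap <- paste0(substr(reads[1], 1, 40), "N", substr(reads[2], 1, 40))
  res2 <- query_sequence(list(bf), gap)
  expect_equal(res2$n_kmers, (40 - k + 1) * 2L)
})

test_that("a half-indexed query sequence reports a fraction near one half", {
  set.seed(84)
  k <- 17
  seq_full <- random_dna(1, 400)
  first_half <- substr(seq_full, 1, 200 + k - 1)
  pm <- build_partition_map(list(seq_full), P = 2, k = k, m = 5)
  hs <- hash_space(2^20, 2, seed = 1)  # large: negligible false positives
  pcs <- count_sample(first_half, pm, k, mode = "hash", hs = hs)
  bf <- partitioned_bloom_filter(do.call(c, lapply(pcs, direct_pbf)),
                                 "s", hs, k, 5, pm)
  frac <- query_sequence(list(bf), seq_full)$fraction
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.58)
})

test_that("false positive rate tracks filter occupancy for a single-hash filter", {
  set.seed(85)
  k <- 17
  pm <- build_partition_map(list(random_dna(200, 90)), P = 1, k = k, m = 5)
  hs <- hash_space(2^13, 1, seed = 4)
  inserted <- unique(canonical_kmer(random_dna(3000, k)))
  idx <- hash_into_partition(inserted, 0, hs)
  bf <- partitioned_bloom_filter(kmforge:::cpp_set_bits(raw(hs$s / 8), idx),
                                 "s", hs, k, 5, pm)
  occupancy <- kmforge:::cpp_popcount(bf$payload) / hs$s
  probes <- setdiff(unique(canonical_kmer(random_dna(4e4, k))), inserted)
  fpr <- mean(query_kmer(bf, probes))
  expect_lt(abs(fpr - occupancy) / occupancy, 0.2)
})

test_that("Bloom filter files round-trip bit-exactly and verify their map", {
  set.seed(86)
  reads <- random_dna(40, 80)
  k <- 15
  pm <- build_partition_map(list(reads), P = 2, k = k, m = 4)
  hs <- hash_space(2^14, 2, seed = 6)
  pcs <- count_sample(reads, pm, k, mode = "hash", hs = hs, sample_id = "rt")
  bf <- partitioned_bloom_filter(do.call(c, lapply(pcs, direct_pbf)),
                                 "rt", hs, k, 4, pm)
  f <- tempfile(fileext = ".kfbf")
  write_bloom_filter(bf, f)
  back <- read_bloom_filter(f, pm = pm)
  expect_identical(back$payload, bf$payload)
  expect_equal(back$sample, "rt")
  expect_equal(back$k, k)
  expect_equal(back$hs$s, hs$s)
  expect_equal(back$hs$seed, hs$seed)
  expect_equal(back$pm_digest, partition_map_digest(pm))

  other <- build_partition_map(list(random_dna(40, 80)), P = 2, k = k, m = 4)
  expect_error(read_bloom_filter(f, pm = other), "digest")

  # bit matrix files round-trip too
  m <- matrix(stats::runif(32 * 5) < 0.3, 32, 5)
  bm <- bm_from_matrix(m, "hash-major")
  fb <- tempfile(fileext = ".kfbm")
  write_bit_matrix(bm, fb, meta = list(p = 1, s = 32, C = 5, seed = 6,
                                       k = k, m = 4, P = 2))
  bmb <- read_bit_matrix(fb)
  expect_identical(bmb$payload, bm$payload)
  expect_equal(bmb$rows, 32)
  expect_equal(attr(bmb, "meta")$C, 5)
})
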