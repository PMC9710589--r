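fake_pc <- function(keys, counts, sample = "s", partition = 0L, mode = "hash",
                    k = 11L, hs = hash_space(2^16, 4), hard_min = 1L) {
  structure(list(sample = sample, partition = as.integer(partition),
                 mode = mode, k = as.integer(k), hard_min = as.integer(hard_min),
                 hs = hs,
                 entries = tibble::tibble(key = keys, count = as.integer(counts))),
            class = "partition_counts")
}

test_that("n-way merge takes the sorted union with zeros for absences", {
  hs <- hash_space(2^16, 4)
  one <- fake_pc(c(3, 9, 11), c(2, 1, 5), sample = "a")
  mg <- nway_merge(list(one))
  expect_equal(mg$keys, c(3, 9, 11))
  expect_equal(mg$counts, matrix(c(2L, 1L, 5L), ncol = 1))

  two <- nway_merge(list(fake_pc(1, 2, sample = "a"), fake_pc(2, 3, sample = "b")))
  expect_equal(two$keys, c(1, 2))
  expect_equal(two$counts, rbind(c(2L, 0L), c(0L, 3L)))

  # random streams against a brute-force table join
  set.seed(70)
  for (rep in 1:10) {
    streams <- lapply(1:4, function(i) {
      keys <- sort(sample(100, sample(0:20, 1)))
      fake_pc(keys, sample(9, length(keys), replace = TRUE),
              sample = paste0("s", i))
    })
    mg <- nway_merge(streams)
    all_keys <- sort(unique(unlist(lapply(streams, function(x) x$entries$key))))
    expect_equal(mg$keys, all_keys)
    for (i in 1:4) {
      want <- integer(length(all_keys))
      want[match(streams[[i]]$entries$key, all_keys)] <- streams[[i]]$entries$count
      expect_equal(mg$counts[, i], want)
    }
    # conservation: merge neither creates nor drops counts
    expect_equal(sum(mg$counts),
                 sum(unlist(lapply(streams, function(x) x$entries$count))))
  }
})

test_that("n-way merge rejects unsorted, cross-partition and cross-seed input", {
  expect_error(nway_merge(list(fake_pc(c(5, 2), c(1, 1)))), "sorted")
  expect_error(nway_merge(list(fake_pc(1, 1, partition = 0),
                               fake_pc(1, 1, partition = 1))), "partitions")
  expect_error(nway_merge(list(fake_pc(1, 1, hs = hash_space(2^16, 4, seed = 1)),
                               fake_pc(1, 1, hs = hash_space(2^16, 4, seed = 2)))),
               "seed")
  km <- fake_pc("ACGTACGTACG", 1, mode = "kmer")
  expect_error(nway_merge(list(km, fake_pc(1, 1))), "mode")
})

test_that("rescue keeps solid counts and rescues shared sub-soft counts", {
  rp <- rescue_params(1, 3, 3, 5)
  # sub-soft count in sample 1 is solid in three other samples -> rescued
  expect_equal(rescue_row(c(1, 0, 5, 4, 3), rp), c(1, 0, 5, 4, 3))
  # solid in only two other samples -> sub-soft counts zeroed
  expect_equal(rescue_row(c(1, 0, 5, 4, 2), rp), c(0, 0, 5, 4, 0))
  expect_error(rescue_row(c(1, 2), rp), "length")

  # share_min = 0: everything at or above hard-min survives
  rp0 <- rescue_params(2, 5, 0, 4)
  expect_equal(rescue_row(c(2, 0, 3, 9), rp0), c(2, 0, 3, 9))
  # soft_min = hard_min: plain thresholding, nothing is sub-soft
  rpt <- rescue_params(2, 2, 3, 4)
  expect_equal(rescue_row(c(2, 0, 7, 2), rpt), c(2, 0, 7, 2))

  expect_error(rescue_params(1, 3, -1, 2), "share_min")
  expect_error(rescue_params(3, 2, 1, 2), "soft_min")
})

test_that("rescue matches the literal three-case transcription on random rows", {
  set.seed(71)
  C <- 10
  rows <- matrix(sample(0:10, 2000 * C, replace = TRUE), ncol = C)
  for (rep in 1:20) {
    hard <- sample(1:3, C, replace = TRUE)
    soft <- hard + sample(0:4, C, replace = TRUE)
    share <- sample(0:5, 1)
    rp <- rescue_params(hard, soft, share, C)
    got <- rescue_counts(rows, rp)
    idx <- sample(nrow(rows), 200)
    for (i in idx) {
      expect_equal(got[i, ], oracle_rescue_row(rows[i, ], hard, soft, share))
    }
  }
})

test_that("rescue is monotone in share_min and reduces to thresholding at the limits", {
  set.seed(72)
  C <- 6
  rows <- matrix(sample(0:8, 500 * C, replace = TRUE), ncol = C)
  hard <- rep(1L, C)
  soft <- sample(2:5, C, replace = TRUE)
  prev <- NULL
  for (share in 0:6) {
    out <- rescue_counts(rows, rescue_params(hard, soft, share, C))
    if (!is.null(prev)) expect_true(all(out == 0 | prev > 0))  # survivors shrink
    # solid cells are never removed
    solid <- sweep(rows, 2, soft, ">=")
    expect_true(all(out[solid] == rows[solid]))
    prev <- out
  }
  # share_min > C: no rescue is possible; pure soft-min thresholding
  out <- rescue_counts(rows, rescue_params(hard, soft, C + 1, C))
  want <- rows
  want[sweep(rows, 2, soft, "<")] <- 0L
  expect_equal(out, want)
})

test_that("binarize flags positive counts", {
  expect_equal(binarize(c(0, 0, 0)), c(FALSE, FALSE, FALSE))
  expect_equal(binarize(c(2, 0, 7)), c(TRUE, FALSE, TRUE))
  set.seed(73)
  m <- matrix(sample(0:3, 60, replace = TRUE), ncol = 6)
  expect_equal(binarize(m), m > 0)
})

test_that("sub-matrices are dense with implicit hash rows", {
  hs <- hash_space(64 * 4, 4)  # s = 64
  p <- 2L
  empty <- nway_merge(list(fake_pc(numeric(0), integer(0), partition = p, hs = hs)))
  bm0 <- build_submatrix(empty)
  expect_equal(bm0$rows, hs$s)
  expect_equal(sum(bm_as_matrix(bm0)), 0)

  one <- nway_merge(list(fake_pc(p * hs$s + 5, 4, partition = p, hs = hs),
                         fake_pc(numeric(0), integer(0), partition = p, hs = hs)))
  bm1 <- build_submatrix(one)
  dense <- bm_as_matrix(bm1)
  expect_equal(sum(dense), 1)
  expect_true(dense[6, 1])  # hash offset 5 -> row 6 (1-based), sample column 1

  # random input against a row-by-row oracle
  set.seed(74)
  keys <- sort(sample(0:(hs$s - 1), 40)) + p * hs$s
  streams <- lapply(1:3, function(i) {
    pick <- sort(sample(seq_along(keys), 25))
    fake_pc(keys[pick], sample(1:6, 25, replace = TRUE),
            sample = paste0("s", i), partition = p, hs = hs)
  })
  rp <- rescue_params(1, 3, 1, 3)
  mg <- nway_merge(streams)
  bm <- build_submatrix(mg, rp)
  want <- matrix(FALSE, hs$s, 3)
  resc <- rescue_counts(mg$counts, rp)
  for (t in seq_along(mg$keys)) {
    want[mg$keys[t] - p * hs$s + 1, ] <- resc[t, ] > 0
  }
  expect_equal(bm_as_matrix(bm), want)

  bad <- nway_merge(list(fake_pc(1, 1, partition = p, hs = hs)))  # key outside range
  expect_error(build_submatrix(bad), "range")
  expect_error(build_submatrix(nway_merge(list(fake_pc("ACGTACGTACG", 1, mode = "kmer")))),
               "hash-mode")
})

test_that("count matrices emit surviving rows as TSV and read back", {
  pcs <- list(fake_pc(c("AAAAA", "CCCCC"), c(1, 4), sample = "a", mode = "kmer",
                      k = 5, hs = NULL),
              fake_pc(c("CCCCC", "GAAAA"), c(5, 2), sample = "b", mode = "kmer",
                      k = 5, hs = NULL))
  mg <- nway_merge(pcs)
  f <- tempfile(fileext = ".tsv")
  rp <- rescue_params(1, c(4, 2), 1, 2)
  mat <- emit_count_matrix(list(mg), rp, file = f)
  # AAAAA count 1 in a only, solid nowhere else -> row dropped
  expect_equal(mat$kmer, c("CCCCC", "GAAAA"))
  expect_equal(mat$a, c(4L, 0L))
  expect_equal(mat$b, c(5L, 2L))
  back <- read_count_matrix(f)
  expect_equal(back, mat)

  # single sample, rescue off: the matrix is the sample's count table
  single <- emit_count_matrix(list(nway_merge(pcs[1])))
  expect_equal(single$kmer, c("AAAAA", "CCCCC"))
  expect_equal(single$a, c(1L, 4L))

  # nothing survives -> header-only file
  rp_hard <- rescue_params(1, 9, 5, 2)
  f2 <- tempfile(fileext = ".tsv")
  m2 <- emit_count_matrix(list(mg), rp_hard, file = f2)
  expect_equal(nrow(m2), 0L)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_count_matrix(f2)), 0L)
})
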