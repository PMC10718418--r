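win <- function(chrom = "c", s = 5, e = 6, id = 0L)
  data.frame(window_id = id, chrom = chrom, start_cM = s, end_cM = e)

test_that("local matrix entries follow the copies-shared definition", {
  ids <- c("A", "B", "C")
  # one haplotype pair spanning the whole window -> 1 copy
  seg <- ibd_segments(data.frame(id1 = "A", hap1 = 0L, id2 = "B",
                                 hap2 = 0L, chrom = "c",
                                 start_cM = 4, end_cM = 7))
  m <- build_local_matrix(seg, win(), ids)
  expect_equal(m[1, 2], 1.0)
  expect_equal(Matrix::diag(m), c(0, 0, 0))
  # both haplotype pairs spanning -> 2 copies
  seg2 <- ibd_segments(data.frame(
    id1 = c("A", "A"), hap1 = c(0L, 1L), id2 = c("B", "B"),
    hap2 = c(0L, 1L), chrom = "c", start_cM = 4, end_cM = 7))
  expect_equal(build_local_matrix(seg2, win(), ids)[1, 2], 2.0)
  # half-window overlap -> 0.5
  seg3 <- ibd_segments(data.frame(id1 = "A", hap1 = 0L, id2 = "B",
                                  hap2 = 0L, chrom = "c",
                                  start_cM = 5.5, end_cM = 9))
  expect_equal(build_local_matrix(seg3, win(), ids)[1, 2], 0.5)
})

test_that("duplicate overlapping calls are unioned, not summed", {
  ids <- c("A", "B")
  seg <- ibd_segments(data.frame(
    id1 = c("A", "A"), hap1 = 0L, id2 = c("B", "B"), hap2 = 0L,
    chrom = "c", start_cM = c(5.0, 5.4), end_cM = c(5.6, 6.0)))
  m <- build_local_matrix(seg, win(), ids)
  expect_equal(m[1, 2], 1.0)  # union [5, 6), not 0.6 + 0.6
})

test_that("local matrices match the dense brute-force oracle", {
  set.seed(11)
  N <- 20
  ids <- sprintf("I%02d", 1:N)
  pair <- t(replicate(50, sample(N, 2)))
  s <- runif(50, 0, 9)
  seg <- ibd_segments(data.frame(
    id1 = ids[pair[, 1]], hap1 = sample(0:1, 50, TRUE),
    id2 = ids[pair[, 2]], hap2 = sample(0:1, 50, TRUE),
    chrom = "c", start_cM = s, end_cM = s + runif(50, 0.2, 4)))
  grid <- make_window_grid(data.frame(chrom = "c", start_cM = 0,
                                      end_cM = 13), 1)
  locals <- build_local_matrices(seg, grid, ids)
  for (i in c(1, 4, 7, 10, 13)) {
    expect_equal(as.matrix(locals[[i]]),
                 oracle_local_matrix(seg, grid[i, ], ids),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_true(all(vapply(locals, function(m) max(m@x, 0) <= 2, logical(1))))
})

test_that("no segments give zero matrices; genome-spanning pair gives 1 everywhere", {
  ids <- c("A", "B")
  grid <- make_window_grid(data.frame(chrom = "c", start_cM = 0,
                                      end_cM = 5), 1)
  empty <- ibd_segments(data.frame(id1 = "A", hap1 = 0L, id2 = "B",
                                   hap2 = 0L, chrom = "c",
                                   start_cM = 0, end_cM = 5))[0, ]
  class(empty) <- c("ibd_segments", "data.frame")
  locals0 <- build_local_matrices(empty, grid, ids)
  expect_true(all(vapply(locals0, function(m) length(m@x) == 0, logical(1))))
  span <- ibd_segments(data.frame(id1 = "A", hap1 = 0L, id2 = "B",
                                  hap2 = 0L, chrom = "c",
                                  start_cM = 0, end_cM = 5))
  locals1 <- build_local_matrices(span, grid, ids)
  expect_true(all(vapply(locals1, function(m) m[1, 2] == 1, logical(1))))
})

test_that("global matrix is the width-weighted genome average plus 2I", {
  ids <- c("A", "B")
  grid <- make_window_grid(data.frame(chrom = "c", start_cM = 0,
                                      end_cM = 4), 1)
  # sharing in exactly one of 4 equal windows -> 1/4
  seg <- ibd_segments(data.frame(id1 = "A", hap1 = 0L, id2 = "B",
                                 hap2 = 0L, chrom = "c",
                                 start_cM = 1, end_cM = 2))
  phi <- build_global_matrix(build_local_matrices(seg, grid, ids))
  expect_equal(phi[1, 2], 1 / 4)
  expect_equal(Matrix::diag(phi), c(2, 2))
  # both copies everywhere -> 2
  seg2 <- ibd_segments(data.frame(
    id1 = c("A", "A"), hap1 = c(0L, 1L), id2 = c("B", "B"),
    hap2 = c(0L, 1L), chrom = "c", start_cM = 0, end_cM = 4))
  phi2 <- build_global_matrix(build_local_matrices(seg2, grid, ids))
  expect_equal(phi2[1, 2], 2)
})

test_that("global off-diagonals reconstruct total unioned IBD / genome length", {
  set.seed(23)
  N <- 12
  ids <- sprintf("I%02d", 1:N)
  pair <- t(replicate(40, sample(N, 2)))
  s <- runif(40, 0, 20)
  seg <- ibd_segments(data.frame(
    id1 = ids[pair[, 1]], hap1 = sample(0:1, 40, TRUE),
    id2 = ids[pair[, 2]], hap2 = sample(0:1, 40, TRUE),
    chrom = sample(c("a", "b"), 40, TRUE),
    start_cM = s, end_cM = s + runif(40, 0.5, 6)))
  spans <- data.frame(chrom = c("a", "b"), start_cM = 0, end_cM = c(26, 26))
  grid <- make_window_grid(spans, 1)
  phi <- build_global_matrix(build_local_matrices(seg, grid, ids))
  # independent oracle: per pair, sum over haplotype pairs of the genome-wide
  # unioned segment length (segments clipped to the spans), over total length
  glen <- sum(spans$end_cM - spans$start_cM)
  for (k in sample(which(upper.tri(matrix(0, N, N))), 20)) {
    i <- (k - 1) %% N + 1; j <- (k - 1) %/% N + 1
    if (i >= j) next
    tot <- 0
    for (ch in c("a", "b")) {
      w <- list(chrom = ch, start_cM = 0, end_cM = 26, window_id = 0)
      tot <- tot + oracle_local_matrix(seg, w, ids)[i, j] * 26
    }
    expect_equal(phi[i, j], tot / glen, tolerance = 1e-12)
  }
})

test_that("sparsification zeroes strictly-below-threshold entries", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(2, 3, 4),
                            x = c(0.05, 0.088, 0.9), dims = c(4, 4),
                            symmetric = TRUE)
  Matrix::diag(m) <- 2
  g <- sparsify_global(m, 0.088)
  expect_equal(g[1, 2], 0)        # < 0.088 zeroed
  expect_equal(g[1, 3], 0.088)    # equal kept
  expect_equal(g[2, 4], 0.9)
  # threshold 0 is the identity
  g0 <- sparsify_global(m, 0)
  expect_equal(g0[1, 2], 0.05)
})

test_that("sparsification reports connected components and is monotone", {
  # chain A-B-C with strong links, D isolated
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = c(0.5, 0.3),
                            dims = c(4, 4), symmetric = TRUE)
  Matrix::diag(m) <- 2
  g <- sparsify_global(m, 0.1)
  expect_equal(g@largest_block, 3L)
  expect_equal(sort(g@block_sizes), c(1L, 3L))
  expect_equal(g@blocks[1], g@blocks[2])
  expect_equal(g@blocks[2], g@blocks[3])
  expect_false(g@blocks[4] == g@blocks[1])
  # nnz monotone in the threshold
  fx <- fx_cohort()
  nnz <- function(th) length(sparsify_global(fx$phi, th)@x)
  expect_true(nnz(0.02) >= nnz(0.088))
  expect_true(nnz(0.088) >= nnz(0.5))
})

test_that("local matrices survive the MTX + sidecar round-trip", {
  fx <- fx_cohort()
  m <- fx$locals[[5]]
  f <- tempfile(fileext = ".mtx")
  write_local_matrix(m, f)
  m2 <- read_local_matrix(f, m@sample_ids)
  expect_equal(as.matrix(m2), as.matrix(m), ignore_attr = TRUE)
  expect_equal(m2@window_id, m@window_id)
  expect_equal(m2@width_cM, m@width_cM)
  expect_equal(m2@nnz_offdiag, m@nnz_offdiag)
  unlink(c(f, paste0(f, ".json")))
})
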