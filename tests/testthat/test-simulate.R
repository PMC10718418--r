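library(Matrix)

test_that("random sparse local matrices have the requested structure", {
  m <- simulate_sparse_psi(200, 400, seed = 3)
  expect_equal(nnz_offdiag(m), 400L)
  expect_equal(length(m@x), 200L)          # 200 unordered pairs stored
  expect_true(all(m@x > 0 & m@x < 2))
  expect_equal(Matrix::diag(m), rep(0, 200))
  expect_equal(as.matrix(m), t(as.matrix(m)))
  expect_identical(as.matrix(simulate_sparse_psi(200, 400, seed = 3)),
                   as.matrix(m))
  m0 <- simulate_sparse_psi(50, 0)
  expect_equal(length(m0@x), 0L)
  expect_error(simulate_sparse_psi(10, 200), "nnz")
})

test_that("a rate-zero cohort has no segments and all windows skip", {
  cfg <- sim_config(N = 30, seg_rate = 0, n_families = 0)
  coh <- simulate_ibd_cohort(cfg, seed = 1)
  expect_equal(nrow(coh$segments), 0)
  grid <- make_window_grid(coh$spans, 1)
  locals <- build_local_matrices(coh$segments, grid, coh$sample_ids)
  expect_true(all(vapply(locals, nnz_offdiag, integer(1)) == 0L))
})

test_that("per-window sharing density matches the analytic expectation", {
  # For an interior window of width w on a chromosome of length Lc, a
  # segment with uniform start and mean length mu overlaps the window with
  # probability (w + mu)/Lc, so E[pairs touching the window] =
  # N * rate * (w + mu)/Lc (truncation at the chromosome end is
  # negligible for a window far from it).
  cfg <- sim_config(N = 400, seg_rate = 4, len_min = 3, len_mean = 5,
                    n_families = 0, chr_lengths_cM = c(chr1 = 200))
  nrep <- 12
  counts <- vapply(seq_len(nrep), function(r) {
    coh <- simulate_ibd_cohort(cfg, seed = 100 + r)
    s <- coh$segments
    sum(s$start_cM < 41 & s$end_cM > 40)
  }, numeric(1))
  expected <- 400 * 4 * (1 + 5) / 200
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("planted families produce kinship-level global sharing", {
  cfg <- sim_config(N = 60, seg_rate = 0, n_families = 2, family_size = 3,
                    family_share = 0.5)
  coh <- simulate_ibd_cohort(cfg, seed = 9)
  grid <- make_window_grid(coh$spans, 1)
  phi <- build_global_matrix(build_local_matrices(coh$segments, grid,
                                                  coh$sample_ids))
  off <- phi[upper.tri(phi)]
  expect_equal(sort(unique(round(off[off > 0], 10))), 0.5)
  expect_equal(sum(off > 0), 2 * choose(3, 2))
  # after thresholding the families are the non-trivial blocks
  g <- sparsify_global(phi, 0.088)
  expect_equal(sort(g@block_sizes, decreasing = TRUE)[1:2], c(3L, 3L))
})

test_that("null phenotype follows the generative model", {
  N <- 3000
  phi <- global_ibd(2 * Diagonal(N))
  cfg <- sim_config(N = N)
  ph <- simulate_phenotype_null(phi, cfg, seed = 17)
  expect_identical(ph, simulate_phenotype_null(phi, cfg, seed = 17))
  # age ~ N(50, 25), sex ~ Bern(0.5)
  expect_equal(mean(ph$age), 50, tolerance = 0.5)
  expect_equal(sd(ph$age), 5, tolerance = 0.3)
  expect_equal(mean(ph$sex), 0.5, tolerance = 0.05)
  # Var(Y | X) = 2 + 1 = 3 at Phi = 2I
  res <- residuals(lm(y ~ age + sex, ph))
  expect_equal(var(res), 3, tolerance = 0.3)
  # OLS recovers the fixed effects
  co <- coef(lm(y ~ age + sex, ph))
  expect_equal(unname(co["age"]), 0.05, tolerance = 3 * 5^-1 * sqrt(3 / N) * 3)
  expect_equal(unname(co["sex"]), 0.5, tolerance = 3 * 2 * sqrt(3 / N))
})

test_that("rare-variant alternative uses the standardized effect size", {
  # direct evaluation of the adopted formula at the MAF cutoff
  expect_equal(0.02 / sqrt(2 * 5e-4 * (1 - 5e-4)), 0.633,
               tolerance = 1e-3)
  set.seed(3)
  N <- 500
  grid <- make_window_grid(data.frame(chrom = "c", start_cM = 0,
                                      end_cM = 50), 1)
  geno <- simulate_genotypes(N, grid, n_variants = 300,
                             maf_range = c(5e-4 / 5, 5e-3), seed = 4)
  phi <- global_ibd(2 * Diagonal(N))
  ph <- simulate_phenotype_null(phi, sim_config(N = N), seed = 5)
  out <- simulate_phenotype_rare_variants(ph, geno, maf_cut = 5e-4,
                                          seed = 6)
  expect_true(out$causal_window %in% grid$window_id)
  expect_equal(out$beta,
               0.02 / sqrt(2 * geno$info$maf[match(out$causal_variants,
                                                   geno$info$id)] *
                             (1 - geno$info$maf[match(out$causal_variants,
                                                      geno$info$id)])))
  # carriers shift upward for positive effects
  idx <- match(out$causal_variants, geno$info$id)
  carrier <- as.numeric(Matrix::rowSums(geno$G[, idx, drop = FALSE])) > 0
  if (sum(carrier) > 2)
    expect_gt(mean(out$pheno$y[carrier]), mean(out$pheno$y[!carrier]))
})

test_that("haplotype effects are scaled by carrier-count variance", {
  N <- 200
  ph <- simulate_phenotype_null(global_ibd(2 * Diagonal(N)),
                                sim_config(N = N), seed = 8)
  H <- rep(0L, N); H[1:50] <- 1L
  out <- simulate_phenotype_haplotype(ph, H)
  expect_equal(out$gamma, 0.02 / sd(H))
  expect_equal(out$pheno$y - ph$y, H * out$gamma)
  # unit variance gives gamma = 0.02 exactly
  H2 <- rep(c(0L, 1L, 2L), length.out = N)
  expect_equal(simulate_phenotype_haplotype(ph, H2)$gamma,
               0.02 / sd(H2))
  expect_error(simulate_phenotype_haplotype(ph, rep(1L, N)), "constant")
})

test_that("causal-window assignment follows the three rules", {
  grid <- make_window_grid(data.frame(chrom = "c", start_cM = 0,
                                      end_cM = 10), 1)
  # rule 1: inside a single window
  expect_equal(assign_causal_window("c", 3.2, 3.9, grid), 3L)
  # rule 2: two windows, larger overlap wins
  expect_equal(assign_causal_window("c", 3.8, 5.0, grid), 4L)
  expect_equal(assign_causal_window("c", 3.0, 4.2, grid), 3L)
  # rule 3: three or more windows, first fully covered window
  expect_equal(assign_causal_window("c", 2.5, 6.2, grid), 3L)
  expect_equal(assign_causal_window("c", 0.0, 9.9, grid), 0L)
})

test_that("planted haplotypes add carrier cliques and carrier counts", {
  cfg <- sim_config(N = 40, seg_rate = 1)
  coh <- simulate_ibd_cohort(cfg, seed = 2)
  out <- plant_causal_haplotype(coh, "chr1", 10, 14, n_carriers = 6,
                                seed = 3)
  expect_equal(sum(out$H), 6)
  expect_equal(length(out$carriers), 6)
  added <- out$cohort$segments
  added <- added[added$start_cM == 10 & added$end_cM == 14, ]
  expect_equal(nrow(added), choose(6, 2))
})

test_that("power estimation and cross-tabulation behave as proportions", {
  expect_equal(estimate_power(rep(1, 50), 0.05)$power, 0)
  set.seed(4)
  p <- runif(4000)
  est <- estimate_power(p, 0.05)
  expect_lt(abs(est$power - 0.05), 3 * est$se + 3 * sqrt(0.05 * 0.95 / 4000))
  ct <- power_crosstab(p < 0.5, p < 0.01)
  expect_equal(sum(ct$proportion), 1)
  expect_equal(ct$cell, c("both", "only1", "only2", "neither"))
})
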