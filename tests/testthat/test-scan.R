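library(Matrix)

test_that("window tests: dense oracle, projection and dual route agree", {
  fx <- fx_cohort()
  fit <- fx$fit
  idx <- order(vapply(fx$locals, nnz_offdiag, integer(1)),
               decreasing = TRUE)[1:12]
  bun <- build_projection(fit, B = 2000, seed = 4)  # B > N: dual route
  for (i in idx[1:4]) {
    d <- test_ibd_window(fit, fx$locals[[i]], NULL, path = "dense",
                         mode = "both")
    p <- test_ibd_window(fit, fx$locals[[i]], bun, mode = "both")
    expect_equal(p$p_finite, d$p_finite, tolerance = 0.15)
    expect_equal(p$Q, d$Q, tolerance = 1e-10)
  }
})

test_that("finite-sample eigen-target is a centered signed mixture", {
  # the subtraction of (Q/(N-c)) Sigma centres the spectrum: the trace
  # tr(Phat Psi) - Q fluctuates around zero across null windows, and the
  # weights carry both signs so the mixture is evaluated at 0
  fx <- fx_cohort()
  fit <- fx$fit
  ca <- ibdmap:::.dense_phat_factor(fit)
  rel_trace <- vapply(seq(5, 95, by = 10), function(i) {
    psi <- fx$locals[[i]]
    ratio <- as.numeric(score_statistic(fit, psi)) / (fit$N - fit$c)
    M <- crossprod(ca$K, as.matrix(psi %*% ca$K)) + 2 * ca$KtK -
      ratio * ca$KtSK
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) < 0 && max(ev) > 0)
    abs(sum(ev)) / sum(abs(ev))
  }, numeric(1))
  expect_lt(median(rel_trace), 0.1)
})

test_that("empty windows are skipped with a reason", {
  fx <- fx_cohort()
  empty <- simulate_sparse_psi(fx$fit$N, 0)
  out <- test_ibd_window(fx$fit, empty,
                         build_projection(fx$fit, B = 20, seed = 1))
  expect_equal(out$skipped, "empty window")
  expect_true(is.na(out$p_finite))
})

test_that("the scan flags planted signal windows and reports lambda_GC", {
  fx <- fx_cohort()
  # plant a strong local effect in one window
  target <- which(vapply(fx$locals, nnz_offdiag, integer(1)) > 50)[3]
  ph2 <- add_local_effect(fx$pheno, fx$locals[[target]], sigma2_l = 25,
                          seed = 55)
  fit2 <- ibd_lmm(y ~ age + sex, ph2, fx$phi)
  scan <- ibd_scan(fit2, fx$locals, fx$grid, B = 100, seed = 2)
  expect_s3_class(scan, "ibd_scan")
  expect_equal(nrow(scan), nrow(fx$grid))
  expect_equal(attr(scan, "threshold"), 0.05 / nrow(fx$grid))
  expect_true(scan$significant[target])
  expect_true(is.finite(attr(scan, "lambda_gc")))
  # serial and parallel scans coincide
  scan2 <- ibd_scan(fit2, fx$locals, fx$grid, B = 100, seed = 2,
                    threads = 2L)
  expect_equal(scan2$p_finite, scan$p_finite)
  # plot methods run quietly to a null device
  pdf(NULL)
  plot(scan); plot(scan, type = "qq")
  dev.off()
})

test_that("Bonferroni threshold reproduces the genome-wide convention", {
  # 3,403 one-cM windows at alpha = 0.05
  expect_equal(0.05 / 3403, 1.47e-5, tolerance = 0.002)
  # uniform p-values give lambda_GC ~ 1 by the median definition
  set.seed(12)
  p <- runif(20000)
  lam <- qchisq(1 - median(p), 1) / qchisq(0.5, 1)
  expect_equal(lam, 1, tolerance = 0.03)
})

test_that("conditional set selection clumps suggestive flanking variants", {
  gwas <- data.frame(
    chrom = "c", bp = c(1e6, 1.02e6, 1.05e6, 1.35e6, 9e6, 2e6),
    cM = c(1.0, 1.02, 1.05, 1.35, 9.0, 2.0),
    p = c(1e-8, 1e-10, 1e-7, 1e-9, 1e-20, 0.5),
    id = paste0("v", 1:6))
  w <- list(chrom = "c", start_cM = 0, end_cM = 1, window_id = 0L)
  sel <- select_conditional_set(gwas, w, flank_cM = 3, p_cut = 1e-6,
                                clump_kb = 100)
  # v5 outside the flank, v6 not suggestive; v1-v3 share a 100 kb bin
  expect_equal(sort(sel$id), c("v2", "v4"))
  # no suggestive variants -> empty set
  sel0 <- select_conditional_set(gwas, list(chrom = "c", start_cM = 50,
                                            end_cM = 51), flank_cM = 3)
  expect_equal(nrow(sel0), 0)
  # boundary: cM exactly at start - flank is included, end + flank excluded
  gwas2 <- data.frame(chrom = "c", bp = c(1, 2), cM = c(-3, 4),
                      p = c(1e-9, 1e-9), id = c("lo", "hi"))
  sel2 <- select_conditional_set(gwas2, w, flank_cM = 3)
  expect_equal(sel2$id, "lo")
})

test_that("conditioning on the generating variant removes the signal", {
  # a planted shared haplotype drives the phenotype; its carrier count,
  # used as a conditional covariate, fully tags the signal
  # genome long enough that a 4 cM shared haplotype stays below the global
  # threshold (4/370 << 0.088), so the signal is local, not polygenic
  cfg <- sim_config(N = 300, seg_rate = 3, n_families = 0)
  coh <- simulate_ibd_cohort(cfg, seed = 14)
  planted <- plant_causal_haplotype(coh, "chr1", 20, 24, n_carriers = 50,
                                    seed = 15)
  grid <- make_window_grid(planted$cohort$spans, 1)
  locals <- build_local_matrices(planted$cohort$segments, grid,
                                 planted$cohort$sample_ids)
  phi <- build_global_matrix(locals, threshold = 0.088)
  ph <- simulate_phenotype_null(phi, cfg, seed = 16)
  ph$y <- ph$y + 2.0 * planted$H
  fit <- ibd_lmm(y ~ age + sex, ph, phi)
  target <- assign_causal_window("chr1", 20, 24, grid) + 1L
  psi <- locals[[target]]
  un <- conditional_test(fit, psi, NULL, B = 100, seed = 3)
  co <- conditional_test(fit, psi, matrix(planted$H, ncol = 1),
                         B = 100, seed = 3)
  expect_lt(un$p_finite, 1e-4)
  expect_gt(co$p_finite, 1e-3)
  expect_gt(co$p_finite, un$p_finite)
  expect_equal(un$n_conditional, 0L)
  expect_equal(co$n_conditional, 1L)
})

test_that("single-variant score test is calibrated and detects strong effects", {
  set.seed(71)
  N <- 400
  phi <- global_ibd(2 * Diagonal(N))
  d <- data.frame(id = paste0("S", 1:N), age = rnorm(N, 50, 5),
                  sex = rbinom(N, 1, 0.5))
  d$y <- 0.05 * d$age + 0.5 * d$sex + rnorm(N)
  fit <- ibd_lmm(y ~ age + sex, d, phi)
  # null dosages: uniform p (KS over replicated tests)
  ps <- replicate(400, single_variant_score_test(fit, rbinom(N, 2, 0.3)))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # covariate-aligned dosage has zero variance -> NA
  expect_true(is.na(single_variant_score_test(fit, d$sex)))
  # strong effect detected
  g <- rbinom(N, 2, 0.4)
  d2 <- d; d2$y <- d2$y + 0.8 * g
  fit2 <- ibd_lmm(y ~ age + sex, d2, phi)
  expect_lt(single_variant_score_test(fit2, g), 5e-8)
})
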