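# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

# a small related cohort with matrices and a converged null fit
fx_cohort <- function() {
  if (!is.null(.fx$coh)) return(.fx$coh)
  cfg <- sim_config(N = 500, seg_rate = 4, n_families = 25,
                    chr_lengths_cM = c(chr1 = 60, chr2 = 50))
  coh <- simulate_ibd_cohort(cfg, seed = 42)
  grid <- make_window_grid(coh$spans, 1)
  locals <- build_local_matrices(coh$segments, grid, coh$sample_ids)
  phi <- build_global_matrix(locals, threshold = 0.088)
  pheno <- simulate_phenotype_null(phi, cfg, seed = 43)
  fit <- ibd_lmm(y ~ age + sex, pheno, phi)
  .fx$coh <- list(cfg = cfg, coh = coh, grid = grid, locals = locals,
                  phi = phi, pheno = pheno, fit = fit)
  .fx$coh
}

# dense brute-force local IBD matrix: independent O(N^2 * segments)
# reference implementation (explicit per-pair interval unions)
oracle_local_matrix <- function(seg, window, sample_ids) {
  N <- length(sample_ids)
  out <- matrix(0, N, N)
  w0 <- window$start_cM; w1 <- window$end_cM
  width <- w1 - w0
  seg <- seg[seg$chrom == window$chrom, , drop = FALSE]
  union_len <- function(s, e) {
    o <- order(s)
    s <- s[o]; e <- e[o]
    tot <- 0; cur_s <- s[1]; cur_e <- e[1]
    for (k in seq_along(s)[-1]) {
      if (s[k] > cur_e) { tot <- tot + (cur_e - cur_s); cur_s <- s[k]; cur_e <- e[k] }
      else cur_e <- max(cur_e, e[k])
    }
    tot + (cur_e - cur_s)
  }
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    pair <- seg[(seg$id1 == sample_ids[i] & seg$id2 == sample_ids[j]) |
                (seg$id1 == sample_ids[j] & seg$id2 == sample_ids[i]), ,
                drop = FALSE]
    if (nrow(pair) == 0) next
    tot <- 0
    for (h1 in 0:1) for (h2 in 0:1) {
      hp <- pair[(pair$id1 == sample_ids[i] & pair$hap1 == h1 &
                    pair$hap2 == h2) |
                 (pair$id1 == sample_ids[j] & pair$hap1 == h2 &
                    pair$hap2 == h1), , drop = FALSE]
      if (nrow(hp) == 0) next
      s <- pmax(hp$start_cM, w0); e <- pmin(hp$end_cM, w1)
      ok <- e > s
      if (any(ok)) tot <- tot + union_len(s[ok], e[ok]) / width
    }
    out[i, j] <- out[j, i] <- min(tot, 2)
  }
  out
}
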