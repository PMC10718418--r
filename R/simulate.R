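# Synthetic-data generators: IBD-segment cohorts, random sparse local
# matrices, and the null / alternative phenotype models used in the
# calibration and power experiments.

#' Simulation configuration
#'
#' Bundles the cohort and phenotype generative settings.  Defaults describe
#' a modest outbred cohort: three chromosomes, a Poisson number of shared
#' segments per individual and chromosome with shifted-exponential lengths
#' above the caller cutoff, and the phenotype model
#' \eqn{Y = 0.05\,\mathrm{age} + 0.5\,\mathrm{sex} + b + \varepsilon} with
#' \eqn{age \sim N(50, 5^2)}, \eqn{sex \sim \mathrm{Bern}(0.5)},
#' \eqn{b \sim N(0, \Phi_0)} and standard-normal errors.
#'
#' @param N number of individuals.
#' @param chr_lengths_cM named numeric vector of chromosome lengths (cM).
#' @param seg_rate Poisson mean number of shared segments per individual
#'   per chromosome.
#' @param len_min minimum (caller cutoff) segment length in cM.
#' @param len_mean mean segment length in cM (shifted exponential above
#'   \code{len_min}).
#' @param n_families number of planted related clusters (0 for none).
#' @param family_size individuals per cluster.
#' @param family_share fraction of each chromosome shared within a cluster
#'   pair (0.5 gives kinship-like global sharing of 0.5 copies).
#' @param beta_age,beta_sex fixed-effect sizes.
#' @param sigma2_G,sigma2_E variance multipliers of the polygenic
#'   (\eqn{b \sim N(0, \sigma_G^2 \Phi_0)}) and error components.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(N = 1000L,
                       chr_lengths_cM = c(chr1 = 150, chr2 = 120,
                                          chr3 = 100),
                       seg_rate = 5, len_min = 3, len_mean = 5,
                       n_families = 0L, family_size = 3L,
                       family_share = 0.5,
                       beta_age = 0.05, beta_sex = 0.5,
                       sigma2_G = 1, sigma2_E = 1) {
  stopifnot(N >= 2, all(chr_lengths_cM > 0), seg_rate >= 0,
            len_min >= 0, len_mean > len_min || seg_rate == 0,
            sigma2_G >= 0, sigma2_E > 0)
  structure(list(N = as.integer(N), chr_lengths_cM = chr_lengths_cM,
                 seg_rate = seg_rate, len_min = len_min,
                 len_mean = len_mean, n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 family_share = family_share,
                 beta_age = beta_age, beta_sex = beta_sex,
                 sigma2_G = sigma2_G, sigma2_E = sigma2_E),
            class = "sim_config")
}

#' Simulate an IBD-segment cohort
#'
#' For each individual and chromosome a Poisson number of partner
#' haplotypes is drawn; each shared segment has a uniform start on the
#' chromosome and a shifted-exponential length (minimum \code{len_min},
#' mean \code{len_mean}), truncated at the chromosome end.  With
#' \code{n_families > 0}, related clusters are planted in which every pair
#' shares the first \code{family_share} fraction of every chromosome on one
#' haplotype, so the thresholded global matrix has non-trivial blocks.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a list of class \code{ibd_cohort}: \code{segments} (an
#'   \code{ibd_segments} table), \code{sample_ids}, \code{spans} (per
#'   chromosome cM span, usable by [make_window_grid()]) and
#'   \code{config}.
#' @export
simulate_ibd_cohort <- function(config = sim_config(), seed = 1L) {
  N <- config$N
  ids <- sprintf("S%05d", seq_len(N))
  segs <- with_seed(seed, {
    pieces <- list()
    for (ch in names(config$chr_lengths_cM)) {
      Lc <- config$chr_lengths_cM[[ch]]
      n_i <- rpois(N, config$seg_rate)
      tot <- sum(n_i)
      if (tot > 0) {
        i1 <- rep.int(seq_len(N), n_i)
        # partner drawn uniformly among the other N - 1 individuals
        i2 <- sample.int(N - 1L, tot, replace = TRUE)
        i2 <- i2 + (i2 >= i1)
        len <- config$len_min + rexp(tot, 1 / (config$len_mean -
                                                 config$len_min))
        start <- runif(tot, 0, Lc)
        end <- pmin(start + len, Lc)
        ok <- (end - start) >= config$len_min
        pieces[[length(pieces) + 1L]] <- data.frame(
          id1 = ids[i1[ok]], hap1 = sample(0:1, sum(ok), replace = TRUE),
          id2 = ids[i2[ok]], hap2 = sample(0:1, sum(ok), replace = TRUE),
          chrom = ch, start_cM = start[ok], end_cM = end[ok],
          stringsAsFactors = FALSE)
      }
    }
    if (config$n_families > 0L) {
      fam_members <- matrix(
        sample.int(N, config$n_families * config$family_size),
        nrow = config$n_families)
      for (f in seq_len(config$n_families)) {
        mem <- fam_members[f, ]
        prs <- utils::combn(mem, 2L)
        for (ch in names(config$chr_lengths_cM)) {
          Lc <- config$chr_lengths_cM[[ch]]
          pieces[[length(pieces) + 1L]] <- data.frame(
            id1 = ids[prs[1L, ]], hap1 = 0L,
            id2 = ids[prs[2L, ]], hap2 = 0L,
            chrom = ch, start_cM = 0,
            end_cM = config$family_share * Lc,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(pieces) == 0L)
      data.frame(id1 = character(0), hap1 = integer(0),
                 id2 = character(0), hap2 = integer(0),
                 chrom = character(0), start_cM = numeric(0),
                 end_cM = numeric(0), stringsAsFactors = FALSE)
    else do.call(rbind, pieces)
  })
  seg_tab <- if (nrow(segs)) ibd_segments(segs) else {
    class(segs) <- c("ibd_segments", "data.frame"); segs
  }
  spans <- data.frame(chrom = names(config$chr_lengths_cM),
                      start_cM = 0,
                      end_cM = as.numeric(config$chr_lengths_cM),
                      stringsAsFactors = FALSE)
  structure(list(segments = seg_tab, sample_ids = ids, spans = spans,
                 config = config, seed = seed),
            class = "ibd_cohort")
}

#' @export
print.ibd_cohort <- function(x, ...) {
  cat(sprintf("IBD cohort: N = %d, %d segment(s), %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$segments), nrow(x$spans)))
  invisible(x)
}

#' Simulate a random sparse local IBD matrix
#'
#' Uniformly sampled distinct unordered pairs receive sharing values drawn
#' from Uniform(0, 2); the matrix is symmetric with zero diagonal and
#' exactly \code{nnz_offdiag} non-zero off-diagonal elements.
#'
#' @param N dimension.
#' @param nnz_offdiag even number of non-zero off-diagonal elements
#'   (\code{nnz_offdiag / 2} unordered pairs).
#' @param seed integer seed.
#' @param window_id id stamped on the result.
#' @return a [local_ibd-class] matrix of width 1 cM.
#' @export
simulate_sparse_psi <- function(N, nnz_offdiag, seed = 1L, window_id = 0L) {
  stopifnot(nnz_offdiag %% 2 == 0, nnz_offdiag >= 0,
            nnz_offdiag <= N * (N - 1))
  m <- nnz_offdiag / 2
  if (m == 0)
    return(.local_ibd(sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(N, N),
                                   symmetric = TRUE),
                      window_id, 1, sprintf("S%05d", seq_len(N))))
  with_seed(seed, {
    # rejection sampling of distinct unordered pairs; collisions are rare
    # in the sparse regime so a few top-up rounds suffice
    key <- character(0); ii <- integer(0); jj <- integer(0)
    while (length(ii) < m) {
      need <- ceiling((m - length(ii)) * 1.2) + 8L
      a <- sample.int(N, need, replace = TRUE)
      b <- sample.int(N, need, replace = TRUE)
      keep <- a != b
      lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
      k <- paste(lo, hi)
      new <- !duplicated(k) & !(k %in% key)
      ii <- c(ii, lo[new]); jj <- c(jj, hi[new]); key <- c(key, k[new])
    }
    ii <- ii[seq_len(m)]; jj <- jj[seq_len(m)]
    x <- runif(m, 0, 2)
    .local_ibd(sparseMatrix(i = ii, j = jj, x = x, dims = c(N, N),
                            symmetric = TRUE),
               window_id, 1, sprintf("S%05d", seq_len(N)))
  })
}

#' Simulate covariates and a null phenotype
#'
#' Draws age ~ N(50, 5^2), sex ~ Bernoulli(0.5), the polygenic effect
#' \eqn{b \sim N(0, \sigma_G^2 \Phi_0)} through the per-block square root
#' of \eqn{\Phi_0}, and standard-normal errors, and assembles
#' \eqn{Y = 0.05\,age + 0.5\,sex + b + \varepsilon} (coefficients from the
#' config).
#'
#' @param phi0 a [global_ibd-class] covariance of the polygenic effect.
#' @param config a [sim_config()] (effect sizes and variance multipliers).
#' @param seed integer seed.
#' @param eigen_cache optional [kinship_eigen()] of \code{phi0}, reused
#'   across replicates.
#' @return a data frame \code{id, y, age, sex} with the polygenic and
#'   error draws attached as attributes \code{b} and \code{eps}.
#' @export
simulate_phenotype_null <- function(phi0, config = sim_config(),
                                    seed = 1L, eigen_cache = NULL) {
  N <- nrow(phi0)
  be <- eigen_cache %||% kinship_eigen(phi0)
  with_seed(seed, {
    age <- rnorm(N, 50, 5)
    sex <- rbinom(N, 1, 0.5)
    b <- sqrt(config$sigma2_G) *
      as.numeric(be$U %*% (sqrt(pmax(be$d, 0)) *
                             as.numeric(crossprod(be$U, rnorm(N)))))
    eps <- rnorm(N, 0, sqrt(config$sigma2_E))
    y <- config$beta_age * age + config$beta_sex * sex + b + eps
    ids <- if (is(phi0, "global_ibd")) phi0@sample_ids
           else paste0("S", seq_len(N))
    structure(data.frame(id = ids, y = y, age = age, sex = sex,
                         stringsAsFactors = FALSE),
              b = b, eps = eps)
  })
}

#' Add a local IBD random effect to a phenotype
#'
#' Plants \eqn{\delta_l \sim N(0, \sigma_l^2 \Psi_l)} (with
#' \eqn{\Psi_l = \tilde\Psi_l + 2I}) on top of an existing phenotype,
#' the alternative of the per-window variance-component test.
#'
#' @param pheno data frame from [simulate_phenotype_null()].
#' @param psi the window's [local_ibd-class] matrix.
#' @param sigma2_l local variance component.
#' @param seed integer seed.
#' @param sqrt_cache a [local_effect_factor()] of \code{psi}, reused across
#'   replicate draws on the same window.
#' @return the phenotype data frame with \code{y} updated.
#' @export
add_local_effect <- function(pheno, psi, sigma2_l, seed = 1L,
                             sqrt_cache = NULL) {
  N <- nrow(pheno)
  stopifnot(nrow(psi) == N)
  fac <- sqrt_cache %||% local_effect_factor(psi)
  delta <- with_seed(seed, {
    z <- rnorm(N)
    sqrt(sigma2_l) *
      as.numeric(fac$U %*% (sqrt(pmax(fac$d, 0)) *
                              as.numeric(crossprod(fac$U, z))))
  })
  pheno$y <- pheno$y + delta
  pheno
}

#' Square-root factor of a local IBD covariance
#'
#' Per-component eigendecomposition of \eqn{\Psi_l = \tilde\Psi_l + 2I}
#' with negative modes clipped to zero (caller-derived sharing matrices
#' need not be positive semi-definite; the positive part defines the
#' planted-effect covariance).
#'
#' @param psi a [local_ibd-class] matrix.
#' @return \code{list(U, d)} for [add_local_effect()].
#' @export
local_effect_factor <- function(psi) {
  N <- nrow(psi)
  psi_full <- .as_dsc(as(psi, "dsCMatrix") + 2 * Diagonal(N))
  g <- .add_blocks(new("global_ibd", drop0(psi_full),
                       sample_ids = paste0("S", seq_len(N)),
                       threshold = 0))
  .block_eigen(g)
}

#' Simulate window-placed genotypes with known allele frequencies
#'
#' Dosages are Binomial(2, MAF) with MAFs log-uniform over
#' \code{maf_range}; each variant is placed uniformly inside a window of
#' the grid (bp positions use a 1 cM = 1 Mb convention).
#'
#' @param N individuals.
#' @param grid a [make_window_grid()] result.
#' @param n_variants number of variants.
#' @param maf_range length-2 range of minor allele frequencies.
#' @param seed integer seed.
#' @return list with \code{G} (sparse N x M dosage matrix) and \code{info}
#'   (data frame \code{id, chrom, cM, bp, maf, window_id}).
#' @export
simulate_genotypes <- function(N, grid, n_variants = 200L,
                               maf_range = c(1e-4, 0.01), seed = 1L) {
  with_seed(seed, {
    win <- sample.int(nrow(grid), n_variants, replace = TRUE)
    u <- runif(n_variants)
    cM <- grid$start_cM[win] + u * (grid$end_cM[win] - grid$start_cM[win])
    maf <- exp(runif(n_variants, log(maf_range[1]), log(maf_range[2])))
    dos <- lapply(seq_len(n_variants), function(j) rbinom(N, 2, maf[j]))
    nz <- lapply(seq_len(n_variants), function(j) which(dos[[j]] > 0))
    G <- sparseMatrix(i = unlist(nz),
                      j = rep.int(seq_len(n_variants),
                                  lengths(nz)),
                      x = unlist(lapply(seq_len(n_variants),
                                        function(j) dos[[j]][nz[[j]]])),
                      dims = c(N, n_variants))
    info <- data.frame(id = sprintf("V%05d", seq_len(n_variants)),
                       chrom = grid$chrom[win], cM = cM,
                       bp = round(cM * 1e6), maf = maf,
                       window_id = grid$window_id[win],
                       stringsAsFactors = FALSE)
    list(G = G, info = info)
  })
}

#' Rare-variant alternative phenotype
#'
#' Selects a window with at least two ultra-rare variants (MAF below
#' \code{maf_cut}), declares all of them causal, and adds
#' \eqn{\sum_j G_{ij}\beta_j} with
#' \eqn{\beta_j = \mathrm{scale} / \sqrt{2\,\mathrm{MAF}_j
#' (1 - \mathrm{MAF}_j)}} (each causal variant contributes
#' \code{scale^2} variance per standardized dosage unit) to a null
#' phenotype.
#'
#' @param pheno data frame from [simulate_phenotype_null()].
#' @param genotypes a [simulate_genotypes()] result.
#' @param maf_cut causal MAF cutoff (default 5e-4).
#' @param scale effect-size scale (default 0.02).
#' @param seed seed for the causal-window draw.
#' @return list: \code{pheno} (updated), \code{causal_window},
#'   \code{causal_variants}, \code{beta}.
#' @export
simulate_phenotype_rare_variants <- function(pheno, genotypes,
                                             maf_cut = 5e-4, scale = 0.02,
                                             seed = 1L) {
  info <- genotypes$info
  eligible <- info$maf < maf_cut
  tab <- table(info$window_id[eligible])
  wins <- as.integer(names(tab)[tab >= 2L])
  if (length(wins) == 0L)
    stop("no window carries >= 2 variants below the MAF cutoff")
  win <- with_seed(seed, wins[sample.int(length(wins), 1L)])
  idx <- which(eligible & info$window_id == win)
  maf <- info$maf[idx]
  beta <- scale / sqrt(2 * maf * (1 - maf))
  pheno$y <- pheno$y + as.numeric(genotypes$G[, idx, drop = FALSE] %*% beta)
  list(pheno = pheno, causal_window = win,
       causal_variants = info$id[idx], beta = beta)
}

#' Haplotype-effect alternative phenotype
#'
#' Adds \eqn{H_i \gamma} with \eqn{\gamma = \mathrm{scale} /
#' \sqrt{\mathrm{Var}(H)}} for carrier counts \eqn{H \in \{0, 1, 2\}}.
#'
#' @param pheno data frame from [simulate_phenotype_null()].
#' @param H integer carrier counts (0/1/2) aligned to \code{pheno}.
#' @param scale effect-size scale (default 0.02).
#' @return list: \code{pheno} (updated), \code{gamma}.
#' @export
simulate_phenotype_haplotype <- function(pheno, H, scale = 0.02) {
  stopifnot(length(H) == nrow(pheno), all(H %in% 0:2))
  vh <- var(H)
  if (vh == 0) stop("constant carrier count H")
  gamma <- scale / sqrt(vh)
  pheno$y <- pheno$y + H * gamma
  list(pheno = pheno, gamma = gamma)
}

#' Plant a shared causal haplotype in a cohort
#'
#' Chooses carriers, gives each one copy of a shared haplotype spanning
#' \code{[start_cM, end_cM)} on \code{chrom}, and adds the implied pairwise
#' IBD segments (every carrier pair shares the interval) to the cohort.
#'
#' @param cohort an [simulate_ibd_cohort()] result.
#' @param chrom,start_cM,end_cM the haplotype interval.
#' @param n_carriers number of carriers.
#' @param seed integer seed.
#' @return list: \code{cohort} (with segments added), \code{H} (carrier
#'   counts), \code{carriers}.
#' @export
plant_causal_haplotype <- function(cohort, chrom, start_cM, end_cM,
                                   n_carriers, seed = 1L) {
  N <- length(cohort$sample_ids)
  stopifnot(n_carriers >= 2L, n_carriers <= N)
  carriers <- with_seed(seed, sort(sample.int(N, n_carriers)))
  prs <- utils::combn(carriers, 2L)
  add <- data.frame(id1 = cohort$sample_ids[prs[1L, ]], hap1 = 0L,
                    id2 = cohort$sample_ids[prs[2L, ]], hap2 = 0L,
                    chrom = chrom, start_cM = start_cM, end_cM = end_cM,
                    stringsAsFactors = FALSE)
  keep <- intersect(c("id1", "hap1", "id2", "hap2", "chrom",
                      "start_cM", "end_cM"), names(cohort$segments))
  cohort$segments <- ibd_segments(
    rbind(as.data.frame(cohort$segments)[keep], add))
  H <- integer(N); H[carriers] <- 1L
  list(cohort = cohort, H = H, carriers = carriers)
}

#' Causal-window assignment for a planted haplotype
#'
#' Maps a causal haplotype interval to the window scored as "causal": a
#' haplotype inside a single window maps to that window; one spanning two
#' windows maps to the window with the larger overlap; one spanning more
#' than two maps to the first window it covers completely.
#'
#' @param chrom,start_cM,end_cM the haplotype interval.
#' @param grid a [make_window_grid()] result.
#' @return the \code{window_id} of the causal window.
#' @export
assign_causal_window <- function(chrom, start_cM, end_cM, grid) {
  g <- grid[grid$chrom == chrom, , drop = FALSE]
  ov <- pmin(g$end_cM, end_cM) - pmax(g$start_cM, start_cM)
  hit <- which(ov > 0)
  if (length(hit) == 0L) stop("haplotype does not overlap the grid")
  if (length(hit) == 1L) return(g$window_id[hit])
  if (length(hit) == 2L) return(g$window_id[hit[which.max(ov[hit])]])
  covered <- hit[g$start_cM[hit] >= start_cM & g$end_cM[hit] <= end_cM]
  if (length(covered)) return(g$window_id[covered[1L]])
  g$window_id[hit[which.max(ov[hit])]]
}

#' Empirical power / type-I-error estimate
#'
#' @param p vector of p-values from replicate tests.
#' @param threshold significance threshold.
#' @return list with \code{power} (proportion below threshold), \code{se}
#'   (binomial standard error) and \code{n}.
#' @export
estimate_power <- function(p, threshold) {
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0L) return(list(power = NA_real_, se = NA_real_, n = 0L))
  prop <- mean(p < threshold)
  list(power = prop, se = sqrt(prop * (1 - prop) / n), n = n)
}

#' Cross-tabulate two tests' discoveries over replicates
#'
#' Returns the proportions of replicates in which both tests, only the
#' first, only the second, or neither identified the association, with
#' binomial standard errors.
#'
#' @param hit1,hit2 logical vectors over replicates.
#' @return data frame with rows both / only1 / only2 / neither.
#' @export
power_crosstab <- function(hit1, hit2) {
  stopifnot(length(hit1) == length(hit2))
  n <- length(hit1)
  cells <- c(both = mean(hit1 & hit2), only1 = mean(hit1 & !hit2),
             only2 = mean(!hit1 & hit2), neither = mean(!hit1 & !hit2))
  data.frame(cell = names(cells), proportion = as.numeric(cells),
             se = sqrt(cells * (1 - cells) / n), stringsAsFactors = FALSE)
}
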