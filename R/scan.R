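# Genome-wide scan, conditional analysis, and the companion single-variant
# score test.

#' Genome-wide IBD mapping scan
#'
#' Tests every window of the grid for a local IBD variance component
#' (finite-sample p-values by default), flags windows passing the
#' Bonferroni threshold \code{alpha / L} with \code{L} the total number of
#' windows, and reports the genomic inflation factor computed from the
#' observed median p-value,
#' \eqn{\lambda_{GC} = \chi^2_1(1 - \mathrm{median}\ p) /
#' \chi^2_1(0.5)}.
#'
#' @param fit an [ibd_lmm()] null fit.
#' @param locals list of [local_ibd-class] matrices (one per window).
#' @param grid the [make_window_grid()] the matrices were built on.
#' @param bundle an [build_projection()] bundle; built automatically
#'   (\code{B}, \code{seed}) when \code{NULL}.
#' @param mode p-value mode passed to [test_ibd_window()].
#' @param alpha genome-wide significance level (default 0.05).
#' @param B,seed bundle parameters when \code{bundle} is \code{NULL}.
#' @param threads number of worker processes for the (embarrassingly
#'   parallel) per-window loop; results are identical for any value.
#' @return an object of class \code{ibd_scan}: the per-window results data
#'   frame (\code{chrom}, \code{start_cM}, \code{end_cM},
#'   \code{nnz_offdiag}, \code{Q}, \code{p_finite}, \code{p_asymptotic},
#'   \code{method}, \code{skipped}, \code{significant}) with attributes
#'   \code{lambda_gc}, \code{threshold}, \code{alpha} and \code{B}.
#' @export
ibd_scan <- function(fit, locals, grid, bundle = NULL,
                     mode = c("finite", "asymptotic", "both"),
                     alpha = 0.05, B = 100L, seed = 1L, threads = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(locals) == nrow(grid))
  if (is.null(bundle)) bundle <- build_projection(fit, B = B, seed = seed)
  test1 <- function(i) test_ibd_window(fit, locals[[i]], bundle, mode = mode)
  rows <- if (threads > 1L && requireNamespace("parallel", quietly = TRUE))
    parallel::mclapply(seq_along(locals), test1, mc.cores = threads)
  else lapply(seq_along(locals), test1)
  res <- do.call(rbind, rows)
  res <- cbind(grid[c("chrom", "start_cM", "end_cM")], res)
  L <- nrow(grid)
  thr <- alpha / L
  pcol <- if (mode == "asymptotic") res$p_asymptotic else res$p_finite
  res$significant <- !is.na(pcol) & pcol < thr
  p_obs <- pcol[!is.na(pcol)]
  lambda <- if (length(p_obs))
    qchisq(1 - median(p_obs), df = 1) / qchisq(0.5, df = 1)
  else NA_real_
  structure(res, lambda_gc = lambda, threshold = thr, alpha = alpha,
            B = bundle$B, mode = mode,
            class = c("ibd_scan", "data.frame"))
}

#' @export
print.ibd_scan <- function(x, ...) {
  tested <- sum(is.na(x$skipped))
  cat(sprintf(paste0("IBD mapping scan: %d window(s), %d tested,",
                     " %d significant at p < %.3g\n"),
              nrow(x), tested, sum(x$significant, na.rm = TRUE),
              attr(x, "threshold")))
  cat(sprintf("  lambda_GC (median-based) = %.3f, B = %d\n",
              attr(x, "lambda_gc"), attr(x, "B")))
  invisible(x)
}

#' @export
summary.ibd_scan <- function(object, ...) {
  hits <- object[which(object$significant), , drop = FALSE]
  out <- list(n_windows = nrow(object),
              n_tested = sum(is.na(object$skipped)),
              n_skipped = sum(!is.na(object$skipped)),
              threshold = attr(object, "threshold"),
              lambda_gc = attr(object, "lambda_gc"),
              hits = as.data.frame(hits))
  class(out) <- "summary.ibd_scan"
  out
}

#' @export
print.summary.ibd_scan <- function(x, ...) {
  cat(sprintf("Windows: %d (%d tested, %d skipped)\n", x$n_windows,
              x$n_tested, x$n_skipped))
  cat(sprintf("Bonferroni threshold: %.3g; lambda_GC = %.3f\n",
              x$threshold, x$lambda_gc))
  if (nrow(x$hits)) {
    cat("Significant windows:\n")
    print(x$hits[c("chrom", "start_cM", "end_cM", "nnz_offdiag",
                   "p_finite")], row.names = FALSE)
  } else cat("No significant windows.\n")
  invisible(x)
}

#' Plot an IBD mapping scan
#'
#' \code{type = "genome"} draws -log10 p against the cumulative cM
#' position; \code{type = "qq"} draws the quantile-quantile plot against
#' the uniform distribution.
#'
#' @param x an \code{ibd_scan} object.
#' @param type \code{"genome"} or \code{"qq"}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ibd_scan <- function(x, type = c("genome", "qq"), ...) {
  p <- if (attr(x, "mode") == "asymptotic") x$p_asymptotic else x$p_finite
  type <- match.arg(type)
  if (type == "qq") {
    p_obs <- sort(p[!is.na(p)])
    n <- length(p_obs)
    plot(-log10((seq_len(n) - 0.5) / n), -log10(p_obs),
         xlab = "expected -log10(p)", ylab = "observed -log10(p)", ...)
    abline(0, 1, col = "grey50")
    return(invisible(x))
  }
  chrom <- factor(x$chrom, levels = unique(x$chrom))
  offs <- c(0, cumsum(tapply(x$end_cM, chrom, max)))
  pos <- x$start_cM + offs[as.integer(chrom)]
  plot(pos, -log10(p), xlab = "genome position (cM)",
       ylab = "-log10(p)", col = as.integer(chrom) %% 2 + 1, ...)
  abline(h = -log10(attr(x, "threshold")), lty = 2)
  invisible(x)
}

#' Select GWAS tag variants for conditional analysis
#'
#' Restricts single-variant results to suggestive hits (\code{p < p_cut},
#' and MAF/imputation-quality filters when those columns are present)
#' within the window extended by \code{flank_cM} on each side, clumps them
#' into \code{clump_kb} bins anchored at the region's minimum bp, and keeps
#' the most significant variant per bin (ties broken by smaller bp).
#'
#' @param gwas data frame with columns \code{chrom}, \code{bp}, \code{cM},
#'   \code{p} and optionally \code{id}, \code{maf}, \code{rsq}.
#' @param window one-row window (chrom, start_cM, end_cM).
#' @param flank_cM flank width in cM (default 3, matching the minimum IBD
#'   segment length so segments overlapping the window are covered).
#' @param p_cut suggestive threshold (default 1e-6).
#' @param clump_kb clump width in kb (default 100).
#' @param maf_min,rsq_min filters applied when the columns exist.
#' @return the selected rows of \code{gwas} (possibly empty).
#' @export
select_conditional_set <- function(gwas, window, flank_cM = 3,
                                   p_cut = 1e-6, clump_kb = 100,
                                   maf_min = 1e-4, rsq_min = 0.3) {
  lo <- window$start_cM - flank_cM
  hi <- window$end_cM + flank_cM
  keep <- gwas$chrom == as.character(window$chrom) &
    gwas$cM >= lo & gwas$cM < hi & !is.na(gwas$p) & gwas$p < p_cut
  if (!is.null(gwas$maf)) keep <- keep & gwas$maf >= maf_min
  if (!is.null(gwas$rsq)) keep <- keep & gwas$rsq >= rsq_min
  sel <- gwas[keep, , drop = FALSE]
  if (nrow(sel) == 0L) return(sel)
  bin <- floor((sel$bp - min(sel$bp)) / (clump_kb * 1000))
  ord <- order(bin, sel$p, sel$bp)
  sel <- sel[ord, , drop = FALSE]
  out <- sel[!duplicated(bin[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conditional re-test of a window
#'
#' Re-fits the null model with the conditional dosage columns appended to
#' the fixed-effect design (collinear columns dropped with a warning),
#' rebuilds the projection bundle, and re-tests the window.  With an empty
#' conditional set the unconditional model is re-used unchanged.
#'
#' @param fit an [ibd_lmm()] fit.
#' @param psi the window's [local_ibd-class] matrix.
#' @param dosages numeric matrix of conditional covariates aligned to the
#'   fit's samples (or \code{NULL} / zero columns).
#' @param B,seed bundle parameters for the conditional re-test.
#' @param mode p-value mode.
#' @return as [test_ibd_window()], with an extra column
#'   \code{n_conditional}.
#' @export
conditional_test <- function(fit, psi, dosages = NULL, B = 100L,
                             seed = 1L, mode = "finite") {
  if (is.null(dosages) || NCOL(dosages) == 0L) {
    bundle <- build_projection(fit, B = B, seed = seed)
    out <- test_ibd_window(fit, psi, bundle, mode = mode)
    out$n_conditional <- 0L
    return(out)
  }
  dos <- as.matrix(dosages)
  if (is.null(colnames(dos))) colnames(dos) <- paste0("cond", seq_len(ncol(dos)))
  X2 <- cbind(fit$X, dos)
  qrX <- qr(X2)
  if (qrX$rank < ncol(X2)) {
    drop_idx <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop_idx),
            " collinear conditional covariate(s)")
    X2 <- X2[, -drop_idx, drop = FALSE]
  }
  refit <- ibd_lmm_fit(fit$y, X2, fit$kinship, theta_init = fit$theta,
                       eigen_cache = list(U = fit$U, d = fit$d))
  bundle <- build_projection(refit, B = B, seed = seed)
  out <- test_ibd_window(refit, psi, bundle, mode = mode)
  out$n_conditional <- ncol(X2) - ncol(fit$X)
  out
}

#' Single-variant score test under the same null model
#'
#' The GWAS-style companion test: score \eqn{U = g'\hat\Sigma^{-1}(Y -
#' X\hat\beta)} with null variance \eqn{g'\hat P g}, computed through the
#' fit's cached solves (no dense matrix), referred to \eqn{\chi^2_1}.
#'
#' @param fit an [ibd_lmm()] fit.
#' @param g dosage vector aligned to the fit's samples.
#' @return the p-value (\code{NA} for monomorphic / fully
#'   covariate-explained dosages), with attributes \code{score} and
#'   \code{variance}.
#' @export
single_variant_score_test <- function(fit, g) {
  stopifnot(length(g) == fit$N)
  U <- sum(g * fit$residuals) / fit$theta[1]
  v <- sum(g * .proj_apply(fit, g))
  if (v <= 1e-10 * max(sum(g^2), 1))
    return(structure(NA_real_, score = U, variance = v))
  structure(pchisq(U^2 / v, df = 1, lower.tail = FALSE),
            score = U, variance = v)
}
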