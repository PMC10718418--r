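# Per-window variance-component tests.
#
# Asymptotic test: Q_l ~ sum_j zeta_j chi2_1 with zeta the eigenvalues of
# Phat^{1/2} Psi_l Phat^{1/2}.
#
# Finite-sample test: p = P(sum_j xi_j chi2_1 > 0) with xi the eigenvalues
# of Phat^{1/2} (Psi_l - Q_l/(N-c) Sigma) Phat^{1/2}; the subtraction
# absorbs the sampling variability of the residual-variance estimate, and
# the target has trace ~ 0 under the null, so the mixture is evaluated at
# zero with signed weights.
#
# Two routes compute the eigenvalues: the dense-oracle route materializes
# a factor K with K K' = Phat (guarded to moderate N), the projection
# route uses the B x B congruence through the random bundle.

# Dense factor K (N x rank) with K K' = Phat, cached on the fit.
.dense_phat_factor <- function(fit, guard = 20000L) {
  if (fit$N > guard)
    stop("dense-oracle path refused at N = ", fit$N,
         "; use the projection path")
  cache <- fit$cache
  if (!is.null(cache$K)) return(cache)
  W <- 1 / fit$v
  XtW <- fit$Xt * W
  inner <- diag(W) - XtW %*% solve(crossprod(fit$Xt, XtW), t(XtW))
  P <- as.matrix(fit$U %*% inner %*% Matrix::t(fit$U))
  ee <- eigen((P + t(P)) / 2, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-12
  K <- ee$vectors[, pos, drop = FALSE] *
    rep(sqrt(ee$values[pos]), each = fit$N)
  cache$K <- K
  cache$KtSK <- crossprod(K, as.matrix(
    fit$U %*% (fit$v * as.matrix(crossprod(fit$U, K)))))
  cache$KtK <- crossprod(K)
  cache
}

.eig_sym <- function(M) eigen((M + t(M)) / 2, symmetric = TRUE,
                              only.values = TRUE)$values

#' Test one window for a local IBD variance component
#'
#' @param fit an [ibd_lmm()] null fit.
#' @param psi a [local_ibd-class] matrix for the window (zero diagonal).
#' @param bundle an [build_projection()] bundle (projection path) or
#'   \code{NULL} (dense-oracle path).
#' @param path \code{"projection"} (default when a bundle is given) or
#'   \code{"dense"}.
#' @param mode \code{"finite"} (default, recommended), \code{"asymptotic"},
#'   or \code{"both"}.
#' @param rel_tol relative weight-truncation tolerance.
#' @param dense_guard refuse the dense path above this N.
#' @return a one-row data frame with \code{window_id}, \code{nnz_offdiag},
#'   \code{Q}, \code{p_finite}, \code{p_asymptotic}, \code{method} (the
#'   mixture-tail method used), \code{path} and \code{skipped} (reason or
#'   \code{NA}).  Windows with no off-diagonal sharing are skipped: with no
#'   local sharing observed the local variance component is untestable.
#' @export
test_ibd_window <- function(fit, psi, bundle = NULL,
                            path = if (is.null(bundle)) "dense"
                                   else "projection",
                            mode = c("finite", "asymptotic", "both"),
                            rel_tol = 1e-8, dense_guard = 20000L) {
  mode <- match.arg(mode)
  path <- match.arg(path, c("projection", "dense"))
  res <- data.frame(window_id = psi@window_id,
                    nnz_offdiag = psi@nnz_offdiag,
                    Q = NA_real_, p_finite = NA_real_,
                    p_asymptotic = NA_real_,
                    method = NA_character_, path = path,
                    skipped = NA_character_,
                    stringsAsFactors = FALSE)
  if (psi@nnz_offdiag == 0L) {
    res$skipped <- "empty window"
    return(res)
  }
  Q <- score_statistic(fit, psi)
  res$Q <- as.numeric(Q)
  ratio <- as.numeric(Q) / (fit$N - fit$c)

  if (path == "dense") {
    ca <- .dense_phat_factor(fit, guard = dense_guard)
    K <- ca$K
    PsiK <- as.matrix(psi %*% K)
    KtPsiK <- crossprod(K, PsiK) + 2 * ca$KtK
    if (mode %in% c("finite", "both")) {
      wts <- truncate_weights(.eig_sym(KtPsiK - ratio * ca$KtSK), rel_tol)
      p <- mixture_pvalue(wts, 0)
      res$p_finite <- as.numeric(p); res$method <- attr(p, "method")
    }
    if (mode %in% c("asymptotic", "both")) {
      wts <- truncate_weights(.eig_sym(KtPsiK), rel_tol)
      p <- mixture_pvalue(wts, as.numeric(Q))
      res$p_asymptotic <- as.numeric(p)
      if (is.na(res$method)) res$method <- attr(p, "method")
    }
    return(res)
  }

  if (is.null(bundle)) stop("projection path requires a bundle")
  if (!isTRUE(all.equal(bundle$fingerprint, .fit_fingerprint(fit),
                        tolerance = 1e-10)))
    stop("projection bundle was built from a different null fit")

  if (!is.null(bundle$dual)) {
    # B > N: identical non-zero spectrum from the N-side factor of RR'/B
    K <- bundle$dual$K
    PsiK <- as.matrix(psi %*% K)
    KtPsiK <- crossprod(K, PsiK) + 2 * bundle$dual$KtK
    if (mode %in% c("finite", "both")) {
      wts <- truncate_weights(
        .eig_sym(KtPsiK - ratio * bundle$dual$KtSK), rel_tol)
      p <- mixture_pvalue(wts, 0)
      res$p_finite <- as.numeric(p); res$method <- attr(p, "method")
    }
    if (mode %in% c("asymptotic", "both")) {
      wts <- truncate_weights(.eig_sym(KtPsiK), rel_tol)
      p <- mixture_pvalue(wts, as.numeric(Q))
      res$p_asymptotic <- as.numeric(p)
      if (is.na(res$method)) res$method <- attr(p, "method")
    }
    return(res)
  }

  B <- bundle$B
  RtPsiR <- as.matrix(crossprod(bundle$R, psi %*% bundle$R))
  if (mode %in% c("finite", "both")) {
    r <- fit$residuals
    rpsir <- as.numeric(crossprod(r, psi %*% r))
    targ <- (bundle$A + RtPsiR - (rpsir / bundle$rtSr) * bundle$RtSR) / B
    wts <- truncate_weights(.eig_sym(targ), rel_tol)
    p <- mixture_pvalue(wts, 0)
    res$p_finite <- as.numeric(p); res$method <- attr(p, "method")
  }
  if (mode %in% c("asymptotic", "both")) {
    targ <- (2 * bundle$RtR + RtPsiR) / B
    wts <- truncate_weights(.eig_sym(targ), rel_tol)
    p <- mixture_pvalue(wts, as.numeric(Q))
    res$p_asymptotic <- as.numeric(p)
    if (is.na(res$method)) res$method <- attr(p, "method")
  }
  res
}
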