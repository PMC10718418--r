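# Random-projection bundle: B columns distributed N(0, Phat), where Phat is
# the projection matrix of the fitted null model.  Each per-window
# eigenvalue problem is then reduced from N x N to B x B, with per-window
# cost O(nnz(Psi) * B + B^3) and no dense N x N object anywhere.

#' Build the random-projection bundle
#'
#' Columns are i.i.d. draws of \eqn{r_4 \sim N(0, \hat P)} constructed as in
#' the scan algorithm: draw standard-normal \eqn{r_1, r_2}, form
#' \eqn{r_3 = \hat\sigma_E r_1 + \hat\sigma_G L r_2} with \eqn{LL' = \Phi}
#' (per-block symmetric square root), then project
#' \eqn{r_4 = \hat\Sigma^{-1} r_3 - \hat\Sigma^{-1} X (X'\hat\Sigma^{-1}
#' X)^{-1} X'\hat\Sigma^{-1} r_3}.  All solves use the cached block
#' factorization of the null fit, so the construction is linear in N for
#' bounded block size.
#'
#' The bundle precomputes the reusable genome-wide pieces: \eqn{R'R},
#' \eqn{R'\hat\Sigma R}, \eqn{r'r}, \eqn{r'\hat\Sigma r} and the
#' finite-sample offset \eqn{A = 2R'R - (2 r'r / r'\hat\Sigma r)
#' R'\hat\Sigma R}, chosen so that the assembled per-window B x B target is
#' exactly \eqn{R'(\Psi_l - \frac{Q_l}{N-c}\hat\Sigma)R} (see
#' [test_ibd_window()]).  When \code{B > N} a dual N x N factor of
#' \eqn{RR'/B} is cached so eigenvalues are extracted from the smaller
#' side.
#'
#' @param fit an [ibd_lmm()] fit.
#' @param B number of random vectors (default 100).
#' @param seed integer seed; the same seed reproduces the bundle
#'   bit-for-bit, and the caller's RNG state is untouched.
#' @return an object of class \code{ibd_projection}.
#' @export
build_projection <- function(fit, B = 100L, seed = 1L) {
  stopifnot(inherits(fit, "ibd_lmm"), B >= 2L)
  N <- fit$N
  R <- with_seed(seed, {
    R1 <- matrix(rnorm(N * B), N, B)
    R2 <- matrix(rnorm(N * B), N, B)
    LR2 <- fit$U %*% (sqrt(pmax(fit$d, 0)) * as.matrix(crossprod(fit$U, R2)))
    R3 <- sqrt(fit$theta[1]) * R1 + sqrt(fit$theta[2]) * as.matrix(LR2)
    .proj_apply(fit, R3)
  })
  rtr <- fit$rtr; rtSr <- fit$rtSr
  dual <- NULL
  RtR <- RtSR <- A <- NULL
  if (B > N) {
    # the B x B precomputes would be larger than the problem itself;
    # factor RR'/B on the N side instead (identical non-zero spectrum)
    ee <- eigen(tcrossprod(R) / B, symmetric = TRUE)
    pos <- ee$values > max(ee$values) * 1e-12
    K <- ee$vectors[, pos, drop = FALSE] * rep(sqrt(ee$values[pos]),
                                               each = N)
    SK <- as.matrix(fit$U %*% (fit$v * as.matrix(crossprod(fit$U, K))))
    dual <- list(K = K, KtK = crossprod(K), KtSK = crossprod(K, SK))
  } else {
    SR <- as.matrix(fit$U %*% (fit$v * as.matrix(crossprod(fit$U, R))))
    RtR <- crossprod(R)
    RtSR <- crossprod(R, SR)
    A <- 2 * RtR - (2 * rtr / rtSr) * RtSR
  }
  structure(list(R = R, B = as.integer(B), RtR = RtR, RtSR = RtSR,
                 A = A, rtr = rtr, rtSr = rtSr, seed = seed, dual = dual,
                 fingerprint = .fit_fingerprint(fit)),
            class = "ibd_projection")
}

.fit_fingerprint <- function(fit)
  c(fit$N, fit$c, unname(fit$theta), sum(fit$residuals),
    sum(fit$residuals^2))

#' @export
print.ibd_projection <- function(x, ...) {
  cat(sprintf("Random-projection bundle: N = %d, B = %d, seed = %s\n",
              nrow(x$R), x$B, format(x$seed)))
  invisible(x)
}

#' Score statistic of the local IBD variance-component test
#'
#' Computes \eqn{Q_l = (N - c)\, r'\Psi_l r / r'\hat\Sigma r} with
#' \eqn{\Psi_l = \tilde\Psi_l + 2 I} (so \eqn{r'\Psi_l r = r'\tilde\Psi_l r
#' + 2 r'r}).  At the REML solution this equals the
#' \eqn{\hat\sigma_E^{-4}}-scaled form \eqn{r'\Psi_l r / \hat\sigma_E^4};
#' both are computed and the relative discrepancy is attached as a
#' diagnostic.
#'
#' @param fit an [ibd_lmm()] fit.
#' @param psi a [local_ibd-class] matrix (zero diagonal).
#' @return the score statistic, with attribute \code{form_discrepancy}.
#' @export
score_statistic <- function(fit, psi) {
  r <- fit$residuals
  rpsir <- as.numeric(crossprod(r, psi %*% r)) + 2 * fit$rtr
  q_ratio <- (fit$N - fit$c) * rpsir / fit$rtSr
  q_sigma <- rpsir / fit$theta[1]^2
  structure(q_ratio,
            form_discrepancy = abs(q_ratio - q_sigma) / max(q_ratio, 1e-300))
}
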