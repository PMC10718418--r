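# Null linear mixed model  Y = X beta + b + eps,  b ~ N(0, sigmaG^2 Phi),
# eps ~ N(0, sigmaE^2 I), fitted by REML.
#
# Phi is block-diagonal after thresholding, so each connected block is
# eigendecomposed once (Phi = U D U', U block-orthogonal and sparse).  In
# the rotated basis Sigma = sigmaE^2 I + sigmaG^2 Phi is diagonal, making
# every REML trace, determinant and solve exact at O(sum block^3) total
# cost -- linear in N for bounded block size.  The optimizer is
# average-information REML with step-halving and projection onto
# sigmaG^2 >= 0, with an exact restricted-likelihood optim() fallback.

# Per-block eigendecomposition of a global_ibd matrix.
.block_eigen <- function(phi) {
  N <- nrow(phi)
  memb <- phi@blocks
  d <- numeric(N)
  ti <- vector("list", length(phi@block_sizes))
  tj <- vector("list", length(ti)); tx <- vector("list", length(ti))
  idx_by_block <- split(seq_len(N), memb)
  for (k in seq_along(idx_by_block)) {
    idx <- idx_by_block[[k]]
    b <- length(idx)
    if (b == 1L) {
      d[idx] <- phi[idx, idx]
      ti[[k]] <- idx; tj[[k]] <- idx; tx[[k]] <- 1
    } else {
      ee <- eigen(as.matrix(phi[idx, idx]), symmetric = TRUE)
      d[idx] <- ee$values
      ti[[k]] <- rep(idx, times = b)
      tj[[k]] <- rep(idx, each = b)
      tx[[k]] <- as.numeric(ee$vectors)
    }
  }
  U <- sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                    dims = c(N, N))
  list(U = U, d = pmax(d, 0))
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal scores \code{qnorm((rank - 3/8) / (n + 1/4))}
#' (Blom offset); ties receive average ranks.
#'
#' @param y numeric vector without missing values.
#' @return numeric vector of normal scores.
#' @export
rank_normalize <- function(y) {
  if (anyNA(y)) stop("rank_normalize: missing values")
  if (length(unique(y)) < 2L) stop("rank_normalize: constant input")
  qnorm((rank(y, ties.method = "average") - 3 / 8) / (length(y) + 1 / 4))
}

#' Fit the null IBD linear mixed model
#'
#' Fits \eqn{Y = X\beta + b + \varepsilon} with
#' \eqn{b \sim N(0, \sigma_G^2 \Phi)} and i.i.d. errors by restricted
#' maximum likelihood, where \eqn{\Phi} is a (sparse, block-diagonal)
#' global IBD matrix.  This is the null model of the per-window IBD
#' variance-component test: the local random effect is absent and its
#' variance is tested against zero downstream (see [ibd_scan()]).
#'
#' Samples are matched to the kinship matrix by ID (inner join, output
#' order follows the kinship matrix), rows with missing model variables are
#' dropped with a message, and duplicated IDs are an error.
#'
#' With \code{rank_normalize = TRUE} the response is first regressed on the
#' covariates by OLS, the residuals are mapped to normal scores, and the
#' mixed model is then fitted to the normal scores with the same
#' covariates re-included.
#'
#' @param formula model formula, e.g. \code{y ~ age + sex}.
#' @param data data frame with the model variables and an ID column.
#' @param kinship a [global_ibd-class] matrix (or any sparse symmetric
#'   matrix, wrapped via [global_ibd()]).
#' @param id_col name of the sample-ID column in \code{data} (default
#'   \code{"id"}).
#' @param rank_normalize apply the inverse-normal residual workflow first.
#' @param theta_init optional starting values \code{c(sigma2_E, sigma2_G)}.
#' @param maxit maximum AI-REML iterations.
#' @param tol_loglik,tol_theta convergence tolerances on the relative
#'   restricted-likelihood change and absolute parameter change.
#' @return an object of class \code{ibd_lmm} with components including
#'   \code{theta} (\code{sigma2_E}, \code{sigma2_G}), \code{beta},
#'   \code{residuals} (the conditional residual \eqn{r = Y - X\hat\beta -
#'   \hat b}), \code{rtr}, \code{rtSr} \eqn{= r'\hat\Sigma r},
#'   \code{loglik}, convergence diagnostics, and cached solver handles.
#' @seealso [build_projection()], [ibd_scan()], [score_statistic()]
#' @export
ibd_lmm <- function(formula, data, kinship, id_col = "id",
                    rank_normalize = FALSE, theta_init = NULL,
                    maxit = 100L, tol_loglik = 1e-8, tol_theta = 1e-6) {
  if (!is(kinship, "global_ibd")) kinship <- global_ibd(kinship)
  if (!id_col %in% names(data)) stop("no ID column '", id_col, "' in data")
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) stop("duplicated sample IDs in data")

  vars <- all.vars(formula)
  cc <- complete.cases(data[vars])
  if (!all(cc)) {
    message(sprintf("dropping %d sample(s) with missing model variables: %s",
                    sum(!cc), paste(head(ids[!cc], 5L), collapse = ", ")))
    data <- data[cc, , drop = FALSE]; ids <- ids[cc]
  }
  keep <- kinship@sample_ids %in% ids
  if (!all(keep)) {
    kin_idx <- which(keep)
    phi <- kinship[kin_idx, kin_idx]
    kinship <- global_ibd(phi, kinship@sample_ids[kin_idx])
  }
  ord <- match(kinship@sample_ids, ids)
  if (anyNA(ord))
    stop("phenotype data is missing samples present in the kinship matrix")
  data <- data[ord, , drop = FALSE]

  mf <- model.frame(formula, data)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(formula, mf)
  N <- length(y); c_ <- ncol(X)
  if (N < c_ + 2L) stop("fewer than c + 2 complete cases")
  if (qr(X)$rank < c_) stop("covariate matrix is rank-deficient")

  if (rank_normalize) {
    ols <- lm.fit(X, y)
    y <- rank_normalize(ols$residuals)
  }

  be <- .block_eigen(kinship)
  fit <- .reml_fit(y, X, be$U, be$d,
                   theta_init = theta_init, maxit = maxit,
                   tol_loglik = tol_loglik, tol_theta = tol_theta)

  fit$call <- match.call()
  fit$formula <- formula
  fit$sample_ids <- kinship@sample_ids
  fit$kinship <- kinship
  fit$rank_normalized <- rank_normalize
  class(fit) <- "ibd_lmm"
  fit
}

#' Fit the null model from a response vector and design matrix
#'
#' Matrix-level interface to the same REML engine as [ibd_lmm()], for
#' simulation pipelines that already hold \code{y} and \code{X} aligned to
#' the kinship matrix.
#'
#' @param y numeric response vector.
#' @param X design matrix (including the intercept column).
#' @param kinship a [global_ibd-class] matrix aligned to \code{y}.
#' @param eigen_cache optional precomputed block eigendecomposition
#'   (\code{list(U, d)}), reused across replicate fits on the same kinship.
#' @inheritParams ibd_lmm
#' @return an \code{ibd_lmm} object.
#' @export
ibd_lmm_fit <- function(y, X, kinship, theta_init = NULL, maxit = 100L,
                        tol_loglik = 1e-8, tol_theta = 1e-6,
                        eigen_cache = NULL) {
  if (!is(kinship, "global_ibd")) kinship <- global_ibd(kinship)
  stopifnot(length(y) == nrow(kinship), nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  be <- eigen_cache %||% .block_eigen(kinship)
  fit <- .reml_fit(y, X, be$U, be$d, theta_init = theta_init,
                   maxit = maxit, tol_loglik = tol_loglik,
                   tol_theta = tol_theta)
  fit$call <- match.call()
  fit$sample_ids <- kinship@sample_ids
  fit$kinship <- kinship
  fit$rank_normalized <- FALSE
  class(fit) <- "ibd_lmm"
  fit
}

#' Precompute the block eigendecomposition of a kinship matrix
#'
#' @param kinship a [global_ibd-class] matrix.
#' @return \code{list(U, d)} for the \code{eigen_cache} argument of
#'   [ibd_lmm_fit()].
#' @export
kinship_eigen <- function(kinship) {
  if (!is(kinship, "global_ibd")) kinship <- global_ibd(kinship)
  .block_eigen(kinship)
}

# Core REML engine in the rotated basis (yt = U'y, Xt = U'X, v = t1 + t2 d).
.reml_fit <- function(y, X, U, d, theta_init = NULL, maxit = 100L,
                      tol_loglik = 1e-8, tol_theta = 1e-6) {
  N <- length(y); c_ <- ncol(X)
  yt <- as.numeric(crossprod(U, y))
  Xt <- as.matrix(crossprod(U, X))
  vy <- var(y)
  lb1 <- 1e-8 * vy

  pieces <- function(th) {
    v <- th[1] + th[2] * d
    w <- 1 / v
    XtW <- Xt * w
    XWX <- crossprod(Xt, XtW)
    ch <- chol(XWX)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
    resid <- yt - drop(Xt %*% beta)
    u <- resid * w
    rss <- sum(resid * u)
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + rss)
    list(v = v, w = w, XtW = XtW, ch = ch, beta = drop(beta), u = u,
         rss = rss, ll = ll)
  }
  Pfun <- function(pz, z) {
    wz <- z * pz$w
    wz - pz$XtW %*% backsolve(pz$ch, forwardsolve(t(pz$ch),
                                                  crossprod(pz$XtW, z)))
  }
  score_ai <- function(pz) {
    # tr(P A) = tr(V^-1 A) - tr((X'WX)^-1 X'W A W X)
    inv_diag <- function(a) {
      S <- backsolve(pz$ch, forwardsolve(t(pz$ch),
                                         crossprod(pz$XtW, pz$XtW * a)))
      sum(pz$w * a) - sum(diag(as.matrix(S)))
    }
    trP1 <- inv_diag(rep(1, N)); trPd <- inv_diag(d)
    u <- pz$u
    sc <- -0.5 * c(trP1 - sum(u * u), trPd - sum(d * u * u))
    a1 <- u; a2 <- d * u
    p1 <- drop(Pfun(pz, a1)); p2 <- drop(Pfun(pz, a2))
    AI <- 0.5 * matrix(c(sum(a1 * p1), sum(a1 * p2),
                         sum(a2 * p1), sum(a2 * p2)), 2, 2)
    list(score = sc, AI = AI)
  }

  th <- theta_init %||% c(vy / 2, vy / 2)
  th <- pmax(th, c(lb1, 0))
  pz <- pieces(th)
  conv <- FALSE; it <- 0L; gnorm <- NA_real_
  for (it in seq_len(maxit)) {
    sa <- score_ai(pz)
    gnorm <- sqrt(sum(sa$score^2))
    step <- tryCatch(solve(sa$AI + diag(1e-10, 2), sa$score),
                     error = function(e) sa$score / max(1, gnorm))
    ok <- FALSE
    for (h in 0:12) {
      th_new <- pmax(th + step / 2^h, c(lb1, 0))
      pz_new <- pieces(th_new)
      if (is.finite(pz_new$ll) && pz_new$ll >= pz$ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    dll <- pz_new$ll - pz$ll
    dth <- max(abs(th_new - th))
    th <- th_new; pz <- pz_new
    if (abs(dll) < tol_loglik * (abs(pz$ll) + 1) && dth < tol_theta) {
      conv <- TRUE; break
    }
  }
  if (!conv) {
    # exact restricted likelihood as a safety net (boundary-friendly)
    opt <- optim(th, function(t2) -pieces(pmax(t2, c(lb1, 0)))$ll,
                 method = "L-BFGS-B", lower = c(lb1, 0),
                 control = list(maxit = 200))
    th <- pmax(opt$par, c(lb1, 0))
    pz <- pieces(th)
    sa <- score_ai(pz)
    gnorm <- sqrt(sum(sa$score^2))
    conv <- opt$convergence == 0 ||
      gnorm < 1e-4 * (abs(pz$ll) + 1)
  }
  if (!conv)
    warning("REML did not fully converge (gradient norm ",
            format(gnorm, digits = 3), ")")

  u <- pz$u                       # rotated P y = V^-1 (y - X beta)
  r <- th[1] * as.numeric(U %*% u)    # conditional residual y - Xb - bhat
  bhat <- as.numeric(U %*% (th[2] * d * u))
  rtSr <- th[1]^2 * sum(pz$v * u^2)
  beta <- pz$beta; names(beta) <- colnames(X)
  list(theta = c(sigma2_E = th[1], sigma2_G = th[2]),
       beta = beta,
       residuals = r, b_hat = bhat, fitted = drop(X %*% beta) + bhat,
       y = y, X = X, U = U, d = d, v = pz$v, u = u,
       yt = yt, Xt = Xt,
       rtr = sum(r^2), rtSr = rtSr, yPy = pz$rss,
       N = N, c = c_, loglik = pz$ll,
       iterations = it, gradient_norm = gnorm, converged = conv,
       boundary = th[2] <= 0,
       cache = new.env(parent = emptyenv()))
}

# Sigma^-1 z through the cached eigenbasis.
.sigma_solve <- function(fit, z) {
  as.numeric(fit$U %*% (as.numeric(crossprod(fit$U, z)) / fit$v))
}
# Projection P z = Sigma^-1 z - Sigma^-1 X (X' Sigma^-1 X)^-1 X' Sigma^-1 z,
# operating in the rotated basis; z in original coordinates.
.proj_apply <- function(fit, z) {
  zt <- as.matrix(crossprod(fit$U, z))
  wz <- zt / fit$v
  XtW <- fit$Xt / fit$v
  XWX <- crossprod(fit$Xt, XtW)
  out <- wz - XtW %*% solve(XWX, crossprod(fit$Xt, wz))
  as.matrix(fit$U %*% out)
}

#' @export
print.ibd_lmm <- function(x, ...) {
  cat("IBD null linear mixed model (REML)\n")
  cat(sprintf("  N = %d, covariates = %d%s\n", x$N, x$c,
              if (x$rank_normalized) ", response rank-normalized" else ""))
  cat(sprintf("  sigma2_E = %.4f, sigma2_G = %.4f%s\n",
              x$theta[1], x$theta[2],
              if (x$boundary) " (at boundary)" else ""))
  cat(sprintf("  REML log-likelihood %.3f after %d iteration(s)\n",
              x$loglik, x$iterations))
  invisible(x)
}

#' @export
coef.ibd_lmm <- function(object, ...) object$beta

#' @export
residuals.ibd_lmm <- function(object, ...) object$residuals

#' @export
fitted.ibd_lmm <- function(object, ...) object$fitted

#' @export
logLik.ibd_lmm <- function(object, ...) {
  structure(object$loglik, df = object$c + 2L, class = "logLik")
}

#' @export
summary.ibd_lmm <- function(object, ...) {
  XWX <- crossprod(object$Xt, object$Xt / object$v)
  se <- sqrt(diag(solve(XWX)))
  coefs <- cbind(Estimate = object$beta, `Std. Error` = se,
                 `z value` = object$beta / se,
                 `Pr(>|z|)` = 2 * pnorm(-abs(object$beta / se)))
  out <- list(coefficients = coefs, theta = object$theta,
              N = object$N, loglik = object$loglik,
              converged = object$converged, boundary = object$boundary)
  class(out) <- "summary.ibd_lmm"
  out
}

#' @export
print.summary.ibd_lmm <- function(x, ...) {
  cat("IBD null linear mixed model (REML)\n\nFixed effects:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nVariance components: sigma2_E = %.4f, sigma2_G = %.4f\n",
              x$theta[1], x$theta[2]))
  cat(sprintf("N = %d, REML log-likelihood %.3f\n", x$N, x$loglik))
  invisible(x)
}

#' Simulate responses from a fitted null model
#'
#' Draws new phenotype vectors from the fitted null law
#' \eqn{N(X\hat\beta,\; \hat\sigma_E^2 I + \hat\sigma_G^2 \Phi)}.
#'
#' @param object an \code{ibd_lmm} fit.
#' @param nsim number of replicates.
#' @param seed optional seed (RNG state is restored on exit).
#' @param ... unused.
#' @return a data frame with \code{nsim} columns.
#' @export
simulate.ibd_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    z1 <- rnorm(object$N); z2 <- rnorm(object$N)
    b <- as.numeric(object$U %*% (sqrt(pmax(object$d, 0)) *
                                    as.numeric(crossprod(object$U, z2))))
    # U diag(sqrt d) U' z ~ N(0, Phi); scaled by the fitted components
    drop(object$X %*% object$beta) +
      sqrt(object$theta[2]) * b + sqrt(object$theta[1]) * z1
  }
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
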