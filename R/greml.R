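#' SNP heritability by average-information REML
#'
#' Fits `y = X b + g + e` with `g ~ N(0, A sigma2_g)`, `e ~ N(0, I sigma2_e)`
#' by restricted maximum likelihood.  Updates use the average-information (AI)
#' algorithm with an EM step as fallback whenever an AI step would leave the
#' parameter space or decrease the restricted likelihood; variance components
#' are clamped at 1e-8.  Standard errors come from the inverse AI matrix at
#' convergence, and the SE of `h2 = sigma2_g / (sigma2_g + sigma2_e)` by the
#' delta method.  The GRM is eigendecomposed once, making each iteration
#' O(n^2).
#'
#' @param y numeric phenotype vector.
#' @param covariates data.frame of fixed-effect covariates (or `NULL` for
#'   intercept only).
#' @param grm a [compute_grm()] result (or bare symmetric matrix).
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence: absolute change in restricted log-likelihood below
#'   `tol` (default 1e-6).
#' @return object of class `greml_fit` with `sigma2_g`, `sigma2_e`, `h2`,
#'   `se` (named vector for the components and h2), `loglik`, `converged`,
#'   `n_iter`, `n`, `weakly_identified`.
#' @export
greml <- function(y, covariates = NULL, grm, max_iter = 100L, tol = 1e-6) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(A) == n)
  X <- covariate_matrix(if (is.null(covariates)) NULL else as.data.frame(covariates), n)
  if (qr(X)$rank < ncol(X)) stop("covariates are rank deficient", call. = FALSE)
  eg <- eigen(A, symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, 0)
  if (max(abs(d - mean(d))) < 1e-8) {
    warning("h2 weakly identified: GRM is numerically proportional to identity")
  }
  yt <- crossprod(U, y)      # rotated data: cov = diag(sg*d + se)
  Xt <- crossprod(U, X)
  vy <- stats::var(y)
  theta <- c(g = vy / 2, e = vy / 2)  # starting values: equal split
  clamp <- 1e-8 * vy
  reml_ll <- function(th) {
    v <- th[1] * d + th[2]
    if (any(v <= 0)) return(-Inf)
    vinv <- 1 / v
    XtVX <- crossprod(Xt, Xt * vinv)
    cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cXtVX)) return(-Inf)
    beta <- backsolve(cXtVX, forwardsolve(t(cXtVX), crossprod(Xt, yt * vinv)))
    r <- yt - Xt %*% beta
    -0.5 * (sum(log(v)) + 2 * sum(log(diag(cXtVX))) + sum(r^2 * vinv))
  }
  # P y and the traces needed by AI/EM, all in the rotated basis
  parts <- function(th) {
    v <- th[1] * d + th[2]
    vinv <- 1 / v
    XtVX <- crossprod(Xt, Xt * vinv)
    XtVXi <- solve(XtVX)
    Py <- vinv * (yt - Xt %*% (XtVXi %*% crossprod(Xt, yt * vinv)))
    # tr(P D) for D = diag(d) (GRM term) and D = I (residual term):
    # tr(P D) = sum(dg * vinv) - tr(XtVXi * Xt' diag(dg*vinv^2) Xt)
    trP <- function(dg) {
      sum(dg * vinv) - sum(XtVXi * crossprod(Xt, Xt * (dg * vinv^2)))
    }
    list(Py = Py, vinv = vinv, XtVXi = XtVXi,
         trPA = trP(d), trPI = trP(rep(1, n)))
  }
  ll <- reml_ll(theta)
  converged <- FALSE
  iter <- 0L
  ai_mat <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    pp <- parts(theta)
    Py <- drop(pp$Py)
    APy <- d * Py
    # P applied again (for AI entries): P z = vinv z - vinv X (X'V^-1X)^-1 X' vinv z
    Pz <- function(z) {
      drop(pp$vinv * (z - Xt %*% (pp$XtVXi %*% crossprod(Xt, pp$vinv * z))))
    }
    PAPy <- Pz(APy); PPy <- Pz(Py)
    # score: dl/dθ_k = -0.5 (tr(P D_k) - y'P D_k P y)
    score <- -0.5 * c(pp$trPA - sum(Py * APy), pp$trPI - sum(Py * Py))
    ai <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                         sum(APy * PPy), sum(Py * PPy)), 2, 2)
    step <- tryCatch(solve(ai, score), error = function(e) NULL)
    new_theta <- if (!is.null(step)) pmax(theta + step, clamp) else NULL
    new_ll <- if (!is.null(new_theta)) reml_ll(new_theta) else -Inf
    if (!is.finite(new_ll) || new_ll < ll - 1e-10) {
      # EM fallback: θ_k' = (θ_k^2 (y'P D_k P y - tr(P D_k)) ) / n + θ_k
      em <- c(theta[1] + theta[1]^2 * (sum(Py * APy) - pp$trPA) / n,
              theta[2] + theta[2]^2 * (sum(Py * Py) - pp$trPI) / n)
      new_theta <- pmax(em, clamp)
      new_ll <- reml_ll(new_theta)
    }
    if (is.finite(new_ll) && abs(new_ll - ll) < tol) {
      theta <- new_theta; ll <- new_ll; ai_mat <- ai; converged <- TRUE
      break
    }
    theta <- new_theta; ll <- new_ll; ai_mat <- ai
  }
  se <- c(g = NA_real_, e = NA_real_, h2 = NA_real_)
  if (!is.null(ai_mat)) {
    cov_theta <- tryCatch(solve(ai_mat), error = function(e) NULL)
    if (!is.null(cov_theta) && all(diag(cov_theta) > 0)) {
      se["g"] <- sqrt(cov_theta[1, 1]); se["e"] <- sqrt(cov_theta[2, 2])
      s <- sum(theta)
      grad <- c(theta[2], -theta[1]) / s^2  # d h2 / d (sg, se)
      vh2 <- drop(t(grad) %*% cov_theta %*% grad)
      if (vh2 > 0) se["h2"] <- sqrt(vh2)
    }
  }
  structure(list(sigma2_g = unname(theta[1]), sigma2_e = unname(theta[2]),
                 h2 = unname(theta[1] / sum(theta)), se = se,
                 loglik = ll, converged = converged, n_iter = iter, n = n,
                 weakly_identified = max(abs(d - mean(d))) < 1e-8),
            class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("GREML fit (n = %d): h2 = %.3f (SE %.3f)%s\n", x$n, x$h2,
              x$se["h2"], if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  sigma2_g = %.4g (SE %.3g), sigma2_e = %.4g (SE %.3g), logLik = %.3f, %d iter\n",
              x$sigma2_g, x$se["g"], x$sigma2_e, x$se["e"], x$loglik, x$n_iter))
  invisible(x)
}

#' @export
summary.greml_fit <- function(object, ...) {
  print(object)
  invisible(object)
}
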