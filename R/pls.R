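## Partial least squares regression (single response, NIPALS).
##
## The five CIELab/Ch colour parameters (L*, a*, b*, C*, h) are strongly
## multicollinear by construction: C* and h are derived from a* and b*.
## Ordinary least squares coefficients are unstable under such collinearity
## (and fail outright when the derivation becomes exact).  PLS extracts
## latent components that maximise the covariance between the standardized
## predictors and the response, which keeps the fit well-defined and the
## component weights interpretable.  With as many components as the
## predictor rank, PLS reproduces the least-squares solution exactly --
## a closed-form limit used as an internal consistency check.

#' Fit a partial least squares regression on colour predictors
#'
#' Single-response PLS by the NIPALS algorithm.  Both predictors and
#' response are z-score standardized before component extraction (so that
#' high-variance colour parameters do not dominate the leading components);
#' final coefficients are back-transformed to the original units, including
#' an intercept, so the model can be written in the same form as a printed
#' prediction equation.  Fitting is deterministic: there is no randomness
#' in the algorithm.
#'
#' @param x Predictor matrix (samples x predictors, typically the five
#'   colour parameters), a data frame, or a formula.
#' @param ... Passed between methods.
#' @return An object of class `carot_pls` with components `ncomp`,
#'   `x_mean`, `x_sd`, `y_mean`, `y_sd`, `weights`, `x_loadings`,
#'   `y_loadings`, `coef_std` (standardized scale),
#'   `coefficients_original_scale` (named vector, `(Intercept)` first),
#'   `scores`, `fitted.values`, `residuals`, `r2_pearson` (squared Pearson
#'   correlation of fitted vs observed), `r2_ss` (1 - SSE/SST), `rmse_cal`
#'   and `rmse_cal_pct` (calibration RMSE, absolute and relative to the
#'   mean observed response).
#' @export
#' @examples
#' X <- matrix(rnorm(150), 30, 5,
#'             dimnames = list(NULL, c("L_star","a_star","b_star",
#'                                     "C_star","h_deg")))
#' y <- X %*% c(1, -2, 0.5, 0, 1) + rnorm(30, 0, 0.1)
#' fit <- fit_pls(X, y)
#' coef(fit)
fit_pls <- function(x, ...) UseMethod("fit_pls")

#' @rdname fit_pls
#' @param data Data frame holding the variables of the formula.
#' @export
fit_pls.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(x, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  out <- fit_pls.default(X, y, ...)
  out$call <- match.call()
  out
}

#' @rdname fit_pls
#' @param y Numeric response vector.
#' @param ncomp Number of latent components (default 5, the number of
#'   colour predictors; values above 5 are rejected).
#' @export
fit_pls.default <- function(x, y, ncomp = 5L, ...) {
  X <- as.matrix(x)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("x and y dimensions do not match")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (ncomp > 5L) stop("at most 5 latent components are supported")
  if (ncomp > p) stop("ncomp cannot exceed the number of predictors")
  if (n <= ncomp) stop("need more samples than components")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[x_sd == 0], collapse = ", "))
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) stop("constant response")
  Z <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  u <- (y - y_mean) / y_sd

  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  Zd <- Z; ud <- u
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Zd, ud))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {    # response fully deflated; stop early
      ncomp <- k - 1L
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      break
    }
    w <- w / nw
    t_ <- drop(Zd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Zd, t_)) / tt
    q_ <- sum(ud * t_) / tt
    Zd <- Zd - tcrossprod(t_, p_)
    ud <- ud - t_ * q_
    W[, k] <- w; P[, k] <- p_; q[k] <- q_; Tm[, k] <- t_
  }
  if (ncomp == 0L) stop("no informative component could be extracted")
  coef_std <- drop(W %*% solve(crossprod(P, W), q))
  b <- coef_std * y_sd / x_sd
  intercept <- y_mean - sum(b * x_mean)
  coefficients <- c("(Intercept)" = intercept, b)
  fitted <- drop(X %*% b) + intercept
  res <- y - fitted
  rmse <- sqrt(mean(res^2))
  structure(list(ncomp = ncomp, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, y_sd = y_sd,
                 weights = W, x_loadings = P, y_loadings = q,
                 coef_std = stats::setNames(coef_std, colnames(X)),
                 coefficients_original_scale = coefficients,
                 scores = Tm, y = y, fitted.values = fitted,
                 residuals = res,
                 r2_pearson = stats::cor(fitted, y)^2,
                 r2_ss = 1 - sum(res^2) / sum((y - y_mean)^2),
                 rmse_cal = rmse,
                 rmse_cal_pct = 100 * rmse / mean(y),
                 call = match.call()),
            class = "carot_pls")
}

#' @export
coef.carot_pls <- function(object, ...) object$coefficients_original_scale

#' @export
residuals.carot_pls <- function(object, ...) object$residuals

#' @export
fitted.carot_pls <- function(object, ...) object$fitted.values

#' Predict from a fitted PLS model
#'
#' @param object A `carot_pls` fit.
#' @param newdata Matrix or data frame with the model's predictor columns.
#' @param path `"coefficients"` (default; original-scale coefficient form)
#'   or `"latent"` (standardize, run through the latent components, and
#'   revert to the original scale).  The two agree to numerical precision;
#'   the latent path exists as a structural self-check.
#' @param ... Unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.carot_pls <- function(object, newdata,
                              path = c("coefficients", "latent"), ...) {
  path <- match.arg(path)
  if (missing(newdata)) return(object$fitted.values)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) &&
      all(names(object$x_mean) %in% colnames(X)))
    X <- X[, names(object$x_mean), drop = FALSE]
  if (path == "coefficients") {
    b <- object$coefficients_original_scale
    drop(X %*% b[-1]) + b[1]
  } else {
    Z <- sweep(sweep(X, 2, object$x_mean), 2, object$x_sd, "/")
    coef_std <- drop(object$weights %*%
                       solve(crossprod(object$x_loadings, object$weights),
                             object$y_loadings))
    drop(Z %*% coef_std) * object$y_sd + object$y_mean
  }
}

#' @export
print.carot_pls <- function(x, digits = 4, ...) {
  cat("Partial least squares regression (NIPALS,", x$ncomp,
      "components)\n")
  cat("Coefficients (original scale):\n")
  print(round(x$coefficients_original_scale, digits))
  cat(sprintf("R2 = %.3f (1 - SSE/SST), calibration RMSE = %.4g (%.1f%%)\n",
              x$r2_ss, x$rmse_cal, x$rmse_cal_pct))
  invisible(x)
}

#' @export
summary.carot_pls <- function(object, ...) {
  tt <- colSums(object$scores^2)
  # fraction of standardized-X variance captured per component
  x_var <- colSums(object$x_loadings^2) * tt /
    ((length(object$y) - 1) * length(object$x_mean))
  y_var <- object$y_loadings^2 * tt / (length(object$y) - 1)
  out <- list(fit = object,
              explained = rbind(X = x_var, y = y_var))
  class(out) <- "summary.carot_pls"
  out
}

#' @export
print.summary.carot_pls <- function(x, ...) {
  print(x$fit)
  cat("\nVariance explained per component (fraction of standardized total):\n")
  colnames(x$explained) <- paste0("LV", seq_len(ncol(x$explained)))
  print(round(x$explained, 4))
  invisible(x)
}

#' @export
plot.carot_pls <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values,
                 xlab = "observed", ylab = "fitted",
                 main = "PLS calibration", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
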