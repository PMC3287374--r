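# Generalized least squares under a fixed covariance structure, ML
# likelihood, AIC / Akaike weights, and polytomy-corrected t-tests.
#
# The model is y = X beta + e, e ~ N(0, sigma2 * V) with V fixed (identity
# for the "star" / conventional model, the Brownian matrix from
# phylo_covariance() for the "grafen" model). sigma2 is profiled out at its
# ML value, so the likelihood used for AIC is a true maximum likelihood and
# fits differing only in V are comparable.

#' Generalized least squares fit under a fixed covariance matrix
#'
#' Computes `beta = (X' V^-1 X)^-1 X' V^-1 y` via a Cholesky whitening of
#' `V`, the profiled ML variance `sigma2_hat = r' V^-1 r / n`, the ML
#' log-likelihood
#' `-(n/2) log(2 pi sigma2_hat) - log|V|/2 - n/2`,
#' and coefficient standard errors on the unbiased scale
#' `r' V^-1 r / (n - p)`. AIC counts the residual variance as one parameter:
#' `AIC = -2 logLik + 2 (p + 1)`.
#'
#' If the Cholesky factorization of `V` fails, a jitter of
#' `1e-10 * trace(V) / n` is added to the diagonal once (with a warning).
#'
#' @param y numeric response vector.
#' @param X design matrix (rows aligned with `y`); must be full column rank.
#' @param V covariance matrix aligned with `y`, or `NULL` for the identity
#'   (star phylogeny / conventional model).
#' @param covariance_label label stored on the fit (e.g. `"star"`,
#'   `"grafen"`).
#' @return a `gls_fit`: list with `coefficients`, `se`, `sigma2_hat` (ML),
#'   `sigma2_unbiased`, `log_likelihood`, `n_obs`, `n_coef`, `aic`,
#'   `residuals`, `covariance_label`, `degenerate`.
#' @export
fit_gls <- function(y, X, V = NULL, covariance_label = "star") {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("X and y have different numbers of rows",
                         call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(p))
  if (is.null(V)) {
    Wy <- y
    WX <- X
    logdetV <- 0
  } else {
    V <- as.matrix(V)
    if (!all(dim(V) == n)) stop("V must be n x n, aligned with y",
                                call. = FALSE)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) {
      jitter <- 1e-10 * sum(diag(V)) / n
      U <- tryCatch(chol(V + diag(jitter, n)), error = function(e) NULL)
      if (is.null(U))
        stop("V is singular even after jitter; increase epsilon on ",
             "replicate branches", call. = FALSE)
      warning(sprintf("V not positive definite; added jitter %g", jitter))
    }
    # whiten: solve t(U) w = . so that cov(Wy) = sigma2 I
    Wy <- forwardsolve(t(U), y)
    WX <- forwardsolve(t(U), X)
    logdetV <- 2 * sum(log(diag(U)))
  }

  qrW <- qr(WX)
  if (qrW$rank < p) {
    bad <- colnames(X)[qrW$pivot[(qrW$rank + 1):p]]
    if (is.null(bad)) bad <- paste0("column ", qrW$pivot[(qrW$rank + 1):p])
    stop("design matrix is rank deficient; collinear: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrW, Wy)
  r_w <- Wy - WX %*% beta             # whitened residuals
  rss <- sum(r_w^2)                    # = r' V^-1 r
  sigma2_ml <- rss / n
  degenerate <- (n <= p) || (rss < 1e-12 * max(1, sum(Wy^2)))

  XtX_inv <- chol2inv(chol(crossprod(WX)))   # (X' V^-1 X)^-1
  if (degenerate) {
    sigma2_unb <- 0
    se <- rep(NA_real_, p)
    logLik <- Inf
    aic <- NA_real_
  } else {
    sigma2_unb <- rss / (n - p)
    se <- sqrt(sigma2_unb * diag(XtX_inv))
    logLik <- -(n / 2) * log(2 * pi * sigma2_ml) - logdetV / 2 - n / 2
    aic <- -2 * logLik + 2 * (p + 1)
  }
  names(beta) <- colnames(X)
  names(se) <- colnames(X)

  structure(list(
    coefficients = beta, se = se,
    sigma2_hat = sigma2_ml, sigma2_unbiased = sigma2_unb,
    log_likelihood = logLik, n_obs = n, n_coef = p, aic = aic,
    residuals = as.numeric(y - X %*% beta),
    covariance_label = covariance_label, degenerate = degenerate
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("GLS fit [%s]: n = %d, p = %d\n",
              x$covariance_label, x$n_obs, x$n_coef))
  if (x$degenerate) {
    cat("  degenerate fit (zero residual variance)\n")
  } else {
    cat(sprintf("  logLik = %.4f, AIC = %.4f, sigma2(ML) = %.6g\n",
                x$log_likelihood, x$aic, x$sigma2_hat))
  }
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Akaike information criterion of a GLS fit
#'
#' `-2 logLik + 2 k` with `k = n_coef + 1` (the residual variance scale is
#' counted; the fixed star/Grafen covariance structure contributes no free
#' parameter, so the AIC difference between the two structures reduces to
#' the difference in -2 logLik).
#'
#' @param fit a `gls_fit`.
#' @return the AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "gls_fit"))
  if (fit$degenerate)
    stop("AIC undefined for a degenerate (zero-residual) fit", call. = FALSE)
  fit$aic
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`. Invariant to adding a constant to all AICs.
#'
#' @param aics numeric vector (length >= 2) of finite AIC values.
#' @return weights summing to 1, in the input order.
#' @examples
#' akaike_weights(c(10.37, -3.25))  # c(0.001, 0.999) at 3 decimals
#' @export
akaike_weights <- function(aics) {
  aics <- as.numeric(aics)
  if (length(aics) < 2) stop("need at least two AIC values", call. = FALSE)
  if (any(!is.finite(aics))) stop("non-finite AIC value", call. = FALSE)
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Polytomy-corrected residual degrees of freedom
#'
#' The conservative correction for soft polytomies: subtract one residual
#' degree of freedom for each unresolved node (internal node with more than
#' two children), on top of the usual `n - p`.
#'
#' @param n_obs number of observations.
#' @param n_coef number of estimated mean parameters.
#' @param n_polytomies number of soft polytomies in the tree used.
#' @return `n_obs - n_coef - n_polytomies`.
#' @examples
#' corrected_df(62, 2, 25)  # 35
#' corrected_df(62, 2, 0)   # 60
#' @export
corrected_df <- function(n_obs, n_coef, n_polytomies) {
  stopifnot(n_obs >= 1, n_coef >= 0, n_polytomies >= 0)
  df <- n_obs - n_coef - n_polytomies
  if (df <= 0)
    stop("corrected df would be <= 0; hypothesis test impossible",
         call. = FALSE)
  df
}

#' t-test for one GLS coefficient at supplied degrees of freedom
#'
#' `t = beta / SE`, two-sided p-value from the Student-t distribution with
#' the supplied (possibly polytomy-corrected) degrees of freedom.
#'
#' @param fit a `gls_fit`.
#' @param coef_index index or name of the coefficient.
#' @param df degrees of freedom (>= 1).
#' @return list with `t_statistic`, `df`, `p_value`.
#' @export
t_test_coefficient <- function(fit, coef_index, df) {
  stopifnot(inherits(fit, "gls_fit"), df >= 1)
  b <- fit$coefficients[coef_index]
  s <- fit$se[coef_index]
  if (length(b) != 1 || is.na(b)) stop("no such coefficient", call. = FALSE)
  if (is.na(s) || s <= 0) stop("standard error is zero or undefined",
                               call. = FALSE)
  t <- as.numeric(b / s)
  list(t_statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Compare conventional (star) and phylogenetic (Grafen) GLS fits
#'
#' Fits the same mean model under the identity covariance ("star", i.e.
#' conventional statistics) and under the supplied phylogenetic covariance
#' ("grafen"), compares them by AIC and Akaike weights, and tests every
#' coefficient in both fits: the conventional fit with raw df `n - p`, the
#' phylogenetic fit with the polytomy-corrected df `n - p - n_polytomies`.
#' AIC ties (|difference| < 1e-9) resolve to the star model as the simpler
#' covariance assumption.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param V phylogenetic covariance matrix aligned with `y`.
#' @param n_polytomies number of soft polytomies (see
#'   [count_soft_polytomies()]).
#' @return a `model_comparison`: list with `fits` (star, grafen),
#'   `aic` (named vector), `akaike_weights`, `best`, and `tests` — a
#'   data.frame with one row per model x coefficient (estimate, se, t,
#'   df_raw, df_corrected, df_used, p).
#' @export
model_comparison <- function(y, X, V, n_polytomies = 0) {
  fit_star <- fit_gls(y, X, V = NULL, covariance_label = "star")
  fit_graf <- fit_gls(y, X, V = V, covariance_label = "grafen")
  aics <- c(star = aic(fit_star), grafen = aic(fit_graf))
  w <- akaike_weights(aics)
  names(w) <- names(aics)
  best <- if (aics["grafen"] < aics["star"] - 1e-9) "grafen" else "star"

  n <- fit_star$n_obs
  p <- fit_star$n_coef
  df_raw <- n - p
  df_corr <- corrected_df(n, p, n_polytomies)

  one_model <- function(fit, df_used) {
    do.call(rbind, lapply(seq_len(p), function(j) {
      tt <- t_test_coefficient(fit, j, df_used)
      data.frame(model = fit$covariance_label,
                 coefficient = names(fit$coefficients)[j],
                 estimate = unname(fit$coefficients[j]),
                 se = unname(fit$se[j]),
                 t = tt$t_statistic, df_raw = df_raw,
                 df_corrected = df_corr, df_used = df_used,
                 p = tt$p_value, stringsAsFactors = FALSE)
    }))
  }
  tests <- rbind(one_model(fit_star, df_raw), one_model(fit_graf, df_corr))

  structure(list(
    fits = list(star = fit_star, grafen = fit_graf),
    aic = aics, akaike_weights = w, best = best,
    n_polytomies = n_polytomies, tests = tests
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (star vs grafen covariance)\n")
  tab <- data.frame(
    model = names(x$aic),
    logLik = vapply(x$fits, function(f) f$log_likelihood, numeric(1)),
    AIC = as.numeric(x$aic),
    AICw = as.numeric(x$akaike_weights)
  )
  print(tab, row.names = FALSE)
  cat("best:", x$best, "  soft polytomies:", x$n_polytomies, "\n\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

# list form of a model_comparison for JSON serialization
comparison_to_list <- function(mc) {
  stopifnot(inherits(mc, "model_comparison"))
  list(
    models = lapply(names(mc$fits), function(nm) {
      f <- mc$fits[[nm]]
      list(covariance_label = nm, logLik = f$log_likelihood,
           AIC = unname(mc$aic[nm]), AICw = unname(mc$akaike_weights[nm]))
    }),
    best = mc$best,
    n_polytomies = mc$n_polytomies,
    coefficients = mc$tests
  )
}
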