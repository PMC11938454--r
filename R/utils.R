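## Internal validation and fitting helpers shared across modules.

stop_validation <- function(msg, ...) {
  stop(structure(class = c("loadpaths_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("%s must be a single finite number", name)
  low_ok <- if (open_lower) x > lower else x >= lower
  high_ok <- if (open_upper) x < upper else x <= upper
  if (!low_ok || !high_ok)
    stop_validation("%s = %g outside the allowed range %s%g, %g%s", name, x,
                    if (open_lower) "(" else "[", lower, upper,
                    if (open_upper) ")" else "]")
  invisible(x)
}

## Least-squares fit returning coefficients, SEs and residual d.f.
## X must already carry an intercept column. Used everywhere a plain lm()
## would be too slow to call thousands of times (grid + bootstrap).
ls_fit <- function(X, y, se = TRUE) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop_validation("rank-deficient design; collinear column(s): %s",
                    paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qr_x, y)
  if (!se) return(list(coef = coef))
  res <- y - X %*% coef
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se_vec <- sqrt(sigma2 * diag(xtx_inv))
  names(se_vec) <- colnames(X)
  list(coef = coef, se = se_vec, df = df, sigma2 = sigma2)
}

## Logistic fit via glm.fit with separation / convergence diagnostics.
logit_fit <- function(X, y, se = TRUE) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), intercept = FALSE)
  )
  converged <- fit$converged && !fit$boundary
  coef <- fit$coefficients
  ## Wald SEs from the final IRLS weights
  out <- list(coef = coef, converged = converged)
  if (any(!is.finite(coef)) || any(abs(coef) > 15)) out$converged <- FALSE
  if (se) {
    w <- fit$weights
    xtwx <- crossprod(X * sqrt(w))
    cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
    if (is.null(cov)) {
      out$converged <- FALSE
      out$se <- rep(NA_real_, length(coef))
    } else {
      out$se <- sqrt(diag(cov))
    }
    names(out$se) <- colnames(X)
  }
  out
}

## Build a design matrix (intercept + named columns + site dummies) from an
## analysis data.frame, after listwise deletion has been applied by the caller.
design_matrix <- function(data, columns, site = TRUE) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  for (cl in columns) {
    v <- data[[cl]]
    if (is.null(v)) stop_validation("column '%s' not found in analysis data", cl)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cl
  }
  if (site && "site" %in% names(data)) {
    s <- factor(data$site)
    if (nlevels(s) > 1L) {
      dummies <- stats::model.matrix(~ s)[, -1L, drop = FALSE]
      colnames(dummies) <- paste0("site", levels(s)[-1L])
      X <- cbind(X, dummies)
    }
  }
  X
}

## Rows complete in all required columns (model-specific listwise deletion).
complete_rows <- function(data, columns) {
  ok <- rep(TRUE, nrow(data))
  for (cl in columns) ok <- ok & !is.na(data[[cl]])
  ok
}

## Truncated-normal draws by rejection; bounds are mild so this is cheap.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}
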