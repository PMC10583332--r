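# Firth-penalized logistic regression: modified-score Newton iterations
# with Jeffreys-prior penalty 0.5 * log det(Fisher information), hat-value
# adjusted residuals and step-halving.  Estimates remain finite under
# complete separation, the estimator's defining property.

# Numerically stable log(1 + exp(eta)).
log1pexp <- function(eta) {
  out <- numeric(length(eta))
  big <- eta > 30
  out[big] <- eta[big]
  out[!big] <- log1p(exp(eta[!big]))
  out
}

penalized_loglik <- function(x, y, beta) {
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  ch <- tryCatch(chol(crossprod(x * sqrt(w))), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  sum(y * eta - log1pexp(eta)) + sum(log(diag(ch)))
}

#' Fit a Firth-penalized logistic regression
#'
#' Maximizes the log-likelihood plus the Jeffreys penalty
#' `0.5 * log det(X' W X)` by Newton steps on the modified score
#' `U*(beta) = X' (y - mu + h (1/2 - mu))`, where `h` are the hat-matrix
#' diagonals, with step-halving whenever a step fails to increase the
#' penalized likelihood.  Under complete separation the penalty keeps the
#' maximizer finite where ordinary maximum likelihood diverges.
#'
#' @param x Design matrix (include the intercept column), full column
#'   rank.
#' @param y Binary outcome vector (0/1).
#' @param tol Convergence tolerance on the max-norm of the modified score.
#' @param max_iter Maximum Newton iterations.
#' @param max_halving Maximum step-halvings per iteration.
#' @param conf.level Level of the Wald confidence intervals.
#' @return An object of class `firth_fit`: `coefficients`, `se`, `ci`
#'   (matrix), `vcov`, `loglik` (penalized), `converged`, `iterations`,
#'   `score_norm`, `hat` (diagonal summary), `fitted` (probabilities).
#' @export
#' @examples
#' # Four successes out of four: fitted probability (k + 1/2)/(n + 1) = 0.9
#' fit <- fit_firth_logistic(matrix(1, 4, 1), rep(1, 4))
#' plogis(fit$coefficients)
fit_firth_logistic <- function(x, y, tol = 1e-8, max_iter = 150L,
                               max_halving = 10L, conf.level = 0.95) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (!is_binary01(y)) nn_stop("outcome must be binary 0/1")
  if (nrow(x) != length(y)) nn_stop("design and outcome sizes differ")
  p <- ncol(x)
  if (qr(x)$rank < p) nn_stop("design matrix is rank deficient")
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  score_norm <- Inf
  info_inv <- NULL
  hat <- NULL
  repeat {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    ch <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(ch)) {
      nn_stop_numeric("Fisher information not positive definite at current estimate")
    }
    info_inv <- chol2inv(ch)
    hat <- rowSums((x %*% info_inv) * x) * w
    score <- drop(crossprod(x, y - mu + hat * (0.5 - mu)))
    score_norm <- max(abs(score))
    if (score_norm < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    delta <- drop(info_inv %*% score)
    cur <- sum(y * eta - log1pexp(eta)) + sum(log(diag(ch)))
    step <- delta
    for (half in seq_len(max_halving + 1L)) {
      cand <- penalized_loglik(x, y, beta + step)
      if (cand > cur - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step
  }
  if (!converged) {
    warning(sprintf(
      "Firth fit did not converge in %d iterations (score norm %.3g); partial result returned",
      max_iter, score_norm
    ), call. = FALSE)
  }
  se <- sqrt(diag(info_inv))
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  ci <- cbind(lower = beta - zcrit * se, upper = beta + zcrit * se)
  rownames(ci) <- colnames(x)
  structure(
    list(coefficients = setNames(beta, colnames(x)),
         se = setNames(se, colnames(x)), ci = ci, vcov = info_inv,
         loglik = penalized_loglik(x, y, beta), converged = converged,
         iterations = iter, score_norm = score_norm,
         hat = summary(hat), fitted = plogis(drop(x %*% beta)),
         n = length(y)),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("Firth-penalized logistic fit (n = %d, %s in %d iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(cbind(estimate = x$coefficients, se = x$se, x$ci), 4))
  cat(sprintf("penalized log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann–Whitney) AUC: the proportion of (case, control) pairs
#' where the case scores higher, ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = case); both classes must be present.
#' @return Scalar AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
roc_auc <- function(scores, labels) {
  if (!is_binary01(labels)) nn_stop("labels must be binary 0/1")
  if (length(scores) != length(labels)) nn_stop("scores and labels differ in length")
  if (anyNA(scores)) nn_stop("missing scores")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    nn_stop_numeric("undefined AUC: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Structural-components (DeLong) variance with a normal-approximation
#' interval, truncated to \[0, 1\].  Under perfect separation the
#' components are degenerate and a zero-width interval at the AUC is
#' returned with a warning.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels; each class needs at least 2 members.
#' @param conf.level Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `variance`.
#' @export
delong_auc_ci <- function(scores, labels, conf.level = 0.95) {
  if (!is_binary01(labels)) nn_stop("labels must be binary 0/1")
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  if (length(xs) < 2L || length(ys) < 2L) {
    nn_stop("each class needs at least 2 members for the DeLong variance")
  }
  m <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(m)
  v10 <- rowMeans(m)
  v01 <- colMeans(m)
  v <- var(v10) / length(xs) + var(v01) / length(ys)
  if (v == 0) {
    warning("degenerate DeLong variance (perfect separation): zero-width interval",
            call. = FALSE)
    return(list(auc = auc, ci_low = auc, ci_high = auc, variance = 0))
  }
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zcrit * sqrt(v), 0), 1)
  list(auc = auc, ci_low = ci[1], ci_high = ci[2], variance = v)
}

#' AIC and penalized likelihood ratio for Firth fits
#'
#' `aic = -2 * penalized_loglik + 2 * k` with `k` the number of
#' coefficients (intercept included), and
#' `plr = 2 * (penalized_loglik_fit - penalized_loglik_reference)`.  The
#' PLR is a test statistic only for nested models; for non-nested pairs it
#' is descriptive.
#'
#' @param fit A `firth_fit`.
#' @param reference Optional reference `firth_fit` for the PLR.
#' @return List with `aic` and `plr` (`NA` when no reference given).
#' @export
model_fit_stats <- function(fit, reference = NULL) {
  stopifnot(inherits(fit, "firth_fit"))
  aic <- -2 * fit$loglik + 2 * length(fit$coefficients)
  plr <- if (is.null(reference)) {
    NA_real_
  } else {
    stopifnot(inherits(reference, "firth_fit"))
    2 * (fit$loglik - reference$loglik)
  }
  list(aic = aic, plr = plr)
}
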