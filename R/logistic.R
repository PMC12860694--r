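#' Weighted logistic regression by iteratively reweighted least squares
#'
#' Maximises the weighted Bernoulli log-likelihood
#' `sum_i w_i [y_i log mu_i + (1 - y_i) log(1 - mu_i)]`. Weights act as
#' frequency-style case weights, so the outcome may be given as per-row
#' proportions with trial counts as weights (aggregated binomial rows) or as
#' 0/1 with unit or post-stratification weights. The Wald covariance is the
#' inverse of the final weighted Fisher information.
#'
#' @param x design matrix (including intercept column), full rank.
#' @param y outcome in [0, 1].
#' @param weights positive case weights (default 1).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-10).
#' @param max_iter maximum IRLS iterations (default 50).
#' @return an `irls_fit`: coefficients, `vcov`, convergence flag and
#'   iteration count, log-likelihood, null (intercept-only) log-likelihood,
#'   `n` (rows) and `wsum` (total weight).
#' @export
fit_logistic_irls <- function(x, y, weights = NULL, tol = 1e-10,
                              max_iter = 50) {
  x <- as.matrix(x)
  if (is.logical(y)) y <- as.numeric(y)
  if (any(is.na(y)) || any(y < 0) || any(y > 1))
    abort2("outcome must lie in [0, 1] with no missing values", "config")
  w <- weights %||% rep(1, nrow(x))
  if (any(w <= 0)) abort2("weights must be positive", "config")

  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort2(paste("design matrix is rank deficient; aliased columns:",
                 paste(aliased, collapse = ", ")), "aliasing")
  }

  beta <- rep(0, ncol(x))
  converged <- FALSE
  iter <- 0L
  eps <- 1e-12
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), eps)
    z <- eta + (y - mu) / v
    wls <- w * v
    xtwx <- crossprod(x, x * wls)
    beta_new <- drop(solve(xtwx, crossprod(x, wls * z)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(beta)) > 15)
      abort2(paste("coefficients diverging (|beta| > 15): (quasi-)complete",
                   "separation"), "separation")
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  v <- pmax(mu * (1 - mu), eps)
  info <- crossprod(x, x * (w * v))
  vc <- solve(info)
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)

  ll <- wll(y, mu, w)
  p0 <- sum(w * y) / sum(w)
  ll0 <- wll(y, rep(p0, length(y)), w)

  structure(list(coefficients = beta, vcov = vc, converged = converged,
                 iterations = iter, loglik = ll, null_loglik = ll0,
                 n = nrow(x), wsum = sum(w), fitted = mu,
                 x = x, y = y, weights = w),
            class = "irls_fit")
}

wll <- function(y, mu, w) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' @export
print.irls_fit <- function(x, ...) {
  cat(sprintf("Weighted logistic fit: %d rows, total weight %.1f, %s in %d iterations\n",
              x$n, x$wsum,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(cbind(coef = x$coefficients,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared `1 - exp(-2 (ll - ll0) / n)` rescaled by its maximum
#' attainable value `1 - exp(2 ll0 / n)`, where n is the total case weight.
#'
#' @param fit an `irls_fit`.
#' @return value in [0, 1].
#' @export
nagelkerke_r2 <- function(fit) {
  n <- fit$wsum
  r2_cs <- 1 - exp(-2 * (fit$loglik - fit$null_loglik) / n)
  r2_max <- 1 - exp(2 * fit$null_loglik / n)
  if (r2_max <= 0) return(0)
  max(0, min(1, r2_cs / r2_max))
}

#' Generalised variance inflation factors
#'
#' Determinant-ratio GVIF per model term on the correlation matrix of the
#' coefficient covariance with the intercept removed:
#' `GVIF_j = det(R_jj) det(R_(-j)(-j)) / det(R)`, with the usual
#' `GVIF^(1/(2 df))` scaling for multi-column terms. Interaction terms are
#' expected to exceed 1 as they are inherently correlated with their main
#' effects.
#'
#' @param fit an `irls_fit` carrying a `term_assign` attribute (as built by
#'   [did_effect()]), or supply `assign`/`terms` explicitly.
#' @param assign integer vector mapping non-intercept design columns to terms.
#' @param terms character labels of the terms.
#' @return data.frame with `term`, `df`, `gvif`, `gvif_scaled`.
#' @export
gvif <- function(fit, assign = NULL, terms = NULL) {
  assign <- assign %||% attr(fit, "term_assign")
  terms <- terms %||% attr(fit, "term_labels")
  if (is.null(assign) || length(unique(assign)) < 2)
    abort2("GVIF needs at least two model terms", "config")
  vc <- fit$vcov[-1, -1, drop = FALSE]
  r <- stats::cov2cor(vc)
  gvif_matrix(r, assign, terms)
}

#' Determinant-ratio GVIF on a correlation matrix
#'
#' @param r correlation matrix of non-intercept predictors or coefficients.
#' @param groups integer group index per column.
#' @param labels optional group labels.
#' @return data.frame with `term`, `df`, `gvif`, `gvif_scaled`.
#' @export
gvif_matrix <- function(r, groups, labels = NULL) {
  detr <- det(r)
  if (abs(detr) < 1e-300)
    abort2("singular correlation matrix: aliased predictors", "aliasing")
  ug <- unique(groups)
  labels <- labels %||% as.character(ug)
  # a per-column label vector collapses to one label per group
  if (length(labels) == length(groups) && length(groups) > length(ug))
    labels <- labels[match(ug, groups)]
  out <- lapply(seq_along(ug), function(i) {
    idx <- which(groups == ug[i])
    g <- det(r[idx, idx, drop = FALSE]) *
      det(r[-idx, -idx, drop = FALSE]) / detr
    data.frame(term = labels[i], df = length(idx), gvif = g,
               gvif_scaled = g^(1 / (2 * length(idx))))
  })
  do.call(rbind, out)
}
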