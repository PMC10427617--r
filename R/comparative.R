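# Brownian-motion trait covariance on a tree (shared path lengths), with
# Pagel's lambda scaling of the off-diagonals.
phylo_covariance <- function(tree, lambda = 1) {
  V <- ape::vcv(tree)
  if (lambda != 1) {
    d <- diag(V)
    V <- V * lambda
    diag(V) <- d
  }
  V
}

# Whitened GLS fit for a fixed covariance; returns everything downstream
# summaries need.
gls_core <- function(X, y, V) {
  U <- chol(V)
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(qrx, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  list(beta = beta, rss = rss, Xw = Xw, yw = yw,
       XtX_inv = chol2inv(qr.R(qrx)),
       logdetV = 2 * sum(log(diag(U))))
}

#' Phylogenetic generalized least squares
#'
#' Fits a linear model whose error covariance follows shared evolutionary
#' history: Brownian motion on the tree, optionally attenuated by Pagel's
#' lambda (off-diagonal scaling). Coefficients are the closed-form GLS
#' solution; the overall F statistic compares the full model against the
#' intercept-only model under the same covariance, so it has
#' `(p - 1, n - p)` degrees of freedom. Factor predictors use R's default
#' treatment contrasts with the alphabetically first level as baseline.
#'
#' @param tree A `phylo` whose tip set matches the data rows.
#' @param data Data frame of tip variables; rows are matched to tips by a
#'   `species` column or by row names.
#' @param formula Model formula over columns of `data`.
#' @param lambda Either a fixed value in `[0, 1]` (default 1, pure
#'   Brownian) or `"ML"` to profile it out by maximum likelihood.
#' @return Object of class `pgls_fit`: coefficient table (estimate, se, t),
#'   `sigma2`, overall `F` with `df1`, `df2`, `p_value`, `lambda`,
#'   `loglik`, `n`.
#' @export
pgls_fit <- function(tree, data, formula, lambda = 1) {
  data <- as.data.frame(data)
  labs <- if ("species" %in% names(data)) data$species else rownames(data)
  if (!setequal(labs, tree$tip.label)) stop("data rows do not match tree tips")
  data <- data[match(tree$tip.label, labs), , drop = FALSE]
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  y <- model.response(mf)
  n <- length(y)
  p <- ncol(X)
  V1 <- phylo_covariance(tree, 1)
  fit_at <- function(lam) gls_core(X, y, phylo_covariance(tree, lam))
  ml_loglik <- function(lam) {
    g <- fit_at(lam)
    -0.5 * (n * log(2 * pi * g$rss / n) + n + g$logdetV)
  }
  if (identical(lambda, "ML")) {
    opt <- optimize(ml_loglik, c(0, 1), maximum = TRUE)
    lambda <- opt$maximum
  }
  g <- fit_at(lambda)
  sigma2 <- g$rss / (n - p)
  se <- sqrt(diag(g$XtX_inv) * sigma2)
  # intercept-only fit under the same covariance for the overall F
  g0 <- gls_core(matrix(1, n, 1), y, phylo_covariance(tree, lambda))
  Fstat <- if (p > 1) ((g0$rss - g$rss) / (p - 1)) / (g$rss / (n - p)) else NA_real_
  pval <- if (p > 1) pf(Fstat, p - 1, n - p, lower.tail = FALSE) else NA_real_
  coefs <- data.frame(estimate = drop(g$beta), se = se,
                      t = drop(g$beta) / se,
                      row.names = colnames(X))
  structure(list(
    coefficients = coefs, sigma2 = sigma2, lambda = lambda,
    F = Fstat, df1 = p - 1L, df2 = n - p, p_value = pval,
    loglik = ml_loglik(lambda), n = n, formula = formula
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (lambda =", format(x$lambda, digits = 4), ", n =", x$n, ")\n")
  print(round(x$coefficients, 5))
  if (!is.na(x$F)) {
    cat(sprintf("F_%d:%d = %.4g, p = %.4g; sigma2 = %.4g\n",
                x$df1, x$df2, x$F, x$p_value, x$sigma2))
  }
  invisible(x)
}

#' Brownian-motion ancestral reconstruction of a continuous character
#'
#' Maximum-likelihood ancestral estimates under Brownian motion. The joint
#' Gaussian density factorizes over branches, so the ML node values solve
#' the sparse linear system in which each internal node is the
#' branch-length-weighted (weights `1 / t`) average of its neighbors; for
#' a Gaussian this joint mode equals the conditional mean of each node
#' given the tips. Node variances are the conditional variances scaled by
#' the contrast-based rate estimate. Estimates are convex combinations of
#' tip values, so they always lie within the observed range.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param x Named numeric vector of tip values (names = tip labels), all
#'   finite.
#' @return Object of class `brownian_asr`: data frame `nodes` with `node`,
#'   `estimate`, `variance` for each internal node (ape numbering), plus
#'   `sigma2` and `root_estimate` attributes-style fields.
#' @export
brownian_asr <- function(tree, x) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("tips without values: ", paste(head(miss, 5), collapse = ", "))
  xv <- as.numeric(x[tree$tip.label])
  if (any(!is.finite(xv))) stop("tip values must be finite")
  N <- nt + nn
  w <- 1 / pmax(tree$edge.length, 1e-12)
  # weighted graph Laplacian split into internal (unknown) and tip blocks
  L <- matrix(0, N, N)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, j] <- L[j, i] <- L[i, j] - w[e]
    L[i, i] <- L[i, i] + w[e]
    L[j, j] <- L[j, j] + w[e]
  }
  int <- (nt + 1L):N
  tips <- seq_len(nt)
  L_II <- L[int, int, drop = FALSE]
  rhs <- -L[int, tips, drop = FALSE] %*% xv
  est <- drop(solve(L_II, rhs))
  # REML rate estimate from the whitened deviations around the GLS mean
  Vt <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  U <- chol(Vt)
  onew <- backsolve(U, rep(1, nt), transpose = TRUE)
  xw <- backsolve(U, xv, transpose = TRUE)
  mu <- sum(onew * xw) / sum(onew^2)
  sigma2 <- sum((xw - mu * onew)^2) / (nt - 1)
  vars <- sigma2 * diag(solve(L_II))
  structure(list(
    nodes = data.frame(node = int, estimate = est, variance = vars),
    sigma2 = sigma2, root_estimate = est[1], tree = tree
  ), class = "brownian_asr")
}

#' @export
print.brownian_asr <- function(x, ...) {
  cat("Brownian ancestral reconstruction:", nrow(x$nodes), "internal nodes\n")
  cat("  sigma2 =", format(x$sigma2, digits = 5),
      "; root estimate =", format(x$root_estimate, digits = 6), "\n")
  invisible(x)
}
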