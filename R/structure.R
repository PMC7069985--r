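## Structure of the methylation correlation matrix: nonparanormal normal
## scores, parallel analysis for factor retention, maximum-likelihood EFA
## with promax rotation, and a sparse Gaussian graphical model (graphical
## lasso along a regularization path, model selected by extended BIC).

#' Nonparanormal (normal-scores) transformation
#'
#' Each column is mapped to standard normal quantiles of its ranks,
#' `qnorm(rank / (n + 1))`, with average ranks for ties; NA cells stay NA.
#' Constant columns are dropped with a warning.
#'
#' @param x numeric matrix or data.frame of numeric columns.
#' @return matrix of normal scores.
#' @export
nonparanormal_transform <- function(x) {
  x <- as.matrix(x)
  keep <- logical(ncol(x))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    if (sum(ok) < 3 || length(unique(v[ok])) < 2) { keep[j] <- FALSE; next }
    keep[j] <- TRUE
    r <- rank(v[ok], ties.method = "average")
    out[ok, j] <- stats::qnorm(r / (sum(ok) + 1))
  }
  if (!all(keep))
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  out[, keep, drop = FALSE]
}

## pairwise-complete correlation with minimum overlap; columns below the
## overlap floor are dropped
.pairwise_cor <- function(x, min_overlap = 20L) {
  n_ok <- colSums(!is.na(x))
  keep <- n_ok >= min_overlap
  x <- x[, keep, drop = FALSE]
  r <- stats::cor(x, use = "pairwise.complete.obs")
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Parallel analysis for the number of factors to retain
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' chosen quantile of eigenvalues from `n_sims` standard-normal datasets of
#' identical shape; the retained count is the number of leading components
#' whose observed eigenvalue exceeds its simulated quantile.
#'
#' @param x data matrix (rows = observations).
#' @param n_sims simulated datasets (default 1000).
#' @param quantile simulated-eigenvalue quantile (default 0.95).
#' @return integer number of factors.
#' @export
parallel_analysis <- function(x, n_sims = 1000, quantile = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("parallel analysis needs at least 2 columns")
  n <- nrow(x); p <- ncol(x)
  obs <- eigen(.pairwise_cor(x, min_overlap = min(n, 20L)),
               symmetric = TRUE, only.values = TRUE)$values
  sims <- matrix(0, n_sims, p)
  for (s in seq_len(n_sims)) {
    z <- matrix(stats::rnorm(n * p), n, p)
    sims[s, ] <- eigen(stats::cor(z), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  thr <- apply(sims, 2, stats::quantile, probs = quantile)
  above <- obs > thr
  if (!above[1]) return(0L)
  as.integer(which.min(c(above, FALSE)) - 1L)
}

#' Maximum-likelihood EFA with promax rotation
#'
#' Factors are extracted by maximum likelihood from the correlation matrix,
#' rotated varimax then promax (power `kappa`).  Loadings are sign-aligned
#' so each factor's largest-|loading| entry is positive.
#'
#' @param x data matrix (rows = observations).
#' @param n_factors number of factors (1 <= n_factors < ncol).
#' @param kappa promax power (default 4).
#' @param min_overlap pairwise-complete correlation floor.
#' @return list of class `factor_solution`: `n_factors`, `loadings`
#'   (site x factor), `factor_cor`, `communalities`.
#' @export
efa_promax <- function(x, n_factors, kappa = 4, min_overlap = 20L) {
  x <- as.matrix(x)
  stopifnot(n_factors >= 1, n_factors < ncol(x))
  R <- .pairwise_cor(x, min_overlap)
  n_obs <- max(colSums(!is.na(x)))
  fa <- tryCatch(
    stats::factanal(covmat = R, factors = n_factors, n.obs = n_obs,
                    rotation = "none"),
    error = function(e) stop("EFA did not converge: ",
                             conditionMessage(e), call. = FALSE))
  L <- stats::loadings(fa)
  class(L) <- NULL
  L <- matrix(L, ncol = n_factors,
              dimnames = list(rownames(fa$loadings), NULL))
  if (n_factors > 1) {
    vm <- stats::varimax(L)
    pm <- stats::promax(vm$loadings, m = kappa)
    L2 <- matrix(pm$loadings, ncol = n_factors,
                 dimnames = dimnames(L))
    rot <- pm$rotmat
    phi <- solve(t(rot) %*% rot)
    phi <- stats::cov2cor(phi)
  } else {
    L2 <- L
    phi <- matrix(1, 1, 1)
  }
  ## sign alignment
  for (k in seq_len(n_factors)) {
    i <- which.max(abs(L2[, k]))
    if (L2[i, k] < 0) {
      L2[, k] <- -L2[, k]
      phi[k, ] <- -phi[k, ]; phi[, k] <- -phi[, k]
    }
  }
  colnames(L2) <- sprintf("F%d", seq_len(n_factors))
  dimnames(phi) <- list(colnames(L2), colnames(L2))
  comm <- rowSums((L2 %*% phi) * L2)
  structure(list(n_factors = n_factors, loadings = L2, factor_cor = phi,
                 communalities = pmin(pmax(comm, 0), 1)),
            class = "factor_solution")
}

## ---- graphical lasso ----

## one graphical-lasso fit at penalty rho (Friedman's blockwise coordinate
## descent); returns covariance W and precision Theta
.glasso_fit <- function(S, rho, tol = 1e-5, max_iter = 200) {
  p <- ncol(S)
  if (p == 1) return(list(W = S, Theta = matrix(1 / S[1, 1], 1, 1)))
  W <- S
  diag(W) <- diag(S) + rho
  B <- matrix(0, p - 1, p)           # lasso coefficients per column
  thr <- tol * mean(abs(S[upper.tri(S)]))
  if (!is.finite(thr) || thr <= 0) thr <- tol
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      ## coordinate descent on 0.5 b'W11 b - s12'b + rho|b|_1
      for (cd in seq_len(100)) {
        delta <- 0
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          bk <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
          delta <- max(delta, abs(bk - beta[k]))
          beta[k] <- bk
        }
        if (delta < thr) break
      }
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < thr) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    denom <- W[j, j] - sum(W[idx, j] * B[, j])
    Theta[j, j] <- 1 / denom
    Theta[idx, j] <- -B[, j] * Theta[j, j]
  }
  Theta <- (Theta + t(Theta)) / 2
  list(W = W, Theta = Theta)
}

#' Sparse partial-correlation network selected by extended BIC
#'
#' Solves the graphical lasso along a log-spaced regularization path and
#' selects the model minimizing
#' `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` with `E` the edge
#' count.  Edge weights are standardized partial correlations
#' `-Theta_ij / sqrt(Theta_ii Theta_jj)`.  Input should be nonparanormal-
#' transformed (see [nonparanormal_transform()]).
#'
#' @param x data matrix (rows = observations).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambdas path length (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of the maximum
#'   absolute off-diagonal correlation.
#' @param edge_threshold `"bound"` (default) suppresses edges with
#'   |partial correlation| below `sqrt(log(p)/n)` -- the consistency bound
#'   commonly used to curb spurious small edges in EBICglasso networks --
#'   before edge counting and selection; `"none"` keeps every numerically
#'   non-zero edge.
#' @param min_overlap pairwise-complete correlation floor; columns with
#'   fewer complete cells are dropped.
#' @return list of class `network_model`: `nodes`, `weights` (partial
#'   correlation matrix), `lambda`, `ebic`, `n_edges`.
#' @export
ebicglasso <- function(x, gamma = 0.5, n_lambdas = 100,
                       lambda_min_ratio = 0.01,
                       edge_threshold = c("bound", "none"),
                       min_overlap = 20L) {
  edge_threshold <- match.arg(edge_threshold)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows")
  S <- .pairwise_cor(x, min_overlap)
  p <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("correlation matrix not positive definite; ridge-stabilized")
    S <- S + diag(1e-4 - min(ev, 0), p)
    S <- stats::cov2cor(S)
  }
  lmax <- max(abs(S[upper.tri(S)]), 1e-4)
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = n_lambdas))
  best <- NULL
  for (rho in lambdas) {
    fit <- .glasso_fit(S, rho)
    Theta <- fit$Theta
    pc <- -Theta / sqrt(diag(Theta) %o% diag(Theta))
    diag(pc) <- 0
    pc[abs(pc) < 1e-4] <- 0
    E <- sum(pc[upper.tri(pc)] != 0)
    ld <- determinant(Theta, logarithm = TRUE)$modulus
    loglik <- (n / 2) * (as.numeric(ld) - sum(S * Theta))
    ebic <- -2 * loglik + E * log(n) + 4 * E * gamma * log(p)
    if (is.null(best) || ebic < best$ebic)
      best <- list(weights = pc, lambda = rho, ebic = ebic, n_edges = E)
  }
  ## suppress sub-consistency-bound edges of the selected model
  if (edge_threshold == "bound") {
    best$weights[abs(best$weights) < sqrt(log(p) / n)] <- 0
    best$n_edges <- sum(best$weights[upper.tri(best$weights)] != 0)
  }
  dimnames(best$weights) <- list(colnames(S), colnames(S))
  structure(list(nodes = colnames(S), weights = best$weights,
                 lambda = best$lambda, ebic = best$ebic,
                 n_edges = best$n_edges),
            class = "network_model")
}

#' Edge list of a network model
#' @param net `network_model` from [ebicglasso()].
#' @return data.frame `node1`, `node2`, `weight` (non-zero edges only).
#' @export
network_edges <- function(net) {
  w <- net$weights
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(node1 = rownames(w)[ut[, 1]], node2 = colnames(w)[ut[, 2]],
             weight = w[ut])
}
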