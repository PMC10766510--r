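# Candidate generation from the latent space: GMM center selection,
# re-embedding, and batch Bayesian optimization over measured activities.

mvn_log_density <- function(X, mean, cov) {
  d <- ncol(X)
  ch <- chol(cov)
  diff <- sweep(X, 2, mean)
  y <- backsolve(ch, t(diff), transpose = TRUE)
  -0.5 * colSums(y^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

gmm_em_once <- function(X, k, tol = 1e-4, max_iter = 200, ridge = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  means <- X[sample.int(n, k), , drop = FALSE]
  base_cov <- stats::cov(X) + diag(ridge, d)
  covs <- replicate(k, base_cov, simplify = FALSE)
  wts <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- vapply(seq_len(k),
                 function(j) mvn_log_density(X, means[j, ], covs[[j]]) +
                   log(wts[j]),
                 numeric(n))
    mx <- do.call(pmax, lapply(seq_len(k), function(j) ld[, j]))
    lse <- mx + log(rowSums(exp(ld - mx)))
    ll <- sum(lse)
    resp <- exp(ld - lse)
    nk <- colSums(resp)
    if (any(nk < d + 1)) { # collapsed component: reseed it
      j <- which.min(nk)
      means[j, ] <- X[sample.int(n, 1), ]
      covs[[j]] <- base_cov
      next
    }
    wts <- nk / n
    for (j in seq_len(k)) {
      means[j, ] <- colSums(resp[, j] * X) / nk[j]
      diff <- sweep(X, 2, means[j, ])
      covs[[j]] <- crossprod(diff * sqrt(resp[, j])) / nk[j] + diag(ridge, d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(means = means, covs = covs, weights = wts, loglik = ll)
}

#' Fit a Gaussian mixture by EM with seeded random restarts
#'
#' Full-covariance EM, `restarts` random initialisations (means drawn from
#' the data); the fit with the best evidence (total data log-likelihood) is
#' returned.
#'
#' @param embeddings n x d matrix of latent coordinates.
#' @param k number of components (default 10).
#' @param restarts number of random restarts (default 100).
#' @param seed integer seed; identical seeds give identical fits.
#' @param tol relative log-likelihood convergence tolerance (1e-4).
#' @return object of class `aptvae_gmm`: `means` (k x d), `covs` (list of
#'   d x d), `weights`, `loglik` (best evidence), `logliks` (all restarts),
#'   `cluster` (hard assignment of the input points).
#' @export
fit_gmm <- function(embeddings, k = 10, restarts = 100, seed = 1L,
                    tol = 1e-4) {
  X <- as.matrix(embeddings)
  if (nrow(X) < k) stop("fewer points than mixture components", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  lls <- numeric(restarts)
  for (r in seq_len(restarts)) {
    fit <- gmm_em_once(X, k, tol = tol)
    lls[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ld <- vapply(seq_len(k),
               function(j) mvn_log_density(X, best$means[j, ], best$covs[[j]]) +
                 log(best$weights[j]),
               numeric(nrow(X)))
  structure(list(means = best$means, covs = best$covs,
                 weights = best$weights, loglik = best$loglik,
                 logliks = lls, k = k,
                 cluster = max.col(ld, ties.method = "first")),
            class = "aptvae_gmm")
}

#' @export
print.aptvae_gmm <- function(x, ...) {
  cat("Gaussian mixture:", x$k, "components, best evidence",
      signif(x$loglik, 6), "over", length(x$logliks), "restarts\n")
  invisible(x)
}

#' Decode GMM centers into candidate sequences
#'
#' Each mixture center is decoded into a profile HMM and reconstituted into
#' its most probable sequence; the table is ordered by component index.
#'
#' @param gmm an [fit_gmm()] result.
#' @param vae a trained VAE with profile-HMM decoder.
#' @param max_candidates,seed passed to [reconstitute()].
#' @param training_sequences optional character vector; when given, each
#'   candidate's minimum edit distance to the training set is reported.
#' @return data.frame: `component`, latent coordinates `z1..zd`,
#'   `sequence`, `log_prob`, and optionally `min_edit_distance`. The decoded
#'   models are attached as `attr(, "models")`.
#' @export
centers_to_candidates <- function(gmm, vae, max_candidates = 256, seed = 1L,
                                  training_sequences = NULL) {
  models <- decode_profile_hmm(vae, gmm$means)
  rows <- lapply(seq_len(nrow(gmm$means)), function(j) {
    rec <- reconstitute(models[[j]], max_candidates = max_candidates,
                        seed = seed + j)
    data.frame(component = j, sequence = rec$sequence,
               log_prob = rec$log_prob, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  zcols <- as.data.frame(gmm$means)
  names(zcols) <- paste0("z", seq_len(ncol(gmm$means)))
  out <- cbind(out[, "component", drop = FALSE], zcols,
               out[, c("sequence", "log_prob")])
  if (!is.null(training_sequences))
    out$min_edit_distance <- vapply(out$sequence, function(s)
      min(utils::adist(s, training_sequences)), numeric(1), USE.NAMES = FALSE)
  attr(out, "models") <- models
  out
}

#' Re-embed sequences into the latent space
#'
#' Posterior means of the encoder (no sampling); deterministic.
#' @param vae a trained VAE.
#' @param seqs character vector of sequences.
#' @return n x d matrix of latent coordinates.
#' @export
re_embed <- function(vae, seqs) {
  encode(vae, seqs)$mu
}

# ---- Gaussian process + batch proposal ----------------------------------

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

gp_fit <- function(Z, y, n_starts = 5) {
  D <- as.matrix(stats::dist(Z))
  n <- length(y)
  nll <- function(par) {
    ell <- exp(par[1]); s2 <- exp(par[2]); nug <- exp(par[3])
    K <- s2 * matern52(D, ell) + diag(nug + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    0.5 * sum(y * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  span <- max(D)
  starts <- expand.grid(l = log(span * c(0.05, 0.2, 0.5)),
                        s = c(0, log(2)), n = log(c(0.05, 0.2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = c(log(span * 1e-3), -8, log(1e-6)),
                   upper = c(log(span * 10), 6, 2)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  par <- best$par
  ell <- exp(par[1]); s2 <- exp(par[2]); nug <- exp(par[3])
  K <- s2 * matern52(D, ell) + diag(nug + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  list(Z = Z, y = y, ell = ell, s2 = s2, nug = nug, chol = ch, alpha = alpha)
}

gp_predict <- function(gp, Znew) {
  Dx <- sqrt(outer(rowSums(Znew^2), rowSums(gp$Z^2), "+") -
               2 * Znew %*% t(gp$Z))
  Dx[Dx < 0 | is.nan(Dx)] <- 0
  Ks <- gp$s2 * matern52(Dx, gp$ell)
  mu <- as.vector(Ks %*% gp$alpha)
  v <- backsolve(gp$chol, t(Ks), transpose = TRUE)
  var <- pmax(gp$s2 - colSums(v^2), 1e-12)
  list(mean = mu, sd = sqrt(var))
}

#' Propose a batch of latent points by Bayesian optimization
#'
#' Fits a Gaussian-process regression (Matern 5/2 kernel, hyperparameters by
#' marginal likelihood) of relative binding activity on latent coordinates,
#' and proposes `batch` points sequentially by maximizing the GP upper
#' confidence bound (`mu + beta * sd`, beta = 2) multiplied by a local
#' penalization factor around each already-selected point, so that the
#' batch spreads instead of collapsing onto one optimum. The penalization
#' radius derives from an estimated Lipschitz constant of the GP mean.
#'
#' @param observations data.frame or matrix whose first d columns are latent
#'   coordinates and whose last column is the relative binding activity
#'   (percent of positive control; standardized internally).
#' @param batch number of proposals (default 10).
#' @param seed integer seed (grid jitter / degenerate fallbacks).
#' @param bounds optional 2 x d matrix (rows: lower, upper); defaults to the
#'   bounding box of the observed coordinates expanded by 10%.
#' @param beta UCB exploration weight (default 2).
#' @param grid_n acquisition search grid resolution per dimension (d = 2).
#' @return list of class `aptvae_bo`: `proposals` (batch x d), `acquisition`
#'   (penalized acquisition at selection time), `acquisition_raw`
#'   (unpenalized), `gp`, `bounds`, `penalization` (trace of per-step
#'   penalizer minima).
#' @export
bo_propose <- function(observations, batch = 10, seed = 1L, bounds = NULL,
                       beta = 2, grid_n = 60) {
  obs <- as.matrix(observations)
  if (nrow(obs) < 2) stop("need at least 2 activity observations",
                          call. = FALSE)
  d <- ncol(obs) - 1
  Z <- obs[, seq_len(d), drop = FALSE]
  y <- obs[, d + 1]
  ysd <- stats::sd(y)
  ys <- if (ysd > 0) (y - mean(y)) / ysd else y * 0 # degenerate: pure exploration
  if (is.null(bounds)) {
    lo <- apply(Z, 2, min); hi <- apply(Z, 2, max)
    pad <- 0.1 * pmax(hi - lo, 1e-6)
    bounds <- rbind(lo - pad, hi + pad)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  gp <- gp_fit(Z, ys)
  grid <- as.matrix(expand.grid(lapply(seq_len(d), function(j)
    seq(bounds[1, j], bounds[2, j], length.out = grid_n))))
  pred <- gp_predict(gp, grid)
  acq_raw <- pred$mean + beta * pred$sd
  # Lipschitz constant of the GP mean, from finite differences on the grid
  h <- (bounds[2, ] - bounds[1, ]) / (grid_n - 1)
  Lhat <- max(1e-6, max(abs(diff(pred$mean)) / max(h)))
  Mhat <- max(ys)
  softplus <- function(a) log1p(exp(pmin(a, 30)))
  chosen <- matrix(NA_real_, batch, d)
  acq_sel <- numeric(batch); acq_sel_raw <- numeric(batch)
  pen_min <- numeric(batch)
  pen <- rep(1, nrow(grid))
  for (b in seq_len(batch)) {
    a_pen <- softplus(acq_raw) * pen
    pick <- which.max(a_pen)
    chosen[b, ] <- grid[pick, ]
    acq_sel[b] <- a_pen[pick]
    acq_sel_raw[b] <- softplus(acq_raw)[pick]
    pp <- gp_predict(gp, chosen[b, , drop = FALSE])
    r <- sqrt(rowSums(sweep(grid, 2, chosen[b, ])^2))
    zpen <- (Lhat * r - Mhat + pp$mean) / sqrt(2 * pp$sd^2 + 1e-12)
    pen <- pen * stats::pnorm(zpen)
    pen_min[b] <- min(stats::pnorm(zpen))
  }
  structure(list(proposals = chosen, acquisition = acq_sel,
                 acquisition_raw = acq_sel_raw, gp = gp, bounds = bounds,
                 penalization = pen_min, lipschitz = Lhat),
            class = "aptvae_bo")
}

#' @export
print.aptvae_bo <- function(x, ...) {
  cat("Bayesian-optimization proposal batch of", nrow(x$proposals),
      "latent points (GP-UCB + local penalization)\n")
  invisible(x)
}
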