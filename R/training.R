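# ELBO objective, regularization schedules and the training loop.
#
# The minimized loss per example is
#   recon NLL (single reparameterized z sample)
#   + kl_scale(epoch) * KL(q(z|x) || N(0, I))
#   - sum_i L_M(p_i)          (profile-HMM decoder only, epochs e < R)
# where L_M is the Dirichlet log-odds transition regularizer pushing early
# training toward match-to-match transitions.

#' KL annealing scale
#'
#' The KL term of the loss is scaled by `e/E` during the first `E` epochs
#' and by 1 afterwards (epoch counter starts at 0).
#' @param e epoch (0-based).
#' @param E number of annealing epochs (default 50).
#' @export
kl_scale <- function(e, E = 50) pmin(e / E, 1)

#' Closed-form KL divergence from a diagonal Gaussian to the standard normal
#'
#' @param mu mean vector or N x d matrix.
#' @param logvar log-variance, same shape.
#' @return per-example KL (scalar or length-N vector), in nats.
#' @export
gaussian_kl <- function(mu, logvar) {
  if (is.null(dim(mu))) return(0.5 * sum(mu^2 + exp(logvar) - 1 - logvar))
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

#' Dirichlet transition regularizer for one match state
#'
#' The log-odds of the transition distribution under a Dirichlet prior
#' `alpha = (1 + w_m, 1, 1)` relative to the flat prior:
#' `L_M(p_i) = log( (2 + w_m)(1 + w_m)/2 * a_MM^{w_m} )` with
#' `w_m = 4 (1 - e/R)`. It is identically zero from epoch `R` on. During
#' training the summed `L_M` is added to the ELBO (subtracted from the
#' loss), rewarding match-to-match transitions early on.
#'
#' @param p_i length-3 transition distribution `(a_MM, a_MI, a_MD)` out of a
#'   match state.
#' @param e epoch (0-based).
#' @param R epoch at which the regularizer reaches zero (default 50).
#' @return scalar `L_M`.
#' @export
transition_regularizer <- function(p_i, e, R = 50) {
  stopifnot(length(p_i) == 3, abs(sum(p_i) - 1) < 1e-6)
  if (e >= R) return(0)
  w <- 4 * (1 - e / R)
  log((2 + w) * (1 + w) / 2) + w * max(log(p_i[1]), LOG_FLOOR)
}

#' Training configuration
#'
#' @param max_epochs cap on epochs (default 2000).
#' @param patience early stopping: stop when the test loss has not improved
#'   for this many epochs (default 50).
#' @param kl_anneal_E KL annealing horizon `E` (default 50 epochs).
#' @param transition_reg_R epoch `R` at which the transition regularizer
#'   reaches zero (default 50; profile-HMM decoder only).
#' @param split_fraction train fraction of the 9:1 train/test split.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate (Adam is used with default parameters
#'   otherwise).
#' @param seed seed controlling the split, shuffling and reparameterization
#'   noise.
#' @export
training_config <- function(max_epochs = 2000, patience = 50,
                            kl_anneal_E = 50, transition_reg_R = 50,
                            split_fraction = 0.9, batch_size = 512,
                            lr = 1e-3, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1, patience <= max_epochs,
            kl_anneal_E >= 1, transition_reg_R >= 1)
  list(max_epochs = max_epochs, patience = patience,
       kl_anneal_E = kl_anneal_E, transition_reg_R = transition_reg_R,
       split_fraction = split_fraction, batch_size = batch_size, lr = lr,
       seed = as.integer(seed))
}

# Loss and (optionally) gradients on one batch.
# X: N x L codes (0-padded), lens: lengths, eps: N x d noise (or NULL for
# z = mu). Returns termwise means and per-parameter gradients.
vae_loss_grad <- function(vae, X, lens, epoch, config, eps = NULL,
                          want_grad = TRUE) {
  N <- nrow(X)
  enc_out <- encoder_forward(vae$enc, X, vae$K %||% 3L, cache = want_grad)
  mu <- enc_out$mu; lv <- enc_out$logvar
  if (is.null(eps)) eps <- matrix(0, N, vae$d)
  z <- mu + exp(0.5 * lv) * eps
  s <- kl_scale(epoch, config$kl_anneal_E)
  kl <- gaussian_kl(mu, lv)
  reg_mean <- 0
  dz <- NULL; gdec <- NULL
  if (vae$kind == "profile_hmm") {
    m <- vae$m
    fwd <- dec_phmm_forward(vae$dec, z, m)
    st <- list(mat = t(X), lens = lens)
    res <- phmm_forward_cpp(lp_to_cube(fwd$lpE, 4, m),
                            lp_to_cube(fwd$lpM, 3, m + 1),
                            lp_to_cube(fwd$lpI, 2, m + 1),
                            lp_to_cube(fwd$lpD, 2, m),
                            st$mat, lens, want_grad)
    nll <- -res$logp
    # transition regularizer over match positions i = 1..m
    if (epoch < config$transition_reg_R) {
      w <- 4 * (1 - epoch / config$transition_reg_R)
      aMM_cols <- (0:(m - 1)) * 3 + 1
      laMM <- fwd$lpM[, aMM_cols, drop = FALSE]
      LM <- log((2 + w) * (1 + w) / 2) + w * laMM
      reg_n <- -rowSums(LM)
      reg_mean <- mean(reg_n)
    } else w <- 0
    if (want_grad) {
      gE <- -cube_to_lp(res$gle, 4, m) / N
      gM <- -cube_to_lp(res$gtM, 3, m + 1) / N
      gI <- -cube_to_lp(res$gtI, 2, m + 1) / N
      gD <- -cube_to_lp(res$gtD, 2, m) / N
      if (w > 0) gM[, aMM_cols] <- gM[, aMM_cols] - w / N
      bk <- dec_phmm_backward(vae$dec, fwd, gE, gM, gI, gD, m)
      gdec <- bk$g; dz <- bk$dz
    }
  } else if (vae$kind == "multicategorical") {
    L <- vae$max_len
    fwd <- dec_mc_forward(vae$dec, z, L)
    gather <- matrix(0, N, L * 4)
    nll <- numeric(N)
    for (n in seq_len(N)) {
      ln <- lens[n]
      cols <- (seq_len(ln) - 1) * 4 + X[n, seq_len(ln)]
      nll[n] <- -sum(fwd$lp[n, cols])
      gather[n, cols] <- 1
    }
    if (want_grad) {
      bk <- dec_mc_backward(vae$dec, fwd, -gather / N)
      gdec <- bk$g; dz <- bk$dz
    }
  } else {
    fwd <- dec_ar_forward(vae$dec, z, X, lens, cache = want_grad)
    nll <- fwd$nll
    if (want_grad) {
      bk <- dec_ar_backward(vae$dec, fwd, z, scale = 1 / N)
      gdec <- bk$g; dz <- bk$dz
    }
  }
  out <- list(recon = mean(nll), kl = mean(kl), reg = reg_mean,
              scale = s, loss = mean(nll) + s * mean(kl) + reg_mean,
              mu = mu, logvar = lv)
  if (want_grad) {
    dmu <- dz + s * mu / N
    dlv <- dz * eps * 0.5 * exp(0.5 * lv) + s * 0.5 * (exp(lv) - 1) / N
    out$genc <- encoder_backward(vae$enc, enc_out$cache, dmu, dlv)
    out$gdec <- gdec
  }
  out
}

#' Per-batch ELBO loss
#'
#' Termwise negative-ELBO evaluation: reconstruction negative log-likelihood
#' (single reparameterized sample, or at `z = mu` when `sample = FALSE`),
#' KL-annealed regularization term, and the transition regularizer
#' (profile-HMM decoder only). All terms are per-sequence means in nats.
#'
#' @param vae an `aptvae_vae`.
#' @param seqs character vector or coded list of sequences.
#' @param epoch 0-based epoch, determining both schedules.
#' @param config a [training_config()].
#' @param sample draw a reparameterized z (uses the current RNG state)?
#' @return list with `loss`, `recon`, `kl`, `reg`, `scale`;
#'   `loss = recon + scale * kl + reg` exactly.
#' @export
elbo_loss <- function(vae, seqs, epoch, config = training_config(),
                      sample = TRUE) {
  codes <- coerce_codes(seqs)
  st <- stack_sequences(codes, max_len = vae$max_len)
  X <- t(st$mat)
  eps <- if (sample) matrix(stats::rnorm(nrow(X) * vae$d), ncol = vae$d)
  res <- vae_loss_grad(vae, X, st$lens, epoch, config, eps, want_grad = FALSE)
  res[c("loss", "recon", "kl", "reg", "scale")]
}

#' Train a sequence VAE
#'
#' Seeded 9:1 train/test split, Adam with default parameters, KL annealing
#' and (for the profile-HMM decoder) the Dirichlet transition regularizer.
#' Training stops after `max_epochs` or when the test loss has not reached
#' a new minimum for `patience` epochs; the returned model is the snapshot
#' with the smallest test loss, not the final epoch. The early-stopping
#' metric is the test negative ELBO at full KL weight, without the
#' transition regularizer.
#'
#' @param seqs character vector of training sequences (already filtered /
#'   unique).
#' @param vae an [vae_init()] VAE.
#' @param config a [training_config()].
#' @param verbose print progress every 25 epochs.
#' @return list with `vae` (best snapshot), `record` (per-epoch data.frame:
#'   epoch, train loss/recon/kl/reg/scale, test loss/recon/kl), and
#'   `best_epoch`.
#' @export
train_vae <- function(seqs, vae, config = training_config(),
                      verbose = FALSE) {
  codes <- coerce_codes(seqs)
  if (length(codes) == 0) stop("empty dataset", call. = FALSE)
  st <- stack_sequences(codes, max_len = vae$max_len)
  X <- t(st$mat); lens <- st$lens
  N <- nrow(X)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  ntr <- floor(config$split_fraction * N)
  if (ntr == 0 || ntr == N)
    stop("train/test split would leave an empty part", call. = FALSE)
  perm <- sample.int(N)
  tr <- perm[seq_len(ntr)]; te <- perm[(ntr + 1):N]
  ad_enc <- adam_init(vae$enc); ad_dec <- adam_init(vae$dec)
  best <- list(loss = Inf, enc = vae$enc, dec = vae$dec, epoch = -1L)
  rec <- vector("list", config$max_epochs)
  since_best <- 0L
  for (e in 0:(config$max_epochs - 1)) {
    ord <- sample(tr)
    nb <- ceiling(length(ord) / config$batch_size)
    tr_recon <- tr_kl <- tr_reg <- 0
    for (b in seq_len(nb)) {
      ii <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                      length(ord))]
      eps <- matrix(stats::rnorm(length(ii) * vae$d), ncol = vae$d)
      res <- vae_loss_grad(vae, X[ii, , drop = FALSE], lens[ii], e, config,
                           eps, want_grad = TRUE)
      upd <- adam_step(vae$enc, res$genc, ad_enc, lr = config$lr)
      vae$enc <- upd$params; ad_enc <- upd$state
      upd <- adam_step(vae$dec, res$gdec, ad_dec, lr = config$lr)
      vae$dec <- upd$params; ad_dec <- upd$state
      wt <- length(ii) / length(ord)
      tr_recon <- tr_recon + wt * res$recon
      tr_kl <- tr_kl + wt * res$kl
      tr_reg <- tr_reg + wt * res$reg
    }
    s <- kl_scale(e, config$kl_anneal_E)
    eps_te <- matrix(stats::rnorm(length(te) * vae$d), ncol = vae$d)
    tst <- vae_loss_grad(vae, X[te, , drop = FALSE], lens[te], e, config,
                         eps_te, want_grad = FALSE)
    test_loss <- tst$recon + tst$kl # full ELBO, no regularizer
    rec[[e + 1]] <- data.frame(
      epoch = e, train_loss = tr_recon + s * tr_kl + tr_reg,
      train_recon = tr_recon, train_kl = tr_kl, train_reg = tr_reg,
      kl_scale = s, test_loss = test_loss, test_recon = tst$recon,
      test_kl = tst$kl)
    if (test_loss < best$loss) {
      best <- list(loss = test_loss, enc = vae$enc, dec = vae$dec,
                   epoch = e)
      since_best <- 0L
    } else since_best <- since_best + 1L
    if (verbose && e %% 25 == 0)
      message(sprintf("epoch %d: train %.3f test %.3f (best %.3f @%d)",
                      e, rec[[e + 1]]$train_loss, test_loss, best$loss,
                      best$epoch))
    if (since_best >= config$patience) break
  }
  vae$enc <- best$enc; vae$dec <- best$dec
  list(vae = vae, record = do.call(rbind, rec[!vapply(rec, is.null, TRUE)]),
       best_epoch = best$epoch, best_test_loss = best$loss)
}

#' Write a training log as TSV
#' @param record the `record` element returned by [train_vae()].
#' @param path file path.
#' @export
write_training_log <- function(record, path) {
  utils::write.table(record, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
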