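# Encoder and decoder networks mapping between sequences and the latent
# space. All nets are plain matrix arithmetic with hand-written backward
# passes (see the methods vignette for the architecture rationale).
#
# Encoder: per-letter 32-channel embedding -> seven 1-D convolution blocks
# (kernel width 7, layer norm, ReLU, additive skip connection) -> masked
# max pooling over positions -> fully connected layer -> (mu, logvar) heads.
#
# Decoders:
#  * profile_hmm: MLP from z to a valid ProfileHMM (softmax-normalized
#    emission rows and per-state transition distributions).
#  * multicategorical: MLP from z to an L x 4 position-wise categorical.
#  * autoregressive: recurrent net conditioned on z emitting letter-by-letter
#    distributions over {A,C,G,U,end}.

PAD_CODE <- 5L
AR_START <- 5L
AR_END <- 5L

#' Initialise a sequence VAE
#'
#' @param decoder one of `"profile_hmm"`, `"multicategorical"`,
#'   `"autoregressive"`.
#' @param max_len maximum (padded) sequence length the encoder accepts.
#' @param d latent dimension (default 2, configurable 1..12).
#' @param m profile-HMM model length; defaults to `max_len`. A shorter `m`
#'   gives the truncated-decoder mode.
#' @param channels encoder channel count (32).
#' @param kernel odd convolution kernel width (default 7).
#' @param hidden decoder hidden width (32).
#' @param seed integer seed for parameter initialisation.
#' @return an object of class `aptvae_vae`.
#' @export
vae_init <- function(decoder = c("profile_hmm", "multicategorical",
                                 "autoregressive"),
                     max_len, d = 2, m = max_len, channels = 32L,
                     kernel = 7L, hidden = 32L, seed = 1L) {
  decoder <- match.arg(decoder)
  stopifnot(d >= 1, d <= 12, max_len >= 1)
  if (decoder == "profile_hmm" && m < 1) stop("m must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  stopifnot(kernel %% 2 == 1)
  C <- channels; H <- hidden
  enc <- list(Emb = he_init(5, C, fan_in = 5))
  for (i in 1:7) {
    enc[[paste0("W", i)]] <- he_init(kernel * C, C)
    enc[[paste0("g", i)]] <- rep(1, C) # layer-norm gain
    enc[[paste0("b", i)]] <- rep(0, C) # layer-norm shift
  }
  enc$Wf <- he_init(C, H); enc$bf <- rep(0, H)
  enc$Wmu <- he_init(H, d, fan_in = H) * 0.1; enc$bmu <- rep(0, d)
  enc$Wlv <- he_init(H, d, fan_in = H) * 0.1; enc$blv <- rep(0, d)
  dec <- if (decoder == "autoregressive") list() else
    list(W1 = he_init(d, H, fan_in = d), b1 = rep(0, H),
         W2 = he_init(H, H), b2 = rep(0, H))
  if (decoder == "profile_hmm") {
    dec$We <- he_init(H, m * 4) * 0.1; dec$be <- rep(0, m * 4)
    dec$WtM <- he_init(H, (m + 1) * 3) * 0.1; dec$btM <- rep(0, (m + 1) * 3)
    dec$WtI <- he_init(H, (m + 1) * 2) * 0.1; dec$btI <- rep(0, (m + 1) * 2)
    dec$WtD <- he_init(H, m * 2) * 0.1; dec$btD <- rep(0, m * 2)
  } else if (decoder == "multicategorical") {
    dec$Wo <- he_init(H, max_len * 4) * 0.1; dec$bo <- rep(0, max_len * 4)
  } else {
    dec$Wx <- he_init(5, H, fan_in = 5); dec$Wz <- he_init(d, H, fan_in = d)
    dec$Wh <- matrix(stats::rnorm(H * H, sd = 1 / sqrt(H)), H, H)
    dec$bh <- rep(0, H)
    dec$Wo <- he_init(H, 5) * 0.1; dec$bo <- rep(0, 5)
  }
  structure(list(kind = decoder, d = d,
                 m = if (decoder == "profile_hmm") as.integer(m) else NA,
                 max_len = as.integer(max_len), C = C, K = as.integer(kernel),
                 H = H, enc = enc, dec = dec, seed = seed),
            class = "aptvae_vae")
}

#' @export
print.aptvae_vae <- function(x, ...) {
  cat("Sequence VAE: decoder =", x$kind, "| latent d =", x$d,
      if (x$kind == "profile_hmm") paste("| model length m =", x$m),
      "| max_len =", x$max_len, "\n")
  invisible(x)
}

# ---- encoder -------------------------------------------------------------

# X: N x L integer codes 1..4, 0 for padding. Returns mu, logvar (N x d)
# and, if cache, everything needed for the backward pass.
#
# Activations live as (N*L) x C matrices with position-major, sequence-minor
# row order (row (l-1)*N + n holds position l of sequence n), so the K-tap
# convolution is K GEMMs against row-shifted views and no 3-D array
# reshaping is needed.

enc_conv_cube <- function(enc, K) {
  C <- ncol(enc$Emb)
  W <- array(0, c(K * C, C, 7)); G <- matrix(0, C, 7); B <- matrix(0, C, 7)
  for (i in 1:7) {
    W[, , i] <- enc[[paste0("W", i)]]
    G[, i] <- enc[[paste0("g", i)]]
    B[, i] <- enc[[paste0("b", i)]]
  }
  list(W = W, G = G, B = B)
}

encoder_forward <- function(enc, X, K, cache = TRUE) {
  N <- nrow(X); L <- ncol(X); C <- ncol(enc$Emb); NL <- N * L
  Xp <- X; Xp[Xp == 0L] <- PAD_CODE
  pad <- X == 0L
  M0 <- enc$Emb[as.vector(Xp), , drop = FALSE] # (N*L) x C
  cw <- enc_conv_cube(enc, K)
  cv <- conv_stack_fwd_cpp(M0, cw$W, cw$G, cw$B, N, K, cache)
  M <- cv$M
  # masked max pooling over positions
  pooled <- matrix(0, N, C); idx <- matrix(1L, N, C)
  anypad <- any(pad)
  for (c in seq_len(C)) {
    Mc <- matrix(M[, c], N, L)
    if (anypad) Mc[pad] <- -Inf
    ic <- max.col(Mc, ties.method = "first")
    idx[, c] <- ic
    pooled[, c] <- Mc[cbind(seq_len(N), ic)]
  }
  hpre <- add_bias(pooled %*% enc$Wf, enc$bf)
  hmask <- hpre > 0
  h <- hpre * hmask
  mu <- add_bias(h %*% enc$Wmu, enc$bmu)
  lv <- add_bias(h %*% enc$Wlv, enc$blv)
  out <- list(mu = mu, logvar = lv)
  if (cache)
    out$cache <- list(Xp = Xp, Ms = cv$Ms, XH = cv$XH, masks = cv$masks,
                      ISD = cv$ISD, cw = cw, K = K, idx = idx,
                      pooled = pooled, hmask = hmask, h = h,
                      N = N, L = L, C = C)
  out
}

encoder_backward <- function(enc, cache, dmu, dlv) {
  N <- cache$N; L <- cache$L; C <- cache$C; NL <- N * L
  g <- list()
  g$Wmu <- crossprod(cache$h, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(cache$h, dlv); g$blv <- colSums(dlv)
  dh <- (dmu %*% t(enc$Wmu) + dlv %*% t(enc$Wlv)) * cache$hmask
  g$Wf <- crossprod(cache$pooled, dh); g$bf <- colSums(dh)
  dP <- dh %*% t(enc$Wf)
  # route pooled gradients back to the argmax positions
  dM <- matrix(0, NL, C)
  lin <- rep.int((seq_len(C) - 1L) * NL, rep.int(N, C)) +
    as.vector((cache$idx - 1L) * N + seq_len(N))
  dM[lin] <- as.vector(dP)
  bk <- conv_stack_bwd_cpp(dM, cache$Ms, cache$XH, cache$masks, cache$ISD,
                           cache$cw$W, cache$cw$G, N, cache$K)
  for (i in 1:7) {
    g[[paste0("W", i)]] <- bk$gW[, , i]
    g[[paste0("g", i)]] <- bk$gG[, i]
    g[[paste0("b", i)]] <- bk$gB[, i]
  }
  dEmbrows <- rowsum(bk$dM, group = as.vector(cache$Xp))
  g$Emb <- matrix(0, 5, C)
  g$Emb[as.integer(rownames(dEmbrows)), ] <- dEmbrows
  g
}

#' Encode sequences into the latent posterior
#'
#' @param vae an [vae_init()] object (typically trained).
#' @param seqs character vector of sequences, or list of integer codes.
#' @return list with `mu` and `logvar`, both N x d matrices: the diagonal
#'   Gaussian posterior q(z|x) per sequence. Deterministic given parameters.
#' @export
encode <- function(vae, seqs) {
  codes <- coerce_codes(seqs)
  st <- stack_sequences(codes, max_len = vae$max_len)
  out <- encoder_forward(vae$enc, t(st$mat), vae$K %||% 3L, cache = FALSE)
  list(mu = out$mu, logvar = out$logvar)
}

# ---- profile-HMM decoder -------------------------------------------------

phmm_masks <- function(m) {
  mM <- rep(0, (m + 1) * 3); mM[m * 3 + 3] <- -Inf   # M_m -> D_{m+1}
  mD <- rep(0, m * 2); mD[(m - 1) * 2 + 2] <- -Inf   # D_m -> D_{m+1}
  list(mM = mM, mD = mD)
}

dec_mlp_forward <- function(dec, z) {
  h1pre <- add_bias(z %*% dec$W1, dec$b1); h1 <- relu(h1pre)
  h2pre <- add_bias(h1 %*% dec$W2, dec$b2); h2 <- relu(h2pre)
  list(h1 = h1, h2 = h2, m1 = h1pre > 0, m2 = h2pre > 0, z = z)
}

dec_mlp_backward <- function(dec, cache, dh2) {
  g <- list()
  dh2 <- dh2 * cache$m2
  g$W2 <- crossprod(cache$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(dec$W2)) * cache$m1
  g$W1 <- crossprod(cache$z, dh1); g$b1 <- colSums(dh1)
  list(g = g, dz = dh1 %*% t(dec$W1))
}

# z: N x d. Returns log-probability matrices in block layout plus cache.
dec_phmm_forward <- function(dec, z, m) {
  cc <- dec_mlp_forward(dec, z)
  msk <- phmm_masks(m)
  lpE <- block_log_softmax(add_bias(cc$h2 %*% dec$We, dec$be), 4)
  lpM <- block_log_softmax(add_bias(cc$h2 %*% dec$WtM, dec$btM), 3, msk$mM)
  lpI <- block_log_softmax(add_bias(cc$h2 %*% dec$WtI, dec$btI), 2)
  lpD <- block_log_softmax(add_bias(cc$h2 %*% dec$WtD, dec$btD), 2, msk$mD)
  list(lpE = lpE, lpM = lpM, lpI = lpI, lpD = lpD, cache = cc, msk = msk)
}

# gE.. are gradients of the loss w.r.t. the log-probabilities.
dec_phmm_backward <- function(dec, fwd, gE, gM, gI, gD, m) {
  dSe <- block_log_softmax_bwd(gE, fwd$lpE, 4)
  dSm <- block_log_softmax_bwd(gM, fwd$lpM, 3, fwd$msk$mM)
  dSi <- block_log_softmax_bwd(gI, fwd$lpI, 2)
  dSd <- block_log_softmax_bwd(gD, fwd$lpD, 2, fwd$msk$mD)
  h2 <- fwd$cache$h2
  g <- list(We = crossprod(h2, dSe), be = colSums(dSe),
            WtM = crossprod(h2, dSm), btM = colSums(dSm),
            WtI = crossprod(h2, dSi), btI = colSums(dSi),
            WtD = crossprod(h2, dSd), btD = colSums(dSd))
  dh2 <- dSe %*% t(dec$We) + dSm %*% t(dec$WtM) + dSi %*% t(dec$WtI) +
    dSd %*% t(dec$WtD)
  mlp <- dec_mlp_backward(dec, fwd$cache, dh2)
  list(g = c(g, mlp$g), dz = mlp$dz)
}

# Convert block-layout log-prob matrices (one row per z) to the (.., N)
# cubes the C++ kernel consumes, and back for gradients.
lp_to_cube <- function(lp, B, G) array(t(lp), c(B, G, nrow(lp)))
cube_to_lp <- function(cb, B, G) t(matrix(cb, B * G, dim(cb)[3]))

#' Decode latent points into profile HMMs
#'
#' Neural map from latent coordinates to valid profile HMMs: match-emission
#' rows and every state's outgoing transition distribution are normalized
#' exponentials, so all model invariants hold by construction.
#'
#' @param vae a VAE with `profile_hmm` decoder.
#' @param z numeric matrix (n x d) or vector (one point) of latent
#'   coordinates.
#' @return a list of [profile_hmm()] objects (length `nrow(z)`).
#' @export
decode_profile_hmm <- function(vae, z) {
  stopifnot(vae$kind == "profile_hmm")
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopifnot(ncol(z) == vae$d, all(is.finite(z)))
  m <- vae$m
  fwd <- dec_phmm_forward(vae$dec, z, m)
  lapply(seq_len(nrow(z)), function(n) {
    e <- matrix(exp(fwd$lpE[n, ]), m, 4, byrow = TRUE)
    tm <- matrix(exp(fwd$lpM[n, ]), m + 1, 3, byrow = TRUE)
    ti <- matrix(exp(fwd$lpI[n, ]), m + 1, 2, byrow = TRUE)
    td <- matrix(exp(fwd$lpD[n, ]), m, 2, byrow = TRUE)
    tm[m + 1, 3] <- 0; td[m, 2] <- 0 # exact zeros for the masked edges
    profile_hmm(e / rowSums(e), tm / rowSums(tm), ti / rowSums(ti),
                td / rowSums(td))
  })
}

# ---- multicategorical decoder -------------------------------------------

dec_mc_forward <- function(dec, z, L) {
  cc <- dec_mlp_forward(dec, z)
  lp <- block_log_softmax(add_bias(cc$h2 %*% dec$Wo, dec$bo), 4)
  list(lp = lp, cache = cc)
}

dec_mc_backward <- function(dec, fwd, glp) {
  dS <- block_log_softmax_bwd(glp, fwd$lp, 4)
  g <- list(Wo = crossprod(fwd$cache$h2, dS), bo = colSums(dS))
  dh2 <- dS %*% t(dec$Wo)
  mlp <- dec_mlp_backward(dec, fwd$cache, dh2)
  list(g = c(g, mlp$g), dz = mlp$dz)
}

#' Decode latent points with the multicategorical decoder
#'
#' @param vae a VAE with `multicategorical` decoder.
#' @param z latent coordinates, n x d matrix or single vector.
#' @return list of L x 4 probability matrices (rows sum to 1), one per
#'   latent point.
#' @export
decode_multicategorical <- function(vae, z) {
  stopifnot(vae$kind == "multicategorical")
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  fwd <- dec_mc_forward(vae$dec, z, vae$max_len)
  lapply(seq_len(nrow(z)), function(n) {
    p <- matrix(exp(fwd$lp[n, ]), vae$max_len, 4, byrow = TRUE)
    colnames(p) <- RNA_LETTERS
    p / rowSums(p)
  })
}

# ---- autoregressive decoder ---------------------------------------------

# Teacher-forced pass computing per-sequence NLL including the end token.
# X: N x L codes (0 pad), lens: lengths. Steps t = 1..Tmax, input token
# x_{t-1} (start token at t = 1), target x_t or end at t = len+1.
dec_ar_forward <- function(dec, z, X, lens, cache = TRUE) {
  N <- nrow(X); L <- ncol(X); H <- ncol(dec$Wh)
  Tmax <- max(lens) + 1L
  zproj <- z %*% dec$Wz
  h <- matrix(0, N, H)
  nll <- numeric(N)
  hs <- if (cache) vector("list", Tmax)
  toks <- if (cache) matrix(1L, N, Tmax)
  lps <- if (cache) vector("list", Tmax)
  tgts <- if (cache) matrix(0L, N, Tmax)
  for (t in seq_len(Tmax)) {
    tok <- if (t == 1) rep(AR_START, N) else ifelse(t - 1 <= lens, X[, t - 1], 1L)
    pre <- dec$Wx[tok, , drop = FALSE] + zproj + h %*% dec$Wh
    pre <- add_bias(pre, dec$bh)
    h <- tanh(pre)
    logits <- add_bias(h %*% dec$Wo, dec$bo)
    lp <- block_log_softmax(logits, 5)
    tgt <- ifelse(t <= lens, X[, pmin(t, L)], ifelse(t == lens + 1, AR_END, 0L))
    act <- tgt > 0L
    nll[act] <- nll[act] - lp[cbind(which(act), tgt[act])]
    if (cache) { hs[[t]] <- h; toks[, t] <- tok; lps[[t]] <- lp; tgts[, t] <- tgt }
  }
  out <- list(nll = nll)
  if (cache)
    out$cache <- list(hs = hs, toks = toks, lps = lps, tgts = tgts,
                      zproj = zproj, Tmax = Tmax, N = N, H = H)
  out
}

# scale: multiplier on the summed NLL (e.g. 1/N for a batch mean).
dec_ar_backward <- function(dec, fwd, z, scale) {
  cc <- fwd$cache
  N <- cc$N; H <- cc$H; Tmax <- cc$Tmax
  g <- list(Wx = matrix(0, 5, H), Wz = matrix(0, nrow(dec$Wz), H),
            Wh = matrix(0, H, H), bh = rep(0, H),
            Wo = matrix(0, H, 5), bo = rep(0, 5))
  dz <- matrix(0, N, nrow(dec$Wz))
  dh_next <- matrix(0, N, H)
  for (t in Tmax:1) {
    lp <- cc$lps[[t]]
    tgt <- cc$tgts[, t]
    act <- tgt > 0L
    glp <- matrix(0, N, 5)
    glp[cbind(which(act), tgt[act])] <- -scale
    dlogits <- block_log_softmax_bwd(glp, lp, 5)
    h <- cc$hs[[t]]
    g$Wo <- g$Wo + crossprod(h, dlogits)
    g$bo <- g$bo + colSums(dlogits)
    dh <- dlogits %*% t(dec$Wo) + dh_next
    dpre <- dh * (1 - h * h)
    g$bh <- g$bh + colSums(dpre)
    g$Wz <- g$Wz + crossprod(z, dpre)
    dz <- dz + dpre %*% t(dec$Wz)
    hprev <- if (t > 1) cc$hs[[t - 1]] else matrix(0, N, H)
    g$Wh <- g$Wh + crossprod(hprev, dpre)
    dh_next <- dpre %*% t(dec$Wh)
    dWxrows <- rowsum(dpre, group = cc$toks[, t])
    g$Wx[as.integer(rownames(dWxrows)), ] <-
      g$Wx[as.integer(rownames(dWxrows)), ] + dWxrows
  }
  list(g = g, dz = dz)
}

#' Next-letter distribution of the autoregressive decoder
#'
#' @param vae a VAE with `autoregressive` decoder.
#' @param z a single latent coordinate (length-d vector).
#' @param prefix character string (possibly empty) of letters already
#'   emitted.
#' @return named probability vector over `A, C, G, U, end`.
#' @export
decode_autoregressive <- function(vae, z, prefix = "") {
  stopifnot(vae$kind == "autoregressive")
  dec <- vae$dec
  codes <- if (nchar(prefix) > 0) encode_rna(prefix)[[1]] else integer(0)
  zp <- matrix(z, 1) %*% dec$Wz
  h <- matrix(0, 1, ncol(dec$Wh))
  toks <- c(AR_START, codes)
  for (tok in toks) {
    pre <- add_bias(dec$Wx[tok, , drop = FALSE] + zp + h %*% dec$Wh, dec$bh)
    h <- tanh(pre)
  }
  logits <- add_bias(h %*% dec$Wo, dec$bo)
  p <- exp(block_log_softmax(logits, 5))[1, ]
  names(p) <- c(RNA_LETTERS, "end")
  p / sum(p)
}

#' Sequence log-likelihood under the autoregressive decoder
#'
#' Chain-rule sum of stepwise log-probabilities including the end token.
#' @param vae a VAE with `autoregressive` decoder.
#' @param z single latent coordinate.
#' @param seq character sequence.
#' @export
ar_log_likelihood <- function(vae, z, seq) {
  codes <- encode_rna(seq)[[1]]
  st <- stack_sequences(list(codes))
  -dec_ar_forward(vae$dec, matrix(z, 1), t(st$mat), st$lens, cache = FALSE)$nll
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load a VAE checkpoint (JSON)
#'
#' The checkpoint stores all parameters at full precision together with a
#' metadata block (decoder kind, m, d, alphabet, max length, seed).
#' @param vae an `aptvae_vae`.
#' @param path file path (".json").
#' @export
write_checkpoint <- function(vae, path) {
  ser <- function(p) lapply(p, function(a)
    list(dim = dim(a) %||% length(a), data = as.vector(a)))
  obj <- list(meta = list(kind = vae$kind, d = vae$d, m = vae$m,
                          max_len = vae$max_len, C = vae$C, K = vae$K,
                          H = vae$H, alphabet = RNA_LETTERS,
                          seed = vae$seed),
              enc = ser(vae$enc), dec = ser(vae$dec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(p) lapply(p, function(a) {
    d <- as.integer(a$dim)
    if (length(d) == 1) as.numeric(a$data) else array(as.numeric(a$data), d)
  })
  meta <- obj$meta
  structure(list(kind = meta$kind, d = meta$d,
                 m = if (is.null(meta$m) || is.na(meta$m)) NA else
                   as.integer(meta$m),
                 max_len = as.integer(meta$max_len), C = meta$C,
                 K = as.integer(meta$K %||% 3L), H = meta$H,
                 enc = de(obj$enc), dec = de(obj$dec), seed = meta$seed),
            class = "aptvae_vae")
}
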