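# Independent oracles used across tests. These deliberately avoid the
# package's dynamic-programming code paths: probabilities are accumulated by
# explicit recursive enumeration of state paths.

# Sum over all state paths emitting exactly `codes` (a path emitting exactly
# L letters has at most L insertion steps, so the enumeration is finite and
# exact).
brute_forward <- function(model, codes) {
  if (is.character(codes)) codes <- encode_rna(codes)[[1]]
  L <- length(codes); m <- model$m
  e <- model$match_emissions; tm <- model$t_match
  ti <- model$t_insert; td <- model$t_delete
  go <- function(kind, k, l) {
    p <- 0
    if (kind == "M") {
      if (k < m && l < L) p <- p + tm[k + 1, 1] * e[k + 1, codes[l + 1]] * go("M", k + 1, l + 1)
      if (k == m && l == L) p <- p + tm[k + 1, 1]
      if (l < L) p <- p + tm[k + 1, 2] * 0.25 * go("I", k, l + 1)
      if (k < m) p <- p + tm[k + 1, 3] * go("D", k + 1, l)
    } else if (kind == "I") {
      if (k < m && l < L) p <- p + ti[k + 1, 1] * e[k + 1, codes[l + 1]] * go("M", k + 1, l + 1)
      if (k == m && l == L) p <- p + ti[k + 1, 1]
      if (l < L) p <- p + ti[k + 1, 2] * 0.25 * go("I", k, l + 1)
    } else {
      if (k < m && l < L) p <- p + td[k, 1] * e[k + 1, codes[l + 1]] * go("M", k + 1, l + 1)
      if (k == m && l == L) p <- p + td[k, 1]
      if (k < m) p <- p + td[k, 2] * go("D", k + 1, l)
    }
    p
  }
  log(go("M", 0, 0))
}

# Max over all self-loop-free state paths of transition product times
# per-state max emission: the exhaustive counterpart of most_probable_path.
brute_best_path_score <- function(model) {
  m <- model$m
  tm <- model$t_match; ti <- model$t_insert; td <- model$t_delete
  maxe <- apply(model$match_emissions, 1, max)
  go <- function(kind, k) {
    best <- -Inf
    if (kind == "M") {
      if (k < m) best <- max(best, log(tm[k + 1, 1] * maxe[k + 1]) + go("M", k + 1))
      if (k == m) best <- max(best, log(tm[k + 1, 1]))
      best <- max(best, log(tm[k + 1, 2] * 0.25) + go("I", k))
      if (k < m) best <- max(best, log(tm[k + 1, 3]) + go("D", k + 1))
    } else if (kind == "I") {
      if (k < m) best <- max(best, log(ti[k + 1, 1] * maxe[k + 1]) + go("M", k + 1))
      if (k == m) best <- max(best, log(ti[k + 1, 1]))
    } else {
      if (k < m) best <- max(best, log(td[k, 1] * maxe[k + 1]) + go("M", k + 1))
      if (k == m) best <- max(best, log(td[k, 1]))
      if (k < m) best <- max(best, log(td[k, 2]) + go("D", k + 1))
    }
    best
  }
  go("M", 0)
}

# Random normalized profile HMM (Dirichlet(1) rows).
random_phmm <- function(m, seed) {
  set.seed(seed)
  rdir <- function(n, k) {
    x <- matrix(stats::rgamma(n * k, 1), n, k)
    x / rowSums(x)
  }
  e <- rdir(m, 4)
  tm <- rdir(m + 1, 3)
  tm[m + 1, ] <- c(tm[m + 1, 1:2] / sum(tm[m + 1, 1:2]), 0)
  ti <- rdir(m + 1, 2)
  td <- rdir(m, 2)
  td[m, ] <- c(1, 0)
  profile_hmm(e, tm, ti, td)
}

# All 4^K coded sequences of length K.
all_sequences <- function(K) {
  if (K == 0) return(list(integer(0)))
  lapply(seq_len(4^K), function(i) {
    v <- integer(K); x <- i - 1
    for (j in K:1) { v[j] <- x %% 4 + 1; x <- x %/% 4 }
    v
  })
}

# Log Dirichlet density, direct lgamma evaluation.
ldirichlet <- function(p, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(p))
}

# Profile HMM whose most probable path visits exactly q insertion states:
# every M_k -> I_k is dominant for k < q, pure match afterwards, and peaked
# emissions keep the match states on the path.
insertion_heavy_phmm <- function(m, q) {
  stopifnot(q <= m + 1)
  e <- matrix(0.01, m, 4); e[, 1] <- 0.97
  tm <- matrix(0, m + 1, 3)
  for (k in 0:m) {
    # insert detour must beat both the direct match transition and the
    # delete shortcut: a_MI/4 * a_IM ~ 0.23 per visit vs 0.04 and 0.01
    tm[k + 1, ] <- if (k < q) c(0.04, 0.95, 0.01) else c(0.9, 0.05, 0.05)
  }
  tm[m + 1, 3] <- 0
  tm <- tm / rowSums(tm)
  ti <- matrix(rep(c(0.95, 0.05), each = m + 1), m + 1, 2)
  td <- matrix(rep(c(0.9, 0.1), each = m), m, 2)
  td[m, ] <- c(1, 0)
  profile_hmm(e, tm, ti, td)
}

# tiny shim: evaluate the decoder exactly at z by zeroing the encoder heads
# and biasing mu to z
within_vae_at_z <- function(vae, z) {
  vae$enc$Wmu <- vae$enc$Wmu * 0
  vae$enc$Wlv <- vae$enc$Wlv * 0
  vae$enc$bmu <- z
  vae$enc$blv <- rep(-30, vae$d) # variance ~ 0 so z = mu deterministically
  vae
}

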