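# Encoder and decoder networks: contracts, validity, and gradient checks.

rand_seqs <- function(n, L, seed = 1) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                     collapse = ""))
}

test_that("encoder output has the contracted shape and is deterministic", {
  vae <- vae_init("profile_hmm", max_len = 20, m = 20, d = 2, seed = 3)
  seqs <- rand_seqs(5, 20)
  e1 <- encode(vae, seqs)
  expect_identical(dim(e1$mu), c(5L, 2L))
  expect_identical(dim(e1$logvar), c(5L, 2L))
  expect_true(all(is.finite(e1$logvar)))
  expect_identical(e1, encode(vae, seqs))
  # one-letter difference must move the embedding (non-degeneracy)
  s <- rand_seqs(1, 20, seed = 9)
  s2 <- paste0("A", substring(s, 2))
  if (identical(s, s2)) s2 <- paste0("C", substring(s, 2))
  expect_false(isTRUE(all.equal(encode(vae, s)$mu, encode(vae, s2)$mu)))
  # sequences longer than the configured maximum are rejected
  expect_error(encode(vae, rand_seqs(1, 25)), "maximum length")
})

test_that("decoded profile HMMs are valid probability objects for any z", {
  vae <- vae_init("profile_hmm", max_len = 20, m = 12, seed = 4)
  set.seed(21)
  z <- matrix(rnorm(200, sd = 3), ncol = 2)
  mods <- decode_profile_hmm(vae, z)
  for (mod in mods[c(1, 25, 50, 100)]) expect_s3_class(mod, "profile_hmm")
  ok <- vapply(mods, function(mod) {
    all(abs(rowSums(mod$match_emissions) - 1) < 1e-6) &&
      all(abs(rowSums(mod$t_match) - 1) < 1e-6) &&
      all(abs(rowSums(mod$t_insert) - 1) < 1e-6) &&
      all(abs(rowSums(mod$t_delete) - 1) < 1e-6) &&
      mod$t_match[mod$m + 1, 3] == 0 && mod$t_delete[mod$m, 2] == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("the decoder map is continuous in z", {
  vae <- vae_init("profile_hmm", max_len = 20, m = 10, seed = 6)
  z <- c(0.3, -0.7)
  delta <- c(1e-6, 0) / sqrt(2) + c(0, 1e-6) / sqrt(2)
  m1 <- decode_profile_hmm(vae, z)[[1]]
  m2 <- decode_profile_hmm(vae, z + delta)[[1]]
  expect_lt(max(abs(m1$match_emissions - m2$match_emissions)), 1e-3)
  expect_lt(max(abs(m1$t_match - m2$t_match)), 1e-3)
})

test_that("a truncated decoder scores longer sequences finitely", {
  # decoder model length 20 attached to length-30 data (truncation mode)
  vae <- vae_init("profile_hmm", max_len = 30, m = 20, seed = 8)
  mod <- decode_profile_hmm(vae, c(0, 0))[[1]]
  expect_identical(mod$m, 20L)
  lp <- log_forward(mod, rand_seqs(3, 30, seed = 2))
  expect_true(all(is.finite(lp) & lp > -1e9))
})

test_that("multicategorical likelihood is the product of per-position terms", {
  vae <- vae_init("multicategorical", max_len = 8, seed = 10)
  z <- c(0.5, 0.2)
  P <- decode_multicategorical(vae, z)[[1]]
  expect_identical(dim(P), c(8L, 4L))
  expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-9)
  s <- "ACGUACGU"
  codes <- encode_rna(s)[[1]]
  manual <- sum(log(P[cbind(1:8, codes)]))
  st <- aptvae:::stack_sequences(list(codes), 8)
  res <- aptvae:::vae_loss_grad(
    within_vae_at_z(vae, z), t(st$mat), st$lens, epoch = 0,
    training_config(), eps = NULL, want_grad = FALSE)
  expect_equal(-res$recon, manual, tolerance = 1e-8)
})


test_that("autoregressive stepwise distributions chain to the sequence likelihood", {
  vae <- vae_init("autoregressive", max_len = 6, seed = 12)
  z <- c(-0.4, 0.9)
  p0 <- decode_autoregressive(vae, z, "")
  expect_identical(names(p0), c("A", "C", "G", "U", "end"))
  expect_equal(sum(p0), 1, tolerance = 1e-9)
  expect_identical(p0, decode_autoregressive(vae, z, ""))
  s <- "GAUC"
  letters_s <- strsplit(s, "")[[1]]
  stepwise <- 0
  for (i in seq_along(letters_s)) {
    p <- decode_autoregressive(vae, z, substr(s, 1, i - 1))
    stepwise <- stepwise + log(p[[letters_s[i]]])
  }
  stepwise <- stepwise + log(decode_autoregressive(vae, z, s)[["end"]])
  expect_equal(ar_log_likelihood(vae, z, s), stepwise, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("loss gradients match finite differences for every decoder kind", {
  seqs <- rand_seqs(6, 10, seed = 31)
  codes <- encode_rna(seqs)
  st <- aptvae:::stack_sequences(codes, 10)
  X <- t(st$mat)
  cfg <- training_config()
  h <- 1e-5
  for (kind in c("profile_hmm", "multicategorical", "autoregressive")) {
    vae <- vae_init(kind, max_len = 10, m = 7, seed = 13)
    set.seed(41)
    eps <- matrix(rnorm(6 * 2), ncol = 2)
    res <- aptvae:::vae_loss_grad(vae, X, st$lens, epoch = 5, cfg, eps, TRUE)
    for (side in c("enc", "dec")) {
      for (nm in names(vae[[side]])) {
        g <- res[[paste0("g", side)]][[nm]]
        expect_true(any(g != 0), label = paste(kind, side, nm, "has gradient"))
        set.seed(43)
        i <- sample(length(vae[[side]][[nm]]), 1)
        vp <- vae; vp[[side]][[nm]][i] <- vp[[side]][[nm]][i] + h
        vm <- vae; vm[[side]][[nm]][i] <- vm[[side]][[nm]][i] - h
        num <- (aptvae:::vae_loss_grad(vp, X, st$lens, 5, cfg, eps, FALSE)$loss -
                  aptvae:::vae_loss_grad(vm, X, st$lens, 5, cfg, eps, FALSE)$loss) /
          (2 * h)
        expect_equal(g[i], num, tolerance = 1e-3,
                     label = paste(kind, side, nm, "gradient"))
      }
    }
  }
})

test_that("checkpoints round-trip parameters and metadata", {
  vae <- vae_init("profile_hmm", max_len = 15, m = 12, seed = 77)
  path <- tempfile(fileext = ".json")
  write_checkpoint(vae, path)
  back <- read_checkpoint(path)
  expect_identical(back$kind, "profile_hmm")
  expect_identical(back$m, 12L)
  expect_identical(back$max_len, 15L)
  seqs <- rand_seqs(4, 15, seed = 5)
  expect_equal(encode(back, seqs), encode(vae, seqs), tolerance = 1e-12)
  mods1 <- decode_profile_hmm(vae, c(0.1, -0.2))
  mods2 <- decode_profile_hmm(back, c(0.1, -0.2))
  expect_equal(mods1[[1]]$match_emissions, mods2[[1]]$match_emissions,
               tolerance = 1e-12)
})
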