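# Objective terms, schedules, and the training loop.

test_that("KL annealing scale follows e/E and saturates at 1", {
  expect_identical(kl_scale(0, 50), 0)
  expect_identical(kl_scale(50, 50), 1)
  expect_identical(kl_scale(25, 50), 0.5)
  expect_identical(kl_scale(500, 50), 1)
})

test_that("Gaussian KL matches the closed form and a Monte-Carlo estimate", {
  expect_identical(gaussian_kl(0, 0), 0)
  expect_equal(gaussian_kl(1, 0), 0.5)
  # matrix form: per-row KL
  expect_equal(gaussian_kl(matrix(c(0, 1), 2, 1), matrix(0, 2, 1)), c(0, 0.5))
  # Monte-Carlo oracle: E_q[log q - log p] with 1e6 samples
  set.seed(1)
  mu <- 0.7; lv <- log(0.4)
  x <- rnorm(1e6, mu, sqrt(exp(lv)))
  draws <- dnorm(x, mu, sqrt(exp(lv)), log = TRUE) - dnorm(x, log = TRUE)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - gaussian_kl(mu, lv)), 3 * se)
})

test_that("transition regularizer equals the Dirichlet density ratio", {
  # zero at e = R for arbitrary distributions
  for (p in list(c(1, 0, 0), c(0.2, 0.5, 0.3), c(1 / 3, 1 / 3, 1 / 3)))
    expect_identical(transition_regularizer(p, e = 50, R = 50), 0)
  # w = 4 and a pure match transition: log((2+4)(1+4)/2 * 1) = log 15
  expect_equal(transition_regularizer(c(1, 0, 0), e = 0, R = 50), log(15),
               tolerance = 1e-12)
  # sampled (w, a): matches direct evaluation of the density ratio
  set.seed(7)
  for (rep in 1:20) {
    e <- sample(0:49, 1); R <- 50
    w <- 4 * (1 - e / R)
    p <- stats::rgamma(3, 1); p <- p / sum(p)
    oracle <- ldirichlet(p, c(1 + w, 1, 1)) - ldirichlet(p, c(1, 1, 1))
    expect_equal(transition_regularizer(p, e, R), oracle, tolerance = 1e-10)
  }
  # monotone in a_MM for fixed e < R
  a <- seq(0.1, 0.9, by = 0.2)
  vals <- vapply(a, function(ai)
    transition_regularizer(c(ai, (1 - ai) / 2, (1 - ai) / 2), e = 10, R = 50),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the recorded loss decomposes exactly into its terms", {
  set.seed(5)
  seqs <- replicate(30, paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE),
                              collapse = ""))
  cfg <- training_config(kl_anneal_E = 50, transition_reg_R = 50)
  vae <- vae_init("profile_hmm", max_len = 12, m = 12, seed = 2)
  for (ep in c(0, 10, 60)) {
    set.seed(100 + ep)
    r <- elbo_loss(vae, seqs, epoch = ep, cfg)
    expect_identical(r$loss, r$recon + r$scale * r$kl + r$reg)
    expect_identical(r$scale, kl_scale(ep, 50))
  }
  # epoch 0: KL contributes nothing; epoch >= R: regularizer identically 0
  set.seed(1); r0 <- elbo_loss(vae, seqs, epoch = 0, cfg)
  expect_identical(r0$scale, 0)
  expect_identical(r0$loss, r0$recon + r0$reg)
  set.seed(1); r60 <- elbo_loss(vae, seqs, epoch = 60, cfg)
  expect_identical(r60$reg, 0)
})

test_that("perfect reconstruction drives the reconstruction term to zero", {
  # deterministic encoder (variance -> 0) + one-hot multicategorical decoder
  s <- "ACGU"
  vae <- vae_init("multicategorical", max_len = 4, seed = 3)
  vae <- within_vae_at_z(vae, c(0, 0))
  vae$dec$W1 <- vae$dec$W1 * 0; vae$dec$W2 <- vae$dec$W2 * 0
  vae$dec$b1 <- vae$dec$b1 * 0; vae$dec$b2 <- vae$dec$b2 * 0
  vae$dec$Wo <- vae$dec$Wo * 0
  onehot <- rep(0, 16)
  onehot[(0:3) * 4 + encode_rna(s)[[1]]] <- 60 # softmax saturates to one-hot
  vae$dec$bo <- onehot
  r <- elbo_loss(vae, s, epoch = 0, training_config(), sample = FALSE)
  expect_lt(r$recon, 1e-8)
})

test_that("training is deterministic, stops early, and returns the best snapshot", {
  set.seed(9)
  seqs <- unique(replicate(80, paste(sample(c("A", "C", "G", "U"), 8,
                                            replace = TRUE), collapse = "")))
  cfg <- training_config(max_epochs = 12, patience = 5, batch_size = 32,
                         kl_anneal_E = 5, transition_reg_R = 5, seed = 4)
  vae <- vae_init("multicategorical", max_len = 8, seed = 4)
  fit1 <- train_vae(seqs, vae, cfg)
  fit2 <- train_vae(seqs, vae, cfg)
  expect_identical(fit1$record, fit2$record)
  expect_identical(fit1$vae$enc, fit2$vae$enc)
  # best snapshot bookkeeping: reported epoch is the argmin of the test loss
  expect_identical(fit1$best_epoch,
                   fit1$record$epoch[which.min(fit1$record$test_loss)])
  expect_identical(fit1$best_test_loss, min(fit1$record$test_loss))
  expect_lte(fit1$best_epoch, max(fit1$record$epoch))
  # loss decomposition holds at every recorded epoch
  with(fit1$record, expect_equal(
    train_loss, train_recon + kl_scale * train_kl + train_reg,
    tolerance = 1e-12))
  # patience: the run never continues more than `patience` epochs past the best
  expect_lte(max(fit1$record$epoch) - fit1$best_epoch, cfg$patience)
  expect_error(train_vae(character(0), vae, cfg), "empty dataset")
  expect_error(train_vae(seqs[1], vae, cfg), "empty part")
})

test_that("the transition regularizer biases early models toward match transitions", {
  set.seed(31)
  seqs <- unique(replicate(150, paste(sample(c("A", "C", "G", "U"), 10,
                                             replace = TRUE), collapse = "")))
  amm <- function(R_setting, seed) {
    cfg <- training_config(max_epochs = 20, patience = 20, batch_size = 32,
                           kl_anneal_E = 50, transition_reg_R = R_setting,
                           seed = seed)
    vae <- vae_init("profile_hmm", max_len = 10, m = 10, seed = seed)
    fit <- train_vae(seqs, vae, cfg)
    z <- encode(fit$vae, seqs[1:20])$mu
    mods <- decode_profile_hmm(fit$vae, z)
    mean(vapply(mods, function(mo) mean(mo$t_match[1:mo$m, 1]), numeric(1)))
  }
  # regularized early training allocates higher mean a_MM than an
  # unregularized control (R = 1 makes the regularizer vanish immediately)
  with_reg <- vapply(1:3, function(s) amm(50, s), numeric(1))
  without <- vapply(1:3, function(s) amm(1, s), numeric(1))
  expect_gt(mean(with_reg), mean(without))
})
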