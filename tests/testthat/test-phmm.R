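# The profile HMM as a standalone probabilistic object.

one_path_model <- function() {
  # m = 1, deterministic: M0 -> M1 (emit A) -> end
  profile_hmm(matrix(c(1, 0, 0, 0), 1, 4),
              matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
              matrix(c(1, 0), 2, 2, byrow = TRUE),
              matrix(c(1, 0), 1, 2))
}

test_that("forward likelihood is exact on single-path and zero-probability cases", {
  mod <- one_path_model()
  expect_equal(log_forward(mod, "A"), 0)
  expect_lt(log_forward(mod, "C"), -1e9) # floor, not -Inf
  expect_error(log_forward(mod, "AXN"), "invalid letter")
})

test_that("model validation rejects non-normalized and malformed inputs", {
  bad_e <- matrix(c(0.5, 0.1, 0.1, 0.1), 1, 4)
  expect_error(profile_hmm(bad_e, matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                           matrix(c(1, 0), 2, 2, byrow = TRUE),
                           matrix(c(1, 0), 1, 2)),
               "sum to 1")
  tm_bad <- matrix(c(1, 0, 0, 0.5, 0, 0.5), 2, 3, byrow = TRUE)
  expect_error(profile_hmm(matrix(0.25, 1, 4), tm_bad,
                           matrix(c(1, 0), 2, 2, byrow = TRUE),
                           matrix(c(1, 0), 1, 2)),
               "D_\\{m\\+1\\}")
})

test_that("forward equals brute-force path enumeration on random small models", {
  for (s in 1:10) {
    m <- (s %% 3) + 1
    mod <- random_phmm(m, 100 + s)
    set.seed(200 + s)
    codes <- sample(1:4, sample(1:4, 1), replace = TRUE)
    expect_equal(log_forward(mod, list(codes)), brute_forward(mod, codes),
                 tolerance = 1e-9)
  }
})

test_that("total emitted probability is <= 1 and non-decreasing in the length cap", {
  mod <- random_phmm(2, 42)
  tot <- 0
  for (K in 0:4) {
    tot_new <- tot + sum(exp(log_forward(mod, all_sequences(K))))
    expect_gte(tot_new, tot)
    expect_lte(tot_new, 1 + 1e-9)
    tot <- tot_new
  }
})

test_that("most probable path follows dominant transitions and the topology", {
  # pure-match model: every M_k -> M_{k+1} strictly dominant
  m <- 4
  e <- matrix(0.01, m, 4); e[, 2] <- 0.97
  tm <- matrix(rep(c(0.9, 0.05, 0.05), each = m + 1), m + 1, 3)
  tm[m + 1, ] <- c(0.95, 0.05, 0)
  ti <- matrix(rep(c(0.9, 0.1), each = m + 1), m + 1, 2)
  td <- matrix(rep(c(0.9, 0.1), each = m), m, 2); td[m, ] <- c(1, 0)
  mod <- profile_hmm(e, tm, ti, td)
  p <- most_probable_path(mod)
  expect_identical(p$states, paste0("M", 0:(m + 1)))
  expect_identical(p$emitted[2:(m + 1)], rep("C", m))
  expect_identical(p$n_insert, 0L)

  # motif-skip: a high M0 -> D1 probability pulls the path through deletion
  m <- 2
  e <- matrix(0.25, m, 4)
  tm <- matrix(c(0.005, 0.005, 0.99,
                 0.9, 0.05, 0.05,
                 0.95, 0.05, 0), m + 1, 3, byrow = TRUE)
  ti <- matrix(rep(c(0.9, 0.1), each = m + 1), m + 1, 2)
  td <- matrix(c(0.9, 0.1, 1, 0), m, 2, byrow = TRUE)
  mod <- profile_hmm(e, tm, ti, td)
  p <- most_probable_path(mod)
  expect_true("D1" %in% p$states)
})

test_that("most probable path score matches exhaustive path enumeration", {
  for (s in 1:12) {
    mod <- random_phmm((s %% 3) + 1, 300 + s)
    p <- most_probable_path(mod)
    expect_equal(p$log_score, brute_best_path_score(mod), tolerance = 1e-9)
    # path respects the begin/end contract
    expect_identical(p$states[1], "M0")
    expect_identical(p$states[length(p$states)], paste0("M", mod$m + 1))
  }
  # determinism of tie-breaking: identical input, identical path
  mod <- random_phmm(3, 55)
  expect_identical(most_probable_path(mod), most_probable_path(mod))
})

test_that("reconstitution scores the right number of candidates and returns the best", {
  # zero insertion visits: exactly one candidate, the match-argmax word
  m <- 3
  e <- matrix(0.01, m, 4); e[1, 1] <- 0.97; e[2, 3] <- 0.97; e[3, 4] <- 0.97
  tm <- matrix(rep(c(0.9, 0.05, 0.05), each = m + 1), m + 1, 3)
  tm[m + 1, ] <- c(0.95, 0.05, 0)
  ti <- matrix(rep(c(0.9, 0.1), each = m + 1), m + 1, 2)
  td <- matrix(rep(c(0.9, 0.1), each = m), m, 2); td[m, ] <- c(1, 0)
  mod <- profile_hmm(e, tm, ti, td)
  r <- reconstitute(mod)
  expect_identical(r$n_scored, 1L)
  expect_identical(r$sequence, "AGU")
  expect_equal(r$log_prob, log_forward(mod, r$sequence))

  # two insertion visits: all 16 assignments enumerated, best returned
  mod <- insertion_heavy_phmm(m = 3, q = 2)
  expect_identical(most_probable_path(mod)$n_insert, 2L)
  r <- reconstitute(mod)
  expect_identical(r$n_scored, 16L)
  expect_false(anyDuplicated(r$candidates$sequence) > 0)
  expect_equal(r$log_prob, max(r$candidates$log_prob))
  expect_gte(r$log_prob, max(log_forward(mod, r$candidates$sequence)) - 1e-9)
})

test_that("reconstitution respects the candidate budget beyond 4 insertion slots", {
  mod <- insertion_heavy_phmm(m = 5, q = 5)
  expect_identical(most_probable_path(mod)$n_insert, 5L)
  r <- reconstitute(mod, max_candidates = 256, seed = 7)
  expect_identical(r$n_scored, 256L)
  expect_false(anyDuplicated(r$candidates$sequence) > 0)
  r2 <- reconstitute(mod, max_candidates = 256, seed = 7)
  expect_identical(r$candidates, r2$candidates)
})

test_that("JSON serialization and logo export round-trip the model", {
  mod <- random_phmm(3, 77)
  path <- tempfile(fileext = ".json")
  write_phmm_json(mod, path)
  back <- read_phmm_json(path)
  expect_equal(back$match_emissions, mod$match_emissions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$t_match, mod$t_match, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$t_insert, mod$t_insert, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$t_delete, mod$t_delete, tolerance = 1e-12, ignore_attr = TRUE)
  seqs <- c("ACG", "UU", "GGGG")
  expect_equal(log_forward(back, seqs), log_forward(mod, seqs), tolerance = 1e-10)
  tsv <- tempfile(fileext = ".tsv")
  write_phmm_logo_tsv(mod, tsv)
  tab <- read.delim(tsv)
  expect_identical(dim(tab), c(3L, 5L))
  expect_equal(rowSums(tab[, c("A", "C", "G", "U")]), rep(1, 3),
               tolerance = 1e-9)
})
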