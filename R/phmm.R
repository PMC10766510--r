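# Profile hidden Markov model as a standalone probabilistic object.
#
# The model has m match states M_1..M_m plus a silent begin M_0 and end
# M_{m+1}, insert states I_0..I_m (uniform 1/4 emission) and delete states
# D_1..D_m. Allowed transitions:
#   M_k -> {M_{k+1}, I_k, D_{k+1}},  I_k -> {M_{k+1}, I_k},
#   D_k -> {M_{k+1}, D_{k+1}},
# with D_{m+1} nonexistent (those edges carry probability zero) and the end
# state emitting the end-of-sequence token with probability 1.

LOG_FLOOR <- -1e10

log_floor <- function(p) {
  out <- rep(LOG_FLOOR, length(p))
  pos <- p > 0
  out[pos] <- log(p[pos])
  out
}

#' Construct a profile HMM
#'
#' @param match_emissions numeric matrix, `m` rows and 4 columns in A, C, G,
#'   U order; each row a distribution over emitted letters.
#' @param t_match `(m+1) x 3` matrix of transition distributions out of the
#'   match states `M_0..M_m`, columns `(to M, to I, to D)`. Row `m` (the
#'   last) must put probability 0 on D, as `D_{m+1}` does not exist.
#' @param t_insert `(m+1) x 2` matrix for `I_0..I_m`, columns `(to M, to I)`.
#' @param t_delete `m x 2` matrix for `D_1..D_m`, columns `(to M, to D)`;
#'   the last row must put probability 0 on D.
#' @param validate check invariants (row sums within 1e-6 of 1, masked
#'   entries zero).
#' @return an object of class `profile_hmm`.
#' @examples
#' mod <- uniform_phmm(3)
#' log_forward(mod, "ACG")
#' @export
profile_hmm <- function(match_emissions, t_match, t_insert, t_delete,
                        validate = TRUE) {
  match_emissions <- as.matrix(match_emissions)
  t_match <- as.matrix(t_match)
  t_insert <- as.matrix(t_insert)
  t_delete <- as.matrix(t_delete)
  m <- nrow(match_emissions)
  obj <- structure(
    list(m = m, match_emissions = match_emissions, t_match = t_match,
         t_insert = t_insert, t_delete = t_delete),
    class = "profile_hmm")
  if (validate) validate_phmm(obj)
  obj
}

validate_phmm <- function(model, tol = 1e-6) {
  m <- model$m
  if (m < 1) stop("model_length must be >= 1", call. = FALSE)
  e <- model$match_emissions
  if (ncol(e) != 4) stop("match_emissions must have 4 columns", call. = FALSE)
  chk <- function(mat, what) {
    if (any(mat < -tol)) stop(what, " has negative probabilities", call. = FALSE)
    if (any(abs(rowSums(mat) - 1) > tol))
      stop(what, " rows must sum to 1 (tolerance 1e-6)", call. = FALSE)
  }
  chk(e, "match_emissions")
  if (!all(dim(model$t_match) == c(m + 1, 3)))
    stop("t_match must be (m+1) x 3", call. = FALSE)
  if (!all(dim(model$t_insert) == c(m + 1, 2)))
    stop("t_insert must be (m+1) x 2", call. = FALSE)
  if (!all(dim(model$t_delete) == c(m, 2)))
    stop("t_delete must be m x 2", call. = FALSE)
  chk(model$t_match, "t_match")
  chk(model$t_insert, "t_insert")
  chk(model$t_delete, "t_delete")
  if (model$t_match[m + 1, 3] > tol)
    stop("M_m -> D_{m+1} must have probability 0 (no D_{m+1} state)",
         call. = FALSE)
  if (model$t_delete[m, 2] > tol)
    stop("D_m -> D_{m+1} must have probability 0", call. = FALSE)
  invisible(model)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM, model length m =", x$m, "\n")
  cat("Consensus (match argmax):",
      paste(RNA_LETTERS[max.col(x$match_emissions, "first")], collapse = ""),
      "\n")
  invisible(x)
}

#' A profile HMM with uniform emissions and transitions
#'
#' Convenience constructor used in examples and as a neutral reference:
#' every match state emits uniformly and every state splits its outgoing
#' probability uniformly over its allowed successors.
#' @param m model length (number of match states).
#' @export
uniform_phmm <- function(m) {
  tm <- matrix(1 / 3, m + 1, 3)
  tm[m + 1, ] <- c(0.5, 0.5, 0)
  td <- matrix(0.5, m, 2)
  td[m, ] <- c(1, 0)
  profile_hmm(matrix(0.25, m, 4), tm, matrix(0.5, m + 1, 2), td)
}

# Log-parameter slabs in the layout the C++ kernel expects:
# le (4, m), ltM (3, m+1), ltI (2, m+1), ltD (2, m).
phmm_log_params <- function(model) {
  list(le = array(log_floor(t(model$match_emissions)), c(4, model$m)),
       ltM = array(log_floor(t(model$t_match)), c(3, model$m + 1)),
       ltI = array(log_floor(t(model$t_insert)), c(2, model$m + 1)),
       ltD = array(log_floor(t(model$t_delete)), c(2, model$m)))
}

coerce_codes <- function(seq) {
  if (is.character(seq)) encode_rna(seq) else if (is.list(seq)) seq else list(as.integer(seq))
}

#' Forward log-likelihood of sequences under a profile HMM
#'
#' Sums over all state paths that emit the sequence, by the forward
#' recurrences over match/insert/delete states in log space (cost O(Lm)).
#' Zero-probability events are represented by a large negative floor
#' (-1e10) rather than -Inf.
#'
#' @param model a [profile_hmm()].
#' @param seq a character vector of sequences, or an integer code vector, or
#'   a list of integer code vectors.
#' @return numeric vector of log-probabilities, one per sequence.
#' @export
log_forward <- function(model, seq) {
  validate_phmm(model)
  codes <- coerce_codes(seq)
  st <- stack_sequences(codes)
  lp <- phmm_log_params(model)
  n <- length(codes)
  res <- phmm_forward_cpp(
    array(lp$le, c(4, model$m, 1))[, , rep(1L, n), drop = FALSE],
    array(lp$ltM, c(3, model$m + 1, 1))[, , rep(1L, n), drop = FALSE],
    array(lp$ltI, c(2, model$m + 1, 1))[, , rep(1L, n), drop = FALSE],
    array(lp$ltD, c(2, model$m, 1))[, , rep(1L, n), drop = FALSE],
    st$mat, st$lens, FALSE)
  res$logp
}

#' Most probable state path of a profile HMM
#'
#' A max-product dynamic program over the state graph in which each emitting
#' state contributes the maximum of its emission distribution (1/4 for
#' insert states). Insertion self-loops are never taken: each extra loop
#' multiplies the score by `a_{I,I}/4 < 1`. Ties are broken preferring
#' Match over Delete over Insert predecessors, then lower state index.
#'
#' @param model a [profile_hmm()].
#' @return list with `states` (e.g. `"M0" "M1" "I1" "M2" "M3"`, begin to
#'   end), `emitted` (per-step letter or NA for silent/insert-slot steps),
#'   `log_score`, and `n_insert` (number of insertion visits).
#' @export
most_probable_path <- function(model) {
  validate_phmm(model)
  m <- model$m
  lp <- phmm_log_params(model)
  ltM <- t(lp$ltM); ltI <- t(lp$ltI); ltD <- t(lp$ltD) # rows = state index
  # per-match-state max emission with deterministic argmax (first letter wins)
  eargmax <- max.col(model$match_emissions, "first")
  lmaxe <- log_floor(model$match_emissions[cbind(seq_len(m), eargmax)])
  stopifnot(all(ltI[, 2] + log(0.25) < 0)) # self-loop never increases score
  M <- rep(LOG_FLOOR, m + 1); I <- rep(LOG_FLOOR, m + 1); D <- rep(LOG_FLOOR, m + 1)
  predM <- integer(m + 1); predD <- integer(m + 1) # 1=Match,2=Delete,3=Insert
  M[1] <- 0
  I[1] <- M[1] + ltM[1, 2] + log(0.25)
  for (k in 1:m) {
    # D_k: sources M_{k-1} (pref) then D_{k-1}
    cand <- c(M[k] + ltM[k, 3], if (k >= 2) D[k] + ltD[k - 1, 2] else LOG_FLOOR)
    predD[k + 1] <- which.max(cand) # which.max prefers first on ties
    D[k + 1] <- cand[predD[k + 1]]
    # M_k: sources M_{k-1} > D_{k-1} > I_{k-1}
    cand <- c(M[k] + ltM[k, 1],
              if (k >= 2) D[k] + ltD[k - 1, 1] else LOG_FLOOR,
              I[k] + ltI[k, 1])
    predM[k + 1] <- which.max(cand)
    M[k + 1] <- cand[predM[k + 1]] + lmaxe[k]
    I[k + 1] <- M[k + 1] + ltM[k + 1, 2] + log(0.25)
  }
  cand <- c(M[m + 1] + ltM[m + 1, 1], D[m + 1] + ltD[m, 1],
            I[m + 1] + ltI[m + 1, 1])
  last <- which.max(cand)
  score <- cand[last]
  # backtrack from M_{m+1}
  states <- paste0("M", m + 1)
  emitted <- NA_character_
  kind <- c("M", "D", "I")[last]; k <- m
  while (!(kind == "M" && k == 0)) {
    states <- c(paste0(kind, k), states)
    emitted <- c(switch(kind, M = RNA_LETTERS[eargmax[k]], I = NA_character_,
                        D = NA_character_), emitted)
    if (kind == "M") {
      p <- predM[k + 1]; kind <- c("M", "D", "I")[p]; k <- k - 1
    } else if (kind == "D") {
      p <- predD[k + 1]
      if (p == 1) { kind <- "M"; k <- k - 1 } else { kind <- "D"; k <- k - 1 }
    } else { # I_k entered from M_k
      kind <- "M"
    }
  }
  states <- c("M0", states)
  emitted <- c(NA_character_, emitted)
  list(states = states, emitted = emitted, log_score = score,
       n_insert = sum(startsWith(states, "I")))
}

#' Reconstitute the most probable sequence from a profile HMM
#'
#' Takes the most probable state path; match states contribute their argmax
#' letter; each insertion visit is a free letter slot. Up to `max_candidates`
#' distinct letter assignments for the insertion slots are formed --
#' exhaustively when `4^q <= max_candidates`, otherwise by seeded sampling
#' without duplication -- every full sequence is scored with [log_forward()],
#' and the best is returned.
#'
#' @param model a [profile_hmm()].
#' @param max_candidates maximum number of candidate sequences to score
#'   (default 256).
#' @param seed integer seed used only when sampling insertion assignments.
#' @return list with `sequence` (character), `log_prob` (its full forward
#'   log-probability), `n_scored`, `path` (the state path used), and
#'   `candidates` (data.frame of every scored sequence and log-probability).
#' @export
reconstitute <- function(model, max_candidates = 256, seed = NULL) {
  path <- most_probable_path(model)
  slots <- which(startsWith(path$states, "I"))
  q <- length(slots)
  # emitted letters in path order, NA at insertion slots; delete states and
  # the begin/end markers emit nothing
  emit_states <- path$states[-c(1, length(path$states))]
  emit_mask <- !startsWith(emit_states, "D")
  template <- path$emitted[-c(1, length(path$states))][emit_mask]
  slot_pos <- which(is.na(template))
  stopifnot(length(slot_pos) == q)
  if (q == 0) {
    assign_mat <- matrix(integer(0), nrow = 1, ncol = 0)
  } else if (4^q <= max_candidates) {
    idx <- 0:(4^q - 1)
    assign_mat <- index_to_base4(idx, q)
  } else if (q <= 15) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    idx <- sort(sample(4^q, max_candidates) - 1)
    assign_mat <- index_to_base4(idx, q)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    seen <- character(0)
    rows <- list()
    while (length(rows) < max_candidates) {
      draw <- sample.int(4, q, replace = TRUE)
      key <- paste(draw, collapse = "")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rows[[length(rows) + 1]] <- draw
      }
    }
    assign_mat <- do.call(rbind, rows)
    assign_mat <- assign_mat[order(apply(assign_mat, 1, paste, collapse = "")), ,
                             drop = FALSE]
  }
  codes <- lapply(seq_len(nrow(assign_mat)), function(i) {
    letters <- template
    if (q > 0) letters[slot_pos] <- RNA_LETTERS[assign_mat[i, ]]
    match(letters, RNA_LETTERS)
  })
  lps <- log_forward(model, codes)
  best <- which.max(lps)
  seqs <- vapply(codes, decode_rna, character(1))
  list(sequence = seqs[best], log_prob = lps[best], n_scored = length(lps),
       path = path,
       candidates = data.frame(sequence = seqs, log_prob = lps,
                               stringsAsFactors = FALSE))
}

# integer indices (0-based) -> q base-4 digits (1..4), first slot most
# significant so scoring order equals enumeration order
index_to_base4 <- function(idx, q) {
  out <- matrix(0L, length(idx), q)
  for (j in q:1) {
    out[, j] <- idx %% 4 + 1
    idx <- idx %/% 4
  }
  out
}

#' Write / read a profile HMM as JSON
#'
#' Match emissions are stored row-major in A/C/G/U order; transitions as a
#' table keyed `"M0->M1"`, `"M0->I0"`, `"I0->I0"`, `"D1->M2"`, ... .
#' @param model a [profile_hmm()].
#' @param path file path.
#' @export
write_phmm_json <- function(model, path) {
  validate_phmm(model)
  m <- model$m
  tr <- list()
  for (k in 0:m) {
    tr[[sprintf("M%d->M%d", k, k + 1)]] <- model$t_match[k + 1, 1]
    tr[[sprintf("M%d->I%d", k, k)]] <- model$t_match[k + 1, 2]
    if (k < m) tr[[sprintf("M%d->D%d", k, k + 1)]] <- model$t_match[k + 1, 3]
    tr[[sprintf("I%d->M%d", k, k + 1)]] <- model$t_insert[k + 1, 1]
    tr[[sprintf("I%d->I%d", k, k)]] <- model$t_insert[k + 1, 2]
    if (k >= 1) {
      tr[[sprintf("D%d->M%d", k, k + 1)]] <- model$t_delete[k, 1]
      if (k < m) tr[[sprintf("D%d->D%d", k, k + 1)]] <- model$t_delete[k, 2]
    }
  }
  obj <- list(model_length = m,
              alphabet = RNA_LETTERS,
              match_emissions = as.vector(t(model$match_emissions)),
              transitions = tr)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phmm_json
#' @export
read_phmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.integer(obj$model_length)
  e <- matrix(obj$match_emissions, nrow = m, ncol = 4, byrow = TRUE)
  tr <- obj$transitions
  g <- function(key) if (is.null(tr[[key]])) 0 else as.numeric(tr[[key]])
  tm <- t(vapply(0:m, function(k) c(g(sprintf("M%d->M%d", k, k + 1)),
                                    g(sprintf("M%d->I%d", k, k)),
                                    g(sprintf("M%d->D%d", k, k + 1))),
                 numeric(3)))
  ti <- t(vapply(0:m, function(k) c(g(sprintf("I%d->M%d", k, k + 1)),
                                    g(sprintf("I%d->I%d", k, k))),
                 numeric(2)))
  td <- t(vapply(1:m, function(k) c(g(sprintf("D%d->M%d", k, k + 1)),
                                    g(sprintf("D%d->D%d", k, k + 1))),
                 numeric(2)))
  profile_hmm(e, tm, ti, td)
}

#' Export match emissions as a position-probability TSV (sequence logo input)
#' @param model a [profile_hmm()].
#' @param path file path for the TSV.
#' @export
write_phmm_logo_tsv <- function(model, path) {
  df <- data.frame(position = seq_len(model$m), model$match_emissions)
  names(df) <- c("position", RNA_LETTERS)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Largest probability of entering a delete state from a match state
#'
#' `max_k a_{M_{k-1}, D_k}`: a summary of how strongly a decoded model skips
#' a block of match states, used to detect motif-skipping behaviour in
#' split-motif analyses.
#' @param model a [profile_hmm()].
#' @export
max_skip_probability <- function(model) {
  max(model$t_match[seq_len(model$m), 3])
}
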