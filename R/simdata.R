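# Seeded generators for the two simulation datasets with ground-truth motif
# labels: ten 10-nt motifs mutated at a 10% per-position rate and padded to
# 20 nt, and paired 5-nt motifs with 2-6 nt separators padded to 20 nt.

rand_letters <- function(n) sample.int(4, n, replace = TRUE)

# Mutate one motif: at each original position, with probability `error_rate`
# apply exactly one edit, the type uniform over deletion / insertion /
# substitution (each error_rate/3 per position). Insertions add one uniform
# letter after the position; substitutions resample from the 3 other
# letters. Returns codes plus a compact trace string.
mutate_motif <- function(motif, error_rate) {
  out <- integer(0)
  trace <- character(0)
  for (i in seq_along(motif)) {
    if (stats::runif(1) < error_rate) {
      type <- sample(c("del", "ins", "sub"), 1)
      if (type == "del") {
        trace <- c(trace, paste0("del@", i))
      } else if (type == "ins") {
        out <- c(out, motif[i], sample.int(4, 1))
        trace <- c(trace, paste0("ins@", i))
      } else {
        out <- c(out, sample(setdiff(1:4, motif[i]), 1))
        trace <- c(trace, paste0("sub@", i))
      }
    } else {
      out <- c(out, motif[i])
    }
  }
  list(codes = out, trace = paste(trace, collapse = ";"))
}

pad_to_length <- function(codes, target_len) {
  total <- target_len - length(codes)
  if (total < 0)
    stop("target_len shorter than a mutated motif", call. = FALSE)
  left <- sample(0:total, 1)
  c(rand_letters(left), codes, rand_letters(total - left))
}

#' Simulated single-motif dataset
#'
#' Ten distinct random 10-nt motifs; each sequence carries one motif with a
#' 10% per-position chance of exactly one edit (deletion, insertion or
#' substitution, each equiprobable, i.e. 3.33...% per type per position),
#' padded with uniform random letters to exactly 20 nt; duplicates are
#' rejected globally until `n` unique sequences exist.
#'
#' @param n number of unique sequences (default 10000).
#' @param n_motifs number of motifs (default 10).
#' @param motif_len motif length (default 10).
#' @param target_len final sequence length (default 20).
#' @param error_rate per-position mutation probability (default 0.10).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return data.frame with columns `sequence`, `motif_id`, `trace`
#'   (semicolon-separated edits); the motif strings are in
#'   `attr(, "motifs")`.
#' @export
generate_single_motif_dataset <- function(n = 10000, n_motifs = 10,
                                          motif_len = 10, target_len = 20,
                                          error_rate = 0.10, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  repeat {
    motifs <- replicate(n_motifs, rand_letters(motif_len), simplify = FALSE)
    if (!anyDuplicated(vapply(motifs, decode_rna, character(1)))) break
  }
  seqs <- character(n); ids <- integer(n); traces <- character(n)
  seen <- new.env(hash = TRUE, size = 2L * n)
  got <- 0L
  while (got < n) {
    id <- sample.int(n_motifs, 1)
    mut <- mutate_motif(motifs[[id]], error_rate)
    s <- decode_rna(pad_to_length(mut$codes, target_len))
    if (is.null(seen[[s]])) {
      seen[[s]] <- TRUE
      got <- got + 1L
      seqs[got] <- s; ids[got] <- id; traces[got] <- mut$trace
    }
  }
  out <- data.frame(sequence = seqs, motif_id = ids, trace = traces,
                    stringsAsFactors = FALSE)
  attr(out, "motifs") <- vapply(motifs, decode_rna, character(1))
  attr(out, "params") <- list(n = n, n_motifs = n_motifs,
                              motif_len = motif_len,
                              target_len = target_len,
                              error_rate = error_rate, seed = seed)
  out
}

#' Simulated paired-motif dataset
#'
#' Two fixed 5-nt motifs; each is independently deleted with probability
#' `drop_prob` (draws deleting both are redrawn, so labels are `both`,
#' `left_only`, `right_only`). When both remain, a uniform-random separator
#' of `gap_range` letters is inserted between them; every sequence is padded
#' with uniform random letters to exactly `target_len`.
#'
#' @param n number of sequences (default 5000; duplicates allowed).
#' @param motif_len motif length (default 5).
#' @param gap_range integer range of separator lengths (default 2:6).
#' @param drop_prob per-motif deletion probability (default 0.25).
#' @param target_len final length (default 20).
#' @param seed integer seed.
#' @return data.frame with `sequence` and `label`; motifs in
#'   `attr(, "motifs")`.
#' @export
generate_paired_motif_dataset <- function(n = 5000, motif_len = 5,
                                          gap_range = c(2, 6),
                                          drop_prob = 0.25, target_len = 20,
                                          seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  repeat {
    left <- rand_letters(motif_len); right <- rand_letters(motif_len)
    if (!identical(left, right)) break
  }
  gaps <- seq.int(gap_range[1], gap_range[2])
  seqs <- character(n); labels <- character(n)
  for (i in seq_len(n)) {
    repeat {
      dl <- stats::runif(1) < drop_prob
      dr <- stats::runif(1) < drop_prob
      if (!(dl && dr)) break
    }
    core <- if (!dl && !dr) {
      c(left, rand_letters(sample(gaps, 1)), right)
    } else if (dl) right else left
    seqs[i] <- decode_rna(pad_to_length(core, target_len))
    labels[i] <- if (!dl && !dr) "both" else if (dl) "right_only" else "left_only"
  }
  out <- data.frame(sequence = seqs, label = labels, stringsAsFactors = FALSE)
  attr(out, "motifs") <- c(left = decode_rna(left), right = decode_rna(right))
  attr(out, "params") <- list(n = n, motif_len = motif_len,
                              gap_range = gap_range, drop_prob = drop_prob,
                              target_len = target_len, seed = seed)
  out
}

#' Write a simulated dataset to FASTA + label TSV + JSON manifest
#'
#' @param dataset a data.frame from one of the generators.
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>_labels.tsv`, `<prefix>_manifest.json`.
#' @export
write_dataset <- function(dataset, prefix) {
  label_col <- intersect(c("motif_id", "label"), names(dataset))[1]
  ids <- sprintf("seq%06d %s=%s", seq_len(nrow(dataset)), label_col,
                 dataset[[label_col]])
  x <- Biostrings::RNAStringSet(dataset$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, paste0(prefix, ".fasta"))
  utils::write.table(dataset, paste0(prefix, "_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(params = attr(dataset, "params"),
                   motifs = as.list(attr(dataset, "motifs")),
                   n = nrow(dataset))
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
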