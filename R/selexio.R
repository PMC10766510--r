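# Reading, filtering and selecting HT-SELEX sequencing data.

#' Read sequencing reads from FASTA or FASTQ
#'
#' Quality scores are ignored; identical reads are aggregated into a count
#' table ordered by first appearance. Gzip input is handled transparently.
#' `T` is kept as read here; conversion to the RNA alphabet happens in
#' [filter_reads()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension / leading character), `"fasta"` or
#'   `"fastq"`.
#' @return data.frame with columns `sequence` and `count`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq"
    else if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) "fasta"
    else {
      con <- gzfile(path, "rt"); first <- readLines(con, n = 1); close(con)
      if (length(first) == 0) "fasta"
      else if (startsWith(first, "@")) "fastq" else "fasta"
    }
  }
  validate_read_file(path, format)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  if (length(seqs) == 0)
    return(data.frame(sequence = character(0), count = integer(0)))
  first <- !duplicated(seqs)
  counts <- table(factor(seqs, levels = seqs[first]))
  data.frame(sequence = seqs[first], count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Structural pre-scan so malformed records can be reported with a line
# number (the underlying parser's errors do not carry one).
validate_read_file <- function(path, format) {
  lines <- readLines(gzfile(path), warn = FALSE)
  if (length(lines) == 0) return(invisible(TRUE))
  if (format == "fasta") {
    nonempty <- which(nzchar(trimws(lines)))
    if (length(nonempty) > 0 && !startsWith(lines[nonempty[1]], ">"))
      stop("parse error at line ", nonempty[1],
           ": FASTA must start with '>'", call. = FALSE)
  } else {
    if (length(lines) %% 4 != 0)
      stop("parse error at line ", length(lines),
           ": FASTQ record truncated (line count not a multiple of 4)",
           call. = FALSE)
    for (i in seq(1, length(lines), by = 4)) {
      if (!startsWith(lines[i], "@"))
        stop("parse error at line ", i, ": expected '@' header", call. = FALSE)
      if (!startsWith(lines[i + 2], "+"))
        stop("parse error at line ", i + 2, ": expected '+' separator",
             call. = FALSE)
      if (nchar(lines[i + 1]) != nchar(lines[i + 3]))
        stop("parse error at line ", i + 3,
             ": quality length differs from sequence length", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a SELEX round
#'
#' @param sequences character vector of unique variable-region sequences
#'   (RNA alphabet).
#' @param counts integer read counts (>= 1), same length.
#' @param round round index `T`.
#' @return object of class `selex_round`.
#' @export
selex_round <- function(sequences, counts, round = NA_integer_) {
  stopifnot(length(sequences) == length(counts), all(counts >= 1),
            !anyDuplicated(sequences))
  structure(list(sequences = sequences, counts = as.integer(counts),
                 round = round),
            class = "selex_round")
}

#' @export
print.selex_round <- function(x, ...) {
  cat("SELEX round", x$round, ":", length(x$sequences), "unique /",
      sum(x$counts), "total reads; U(T) =",
      signif(unique_ratio(x), 4), "\n")
  invisible(x)
}

#' Filter SELEX reads by the three preprocessing rules
#'
#' A read is kept iff (i) it carries both adapters as exact prefix/suffix
#' matches, (ii) the extracted variable region has exactly the design
#' length, and (iii) the variable region's aggregated read count is at
#' least 2. Sequences are mapped to the RNA alphabet (T to U).
#'
#' @param reads data.frame from [read_reads()] (`sequence`, `count`).
#' @param adapter5,adapter3 5' and 3' adapter sequences (may be "").
#' @param design_len design length of the variable (random) region.
#' @param round round index attached to the result.
#' @return a [selex_round()] of unique variable regions with counts.
#' @export
filter_reads <- function(reads, adapter5, adapter3, design_len,
                         round = NA_integer_) {
  norm <- function(x) chartr("T", "U", toupper(x))
  s <- norm(reads$sequence)
  a5 <- norm(adapter5); a3 <- norm(adapter3)
  ok <- startsWith(s, a5) & endsWith(s, a3) &
    nchar(s) >= nchar(a5) + nchar(a3)
  var <- substr(s[ok], nchar(a5) + 1L, nchar(s[ok]) - nchar(a3))
  cnt <- reads$count[ok]
  ok2 <- nchar(var) == design_len
  var <- var[ok2]; cnt <- cnt[ok2]
  if (length(var) == 0)
    return(selex_round(character(0), integer(0), round))
  agg <- rowsum(cnt, group = var, reorder = FALSE)
  keep <- agg[, 1] >= 2
  selex_round(rownames(agg)[keep], agg[keep, 1], round)
}

#' Unique ratio U(T) of a SELEX round
#'
#' Number of distinct sequences divided by total reads (with multiplicity):
#' 1 when every read is unique, small when the pool is strongly enriched.
#' @param round a [selex_round()].
#' @export
unique_ratio <- function(round) {
  total <- sum(round$counts)
  if (total == 0) stop("unique ratio undefined for an empty round",
                       call. = FALSE)
  length(round$sequences) / total
}

#' Select the training round from a SELEX series
#'
#' Returns the round minimizing U(T) subject to U(T) > 0.5 (the most
#' enriched pool that is not yet dominated by duplicated reads); ties are
#' broken toward the later round.
#' @param rounds list of [selex_round()] objects.
#' @export
select_round <- function(rounds) {
  u <- vapply(rounds, unique_ratio, numeric(1))
  t_idx <- vapply(rounds, function(r) as.numeric(r$round), numeric(1))
  elig <- which(u > 0.5)
  if (length(elig) == 0)
    stop("no round satisfies U(T) > 0.5", call. = FALSE)
  # smallest U; ties toward larger round index T
  best <- elig[order(u[elig], -t_idx[elig])][1]
  rounds[[best]]
}

#' Write a SELEX round as unique-sequence FASTA plus count TSV
#' @param round a [selex_round()].
#' @param prefix output prefix (`<prefix>.fasta`, `<prefix>_counts.tsv`).
#' @export
write_selex_round <- function(round, prefix) {
  x <- Biostrings::RNAStringSet(round$sequences)
  names(x) <- sprintf("seq%06d count=%d", seq_along(round$sequences),
                      round$counts)
  Biostrings::writeXStringSet(x, paste0(prefix, ".fasta"))
  utils::write.table(
    data.frame(sequence = round$sequences, count = round$counts),
    paste0(prefix, "_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}
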