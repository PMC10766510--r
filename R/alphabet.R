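#' @useDynLib aptvae, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# RNA alphabet used throughout: A, C, G, U coded 1..4. Code 5 is the padding
# token used only inside the encoder; sequences themselves never contain it.
RNA_LETTERS <- c("A", "C", "G", "U")

#' Encode RNA sequences as integer codes
#'
#' Maps character sequences over the RNA alphabet \{A, C, G, U\} to integer
#' codes 1..4. `T` is accepted and mapped to `U` (sequencers report DNA);
#' lower case is accepted. Any other character is an error.
#'
#' @param x character vector of sequences.
#' @return list of integer vectors, one per sequence.
#' @examples
#' encode_rna(c("ACGU", "acgt"))
#' @export
encode_rna <- function(x) {
  x <- chartr("acgut", "ACGUT", x)
  x <- chartr("T", "U", x)
  lapply(strsplit(x, "", fixed = TRUE), function(ch) {
    code <- match(ch, RNA_LETTERS)
    if (anyNA(code)) {
      bad <- unique(ch[is.na(code)])
      stop("invalid letter(s) in sequence: ", paste(bad, collapse = ", "),
           " (alphabet is A, C, G, U; no ambiguity codes)", call. = FALSE)
    }
    code
  })
}

#' Decode integer codes back to an RNA string
#' @param code integer vector over 1..4.
#' @return single character string.
#' @export
decode_rna <- function(code) {
  paste(RNA_LETTERS[code], collapse = "")
}

# Stack a list of coded sequences into an Lmax x N integer matrix (column
# per sequence, zero-padded at the bottom) plus a length vector. This is the
# layout the C++ forward kernel and the encoder consume.
stack_sequences <- function(codes, max_len = NULL) {
  lens <- lengths(codes)
  if (is.null(max_len)) max_len <- max(lens, 1L)
  if (any(lens > max_len))
    stop("sequence longer than configured maximum length (", max_len, ")",
         call. = FALSE)
  mat <- matrix(0L, nrow = max_len, ncol = length(codes))
  for (i in seq_along(codes)) if (lens[i] > 0) mat[seq_len(lens[i]), i] <- codes[[i]]
  list(mat = mat, lens = as.integer(lens), max_len = as.integer(max_len))
}
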