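#' Validate and normalise a nucleotide sequence
#'
#' Uppercases, converts RNA U to T, and rejects any remaining non-ACGT
#' character, naming the first offending position.
#'
#' @param x character vector of sequences.
#' @param allow_n allow ambiguity code N (reads may carry N; allele
#'   sequences may not).
#' @param what label used in error messages.
#' @return the normalised character vector.
#' @export
normalize_seq <- function(x, allow_n = FALSE, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  ok_chars <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  for (i in seq_along(x)) {
    if (!nzchar(x[[i]])) stop(what, " ", i, " is empty")
    ch <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% ok_chars)
    if (length(bad)) {
      stop(sprintf("invalid character '%s' in %s %s at position %d",
                   ch[bad[1]], what, names(x)[i] %||% i, bad[1]))
    }
  }
  x
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Reverse complement
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) .revcomp_cpp(x)

# reference-consuming length of a cigar string (M + D)
cigar_ref_len <- function(cigar) {
  .cigar_lens_cpp(as.character(cigar))$ref_len
}

# read-consuming length (M + I + S); used for contract checks
cigar_read_len <- function(cigar) {
  .cigar_lens_cpp(as.character(cigar))$read_len
}
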