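# Internal sequence and interval helpers.
#
# Coordinate convention: all internal intervals are 0-based half-open
# [start, end) on the working-sense sequence.  Conversion to the 1-based
# inclusive input-sequence coordinates used in reports happens in one place
# (work_to_input), so the arithmetic is never duplicated.

.CODE_TAB <- local({
  tab <- integer(127L)
  tab[utf8ToInt("ACGTN")] <- 1:5
  tab
})

# map a nucleotide string to integer codes A=1 C=2 G=3 T=4 N=5
seq_codes <- function(s) {
  x <- .CODE_TAB[utf8ToInt(s)]
  x[x == 0L] <- 5L   # any residual ambiguity behaves like N
  x
}

rc <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Nucleotide string over A/C/G/T/N (vectorised).
#' @return The reverse complement(s).
#' @export
revcomp <- function(seq) vapply(seq, rc, character(1L), USE.NAMES = FALSE)

# substring in 0-based half-open coordinates
substr0 <- function(s, start, end) substr(s, start + 1L, end)

iv_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.STOPS <- c("TAA", "TAG", "TGA")

# translate a nucleotide string codon-by-codon; incomplete trailing codon is
# dropped; codons containing anything outside ACGT give "X"
aa_translate <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_stop <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(FALSE)
  any(substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n)) %in% .STOPS)
}

#' Convert working-sense coordinates to input-sequence coordinates
#'
#' Internal intervals are 0-based half-open on the working-sense sequence
#' (the input sequence, reverse-complemented when `sense == "reverse"`).
#' Reports use 1-based inclusive coordinates on the input (forward) sequence.
#'
#' @param start,end 0-based half-open interval on the working sequence.
#' @param sense `"forward"` or `"reverse"`.
#' @param input_length length of the input sequence in nucleotides.
#' @return Integer vector `c(start, end)`, 1-based inclusive on the input.
#' @keywords internal
work_to_input <- function(start, end, sense, input_length) {
  if (sense == "forward") c(start + 1L, end)
  else c(input_length - end + 1L, input_length - start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
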