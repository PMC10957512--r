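# Position weight matrices for RSS and leader motifs.
#
# A PWM models a fixed-length motif as independent per-position nucleotide
# probabilities.  Scores are natural-log likelihoods; an N base contributes
# log(1/4) (uninformative).  Each PWM carries a pass threshold: the default,
# set at build time, is the lowest log-likelihood of any training sequence
# under the finished matrix, so every motif the matrix was trained on passes
# by construction.  RSS motifs may additionally carry an IUPAC consensus
# pattern that Functional classification requires candidates to match.

#' Build a position weight matrix from aligned training motifs
#'
#' Builds per-position nucleotide probabilities with additive smoothing:
#' entry (i, b) = (count of base b at position i + pseudocount) /
#' (n + 4 * pseudocount).  The pass threshold is the minimum log-likelihood
#' of the training sequences under the finished matrix, so no training motif
#' is rejected by its own model.
#'
#' @param training_seqs Character vector of equal-length nucleotide strings
#'   (at least one).
#' @param pseudocount Non-negative smoothing count added to every cell.
#'   Default 0.1 avoids minus-infinity scores for bases unseen in training.
#' @param consensus Optional IUPAC consensus pattern of the same length,
#'   used for Functional classification of RSS motifs.
#' @param name Motif name carried in reports (e.g. `"V_HEPTAMER"`).
#' @return An object of class `vdj_pwm`: probability matrix (`mat`,
#'   positions x A,C,G,T), `threshold`, `pseudocount`, `consensus`, `name`.
#' @examples
#' pwm <- build_pwm(c("CACAGTG", "CACAGTA"), pseudocount = 0.1,
#'                  consensus = "CACAGTG", name = "V_HEPTAMER")
#' score_pwm(pwm, "CACAGTG")
#' @export
build_pwm <- function(training_seqs, pseudocount = 0.1, consensus = NULL,
                      name = "PWM") {
  if (length(training_seqs) < 1L)
    stop("at least one training sequence is required")
  L <- nchar(training_seqs[1L])
  if (any(nchar(training_seqs) != L))
    stop("training sequences must all have the same length")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (!is.null(consensus) && nchar(consensus) != L)
    stop("consensus length must equal motif length")

  codes <- vapply(training_seqs, seq_codes, integer(L))     # L x n
  if (any(codes == 5L))
    stop("training sequences must contain only A, C, G, T")
  n <- length(training_seqs)
  counts <- matrix(0, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in 1:4) counts[, b] <- rowSums(codes == b)
  mat <- (counts + pseudocount) / (n + 4 * pseudocount)
  pwm <- new_pwm(name, mat, pseudocount, threshold = -Inf,
                 consensus = consensus)
  pwm$threshold <- min(vapply(training_seqs,
                              function(s) pwm_loglik(pwm, seq_codes(s), 0L),
                              numeric(1L)))
  pwm
}

new_pwm <- function(name, mat, pseudocount, threshold, consensus = NULL) {
  if (any(abs(rowSums(mat) - 1) > 1e-6))
    stop("PWM rows must sum to 1; first bad position: ",
         which(abs(rowSums(mat) - 1) > 1e-6)[1L])
  # column 5 is the score of an N base at any position
  logmat <- cbind(log(mat), N = rep(log(0.25), nrow(mat)))
  structure(list(name = name, mat = mat, logmat = logmat,
                 pseudocount = pseudocount, threshold = threshold,
                 consensus = consensus),
            class = "vdj_pwm")
}

#' @export
print.vdj_pwm <- function(x, ...) {
  cat(sprintf("PWM %s: length %d, threshold %.3f%s\n", x$name, nrow(x$mat),
              x$threshold,
              if (!is.null(x$consensus)) paste0(", consensus ", x$consensus)
              else ""))
  invisible(x)
}

pwm_length <- function(pwm) nrow(pwm$mat)

# log-likelihood of the length-L window starting at 0-based `start` in the
# coded sequence; caller guarantees the window is in range
pwm_loglik <- function(pwm, codes, start) {
  L <- nrow(pwm$mat)
  sum(pwm$logmat[cbind(seq_len(L), codes[(start + 1L):(start + L)])])
}

# vectorised scan: log-likelihood at each 0-based start position in `starts`
pwm_scan <- function(pwm, codes, starts) {
  L <- nrow(pwm$mat)
  if (length(starts) == 0L) return(numeric(0L))
  idx <- outer(starts, seq_len(L), `+`)           # n x L, 1-based columns
  sc <- matrix(pwm$logmat[cbind(rep(seq_len(L), each = length(starts)),
                                codes[idx])],
               nrow = length(starts))
  rowSums(sc)
}

#' Score a window against a PWM
#'
#' Computes the natural-log likelihood of a window under the PWM
#' (sum over positions of log p_i(base_i); N scores log 0.25) and evaluates
#' the pass threshold and, when the PWM defines one, the IUPAC consensus.
#'
#' @param pwm A [build_pwm()] object.
#' @param window Nucleotide string of exactly the PWM's length.
#' @return A motif hit: list with `position` (`NA`; set by search functions),
#'   `log_likelihood`, `passes_threshold`, `matches_consensus` (`NA` when the
#'   PWM has no consensus).
#' @export
score_pwm <- function(pwm, window) {
  if (nchar(window) != pwm_length(pwm))
    stop("window length ", nchar(window), " != PWM length ", pwm_length(pwm))
  ll <- pwm_loglik(pwm, seq_codes(window), 0L)
  motif_hit_from_ll(pwm, ll, NA_integer_, window)
}

motif_hit_from_ll <- function(pwm, ll, position, window) {
  list(position = position,
       log_likelihood = ll,
       passes_threshold = ll >= pwm$threshold,
       matches_consensus = if (is.null(pwm$consensus)) NA
                           else matches_consensus(window, pwm$consensus),
       sequence = window)
}

#' Test a sequence against an IUPAC consensus pattern
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @param pattern IUPAC pattern of the same length.
#' @return `TRUE` iff every base lies in the IUPAC class of its pattern
#'   position. An N base matches only an N pattern position.
#' @export
matches_consensus <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern))
    stop("sequence and pattern lengths differ")
  pat <- strsplit(toupper(pattern), "")[[1L]]
  bad <- !(pat %in% names(Biostrings::IUPAC_CODE_MAP))
  if (any(bad)) stop("unknown IUPAC code in pattern: ", pat[bad][1L])
  bases <- strsplit(toupper(seq), "")[[1L]]
  all(mapply(function(b, p) {
    if (b == "N") return(p == "N")
    grepl(b, Biostrings::IUPAC_CODE_MAP[[p]], fixed = TRUE)
  }, bases, pat))
}

#' Find the best-scoring placement of a spaced motif pair
#'
#' Exhaustively evaluates every placement of `left_pwm` with its start inside
#' `window` and `right_pwm` separated by a gap in
#' `[spacer - tolerance, spacer + tolerance]`, and returns the placement with
#' the highest joint log-likelihood (sum of the two motif log-likelihoods;
#' the spacer contributes no probability term).  Ties are broken towards the
#' canonical spacer length, then the leftmost position.
#'
#' This is the paired nonamer/heptamer RSS search: for a V 3' RSS the left
#' motif is the heptamer and the right the nonamer; for J and D 5' RSS the
#' order is reversed.
#'
#' @param seq Working-sense nucleotide string to search.
#' @param left_pwm,right_pwm PWMs for the upstream and downstream motifs.
#' @param spacer Canonical gap between the two motifs (12 or 23 nt for RSS).
#' @param tolerance Allowed deviation from `spacer` in nt (default 0).
#' @param window Integer `c(lo, hi)`: allowed 0-based start positions
#'   (inclusive) for the left motif.
#' @return `NULL` if no placement fits, else a list with motif hits `left`
#'   and `right` (each with `position` set), `spacer_used`,
#'   `joint_log_likelihood`, and the `spacer_seq` between the motifs.
#' @export
find_best_motif_pair <- function(seq, left_pwm, right_pwm, spacer,
                                 tolerance = 0L, window) {
  codes <- seq_codes(seq)
  n <- length(codes)
  Ll <- pwm_length(left_pwm); Lr <- pwm_length(right_pwm)
  gaps <- (spacer - tolerance):(spacer + tolerance)
  gaps <- gaps[gaps >= 0L]
  lo <- max(0L, window[1L]); hi <- min(window[2L], n - Ll)
  if (lo > hi) return(NULL)
  starts <- lo:hi
  left_sc <- pwm_scan(left_pwm, codes, starts)

  cand_start <- integer(0L); cand_gap <- integer(0L); cand_joint <- numeric(0L)
  for (gap in gaps) {
    rstarts <- starts + Ll + gap
    ok <- rstarts + Lr <= n
    if (!any(ok)) next
    right_sc <- pwm_scan(right_pwm, codes, rstarts[ok])
    cand_start <- c(cand_start, starts[ok])
    cand_gap <- c(cand_gap, rep(gap, sum(ok)))
    cand_joint <- c(cand_joint, left_sc[ok] + right_sc)
  }
  if (length(cand_joint) == 0L) return(NULL)
  # joint likelihood decides; ties go to the canonical spacer, then leftmost
  i <- order(-cand_joint, abs(cand_gap - spacer), cand_start)[1L]
  ls <- cand_start[i]
  rs <- ls + Ll + cand_gap[i]
  best <- list(gap = cand_gap[i], joint = cand_joint[i])
  lwin <- substr0(seq, ls, ls + Ll)
  rwin <- substr0(seq, rs, rs + Lr)
  list(left = motif_hit_from_ll(left_pwm, pwm_loglik(left_pwm, codes, ls),
                                ls, lwin),
       right = motif_hit_from_ll(right_pwm, pwm_loglik(right_pwm, codes, rs),
                                 rs, rwin),
       spacer_used = best$gap,
       joint_log_likelihood = best$joint,
       spacer_seq = substr0(seq, ls + Ll, rs))
}
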