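# Shared fixtures and independent oracles used across test files.

# deterministic random nucleotide string
rnt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = "")

# brute-force oracle for find_best_motif_pair: full cross product of
# placements, scored with score_pwm, same tie-break order
bf_motif_pair <- function(seq, left, right, spacer, tolerance, window) {
  Ll <- nrow(left$mat); Lr <- nrow(right$mat)
  n <- nchar(seq)
  best <- NULL
  for (s in max(0, window[1]):min(window[2], n - Ll)) {
    for (gap in (spacer - tolerance):(spacer + tolerance)) {
      if (gap < 0) next
      rs <- s + Ll + gap
      if (rs + Lr > n) next
      lsc <- score_pwm(left, substr(seq, s + 1, s + Ll))$log_likelihood
      rsc <- score_pwm(right, substr(seq, rs + 1, rs + Lr))$log_likelihood
      cand <- list(start = s, gap = gap, joint = lsc + rsc)
      if (is.null(best) || cand$joint > best$joint ||
          (cand$joint == best$joint &&
           (abs(cand$gap - spacer) < abs(best$gap - spacer) ||
            (abs(cand$gap - spacer) == abs(best$gap - spacer) &&
             cand$start < best$start))))
        best <- cand
    }
  }
  best
}

# IUPAC membership oracle by explicit class expansion
iupac_classes <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))
bf_matches <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(mapply(function(b, pc) b %in% iupac_classes[[pc]], s, p))
}

# minimal annotation stub for overlap-resolution tests (input coordinates,
# 1-based inclusive)
fake_annotation <- function(start, end, functionality, ll,
                            gene_type = "V", name = "X*01") {
  structure(list(gene_type = gene_type, sense = "forward",
                 input_length = 10000L,
                 features = list(),
                 closest_reference = name, percent_identity = 100,
                 functionality = functionality,
                 joint_log_likelihood = ll,
                 input_start = start, input_end = end,
                 notes = character(0)),
            class = "vdj_annotation")
}

# independent oracle for overlap resolution: keep all Functional, then
# repeatedly scan for the best-priority unresolved non-functional (highest
# joint likelihood, then longest, leftmost, name), keeping it unless it
# overlaps something already kept
bf_resolve <- function(anns) {
  n <- length(anns)
  if (n == 0) return(anns)
  st <- vapply(anns, `[[`, numeric(1), "input_start")
  en <- vapply(anns, `[[`, numeric(1), "input_end")
  ov <- outer(seq_len(n), seq_len(n),
              Vectorize(function(i, j) st[i] <= en[j] && st[j] <= en[i]))
  fun <- vapply(anns, `[[`, "", "functionality") == "Functional"
  ll <- vapply(anns, `[[`, numeric(1), "joint_log_likelihood")
  nm <- vapply(anns, `[[`, "", "closest_reference")
  kept <- which(fun)
  pending <- which(!fun)
  while (length(pending) > 0) {
    best <- pending[1]
    for (i in pending)
      if (ll[i] > ll[best] ||
          (ll[i] == ll[best] &&
           ((en[i] - st[i]) > (en[best] - st[best]) ||
            ((en[i] - st[i]) == (en[best] - st[best]) &&
             (st[i] < st[best] ||
              (st[i] == st[best] && nm[i] < nm[best]))))))
        best <- i
    if (!any(ov[best, kept])) kept <- c(kept, best)
    pending <- setdiff(pending, best)
  }
  anns[sort(kept)]
}

ann_key <- function(a) paste(a$gene_type, a$input_start, a$input_end,
                             a$functionality, a$closest_reference,
                             a$joint_log_likelihood)

# shared fixtures built once per test run
test_motifs <- synthetic_motif_set()
test_refset <- synthetic_reference_set(n_v = 12, n_d = 6, n_j = 6, seed = 42)
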