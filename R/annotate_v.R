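# V gene annotation: 3' RSS localisation with boundary adjustment, leader
# (L-PART1/L-PART2) detection, IMGT position mapping of the conserved
# cysteines, and functionality classification.

#' Locate the 3' RSS of a V candidate and adjust the V-REGION end
#'
#' Searches heptamer start positions in
#' `[end - v_end_adjust_max, end + rss_search_window]` for the best joint
#' heptamer + spacer + nonamer placement; the V-REGION 3' end is moved to the
#' heptamer start (the heptamer abuts the V-REGION).
#'
#' @param assembly Working-sense [assembly()].
#' @param candidate One-row extended candidate (`gene_type == "V"`).
#' @param pwms Named PWM list containing `V_HEPTAMER` and `V_NONAMER`.
#' @param config A [locus_config()].
#' @return List with `rss` (motif pair from [find_best_motif_pair()], or
#'   `NULL`), `v_end` (possibly adjusted), `notes`.
#' @export
locate_v_rss <- function(assembly, candidate, pwms, config) {
  stopifnot(candidate$gene_type == "V")
  e <- candidate$end
  pair <- find_best_motif_pair(
    assembly$seq, pwms$V_HEPTAMER, pwms$V_NONAMER,
    spacer = config$v_spacer, tolerance = config$spacer_tolerance,
    window = c(e - config$v_end_adjust_max, e + config$rss_search_window))
  if (is.null(pair))
    return(list(rss = NULL, v_end = e, notes = "V RSS not found"))
  # a degenerate window (all N) carries no motif information
  if (grepl("^N+$", pair$left$sequence) && grepl("^N+$", pair$right$sequence))
    return(list(rss = NULL, v_end = e,
                notes = "V RSS region contains only N"))
  list(rss = pair, v_end = pair$left$position, notes = character(0L))
}

#' Locate the leader (L-PART1 / L-PART2) of a V candidate
#'
#' L-PART2 is the fixed window of `l_part2_length` nt ending at the V-REGION
#' start, required to be preceded by an AG acceptor dinucleotide.  L-PART1
#' candidates are PWM-length windows upstream (within
#' `leader_search_window`) followed by a GT donor.  Placements where the
#' spliced leader starts with ATG, is stop-free and is in frame with the
#' V-REGION are preferred; joint PWM log-likelihood breaks ties.
#'
#' @inheritParams locate_v_rss
#' @param v_start 0-based V-REGION start (defaults to `candidate$start`).
#' @return A leader call (list with `l_part1`, `l_part2`, `intron`
#'   intervals, motif hits `l_part1_hit`/`l_part2_hit`, `donor_present`,
#'   `acceptor_present`, `leader_peptide`, `in_frame_with_v`, `stop_free`,
#'   `valid`, `joint_log_likelihood`) or `NULL` when no placement exists.
#' @export
locate_leader <- function(assembly, candidate, pwms, config,
                          v_start = candidate$start) {
  stopifnot(candidate$gene_type == "V")
  seq <- assembly$seq
  codes <- seq_codes(seq)
  s <- v_start
  lp2_len <- config$l_part2_length
  lp1_len <- pwm_length(pwms$L_PART1)
  if (pwm_length(pwms$L_PART2) != lp2_len)
    stop("L_PART2 PWM length (", pwm_length(pwms$L_PART2),
         ") does not match configured l_part2_length (", lp2_len, ")")
  # acceptor: AG immediately upstream of L-PART2
  if (s - lp2_len - 2L < 0L) return(NULL)
  if (substr0(seq, s - lp2_len - 2L, s - lp2_len) != "AG") return(NULL)
  lp2_start <- s - lp2_len
  lp2_hit <- motif_hit_from_ll(pwms$L_PART2,
                               pwm_loglik(pwms$L_PART2, codes, lp2_start),
                               lp2_start, substr0(seq, lp2_start, s))
  # L-PART1 placements: window followed by GT donor, upstream of the acceptor
  lo <- max(0L, s - config$leader_search_window)
  hi <- s - lp2_len - 2L - 2L - lp1_len   # GT donor + AG acceptor must fit
  if (hi < lo) return(NULL)
  starts <- lo:hi
  donor_ok <- substring(seq, starts + lp1_len + 1L,
                        starts + lp1_len + 2L) == "GT"
  starts <- starts[donor_ok]
  if (length(starts) == 0L) return(NULL)
  sc1 <- pwm_scan(pwms$L_PART1, codes, starts)
  lp1_seqs <- substring(seq, starts + 1L, starts + lp1_len)
  spliced <- paste0(lp1_seqs, lp2_hit$sequence)
  starts_atg <- substring(spliced, 1L, 3L) == "ATG"
  stop_free <- !vapply(spliced, has_stop, logical(1L), USE.NAMES = FALSE)
  in_frame <- (nchar(spliced) %% 3L) == 0L
  valid <- starts_atg & stop_free & in_frame
  joint <- sc1 + lp2_hit$log_likelihood
  i <- order(!valid, -joint, starts)[1L]
  lp1_start <- starts[i]
  lp1_hit <- motif_hit_from_ll(pwms$L_PART1, sc1[i], lp1_start, lp1_seqs[i])
  list(l_part1 = c(lp1_start, lp1_start + lp1_len),
       l_part2 = c(lp2_start, s),
       intron = c(lp1_start + lp1_len, lp2_start),
       l_part1_hit = lp1_hit, l_part2_hit = lp2_hit,
       donor_present = TRUE, acceptor_present = TRUE,
       leader_peptide = aa_translate(spliced[i]),
       in_frame_with_v = in_frame[i],
       stop_free = stop_free[i],
       starts_with_atg = starts_atg[i],
       valid = valid[i],
       joint_log_likelihood = joint[i])
}

#' Map a V sequence onto IMGT positions via a gapped reference
#'
#' Globally aligns the candidate V sequence to the closest allele's ungapped
#' sequence, then transfers the allele's IMGT gap pattern so that conserved
#' positions can be read off: Cys23 (gapped columns 67-69) and Cys104
#' (columns 310-312) are checked for TGT/TGC, and stop codons are located
#' relative to position 104.  When the allele has no gapped sequence, its
#' ungapped sequence is used as a gap-free alignment and a note records the
#' lower-confidence mode.
#'
#' @param v_seq Candidate V-REGION nucleotide string.
#' @param refset [reference_set()].
#' @param matched_allele Name of the closest allele.
#' @return List with `in_frame`, `cys23_present`, `cys104_present`,
#'   `stop_before_cys104`, `stop_after_cys104`, `any_stop`,
#'   `gapped_alignment_used`, `notes`.
#' @export
map_to_imgt_positions <- function(v_seq, refset, matched_allele) {
  al <- ref_allele(refset, matched_allele)
  notes <- character(0L)
  gapped <- al$gapped
  if (is.na(gapped)) {
    gapped <- al$seq
    notes <- c(notes,
               "no gapped reference; IMGT positions from ungapped alignment")
  }
  gapped <- chartr("-", ".", gapped)
  # map reference ungapped position -> gapped column
  gchars <- strsplit(gapped, "")[[1L]]
  ref_cols <- which(gchars != ".")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(v_seq),
                                       Biostrings::DNAString(al$seq),
                                       type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 5, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gv <- rep(".", length(gchars))
  rpos <- 0L
  had_insertion <- FALSE
  for (k in seq_along(ap)) {
    if (as_[k] != "-") {
      rpos <- rpos + 1L
      if (ap[k] != "-") gv[ref_cols[rpos]] <- ap[k]
    } else if (ap[k] != "-") {
      had_insertion <- TRUE
    }
  }
  if (had_insertion)
    notes <- c(notes, "insertion relative to reference not representable in IMGT alignment")
  # frame is preserved iff every indel run has a length divisible by 3
  run_lengths <- function(x) with(rle(x), lengths[values])
  indels <- c(run_lengths(ap == "-"), run_lengths(as_ == "-"))
  in_frame <- all(indels %% 3L == 0L)
  ncod <- length(gv) %/% 3L
  codons <- vapply(seq_len(ncod), function(ci)
    paste(gv[(3L * ci - 2L):(3L * ci)], collapse = ""), character(1L))
  full <- !grepl("\\.", codons)
  cys <- function(ci) ci <= ncod && full[ci] && codons[ci] %in% c("TGT", "TGC")
  stops <- which(full & codons %in% .STOPS)
  list(in_frame = in_frame,
       cys23_present = cys(23L),
       cys104_present = cys(104L),
       stop_before_cys104 = any(stops <= 104L),
       stop_after_cys104 = any(stops > 104L),
       any_stop = length(stops) > 0L,
       gapped_alignment_used = matched_allele,
       notes = notes)
}

#' Classify a V gene
#'
#' Functional requires: both RSS motifs pass their PWM thresholds and match
#' the canonical consensus when one is defined; a leader whose two parts pass
#' their thresholds and splice to a stop-free sequence in frame with the
#' V-REGION; the V-REGION in frame with conserved cysteines at IMGT positions
#' 23 and 104 and no stop codon at or before position 104.  A stop codon
#' strictly after position 104 does not block Functional (its nucleotides may
#' be excised during junction formation) but is noted.  Failing candidates
#' are ORF when the V-REGION is entirely stop-free, else pseudogene.
#'
#' @param leader Leader call from [locate_leader()] or `NULL`.
#' @param rss Motif pair from [locate_v_rss()] or `NULL`.
#' @param vcheck Result of [map_to_imgt_positions()].
#' @return List with `functionality` (`"Functional"`, `"ORF"`,
#'   `"pseudogene"`) and `notes`.
#' @export
classify_v <- function(leader, rss, vcheck) {
  notes <- character(0L)
  rss_ok <- !is.null(rss) &&
    rss$left$passes_threshold && rss$right$passes_threshold &&
    !isFALSE(rss$left$matches_consensus) &&
    !isFALSE(rss$right$matches_consensus)
  leader_ok <- !is.null(leader) && leader$valid &&
    leader$l_part1_hit$passes_threshold && leader$l_part2_hit$passes_threshold
  v_ok <- vcheck$in_frame && vcheck$cys23_present && vcheck$cys104_present &&
    !vcheck$stop_before_cys104
  if (!rss_ok) notes <- c(notes, "RSS check failed")
  if (is.null(leader)) notes <- c(notes, "leader not found")
  else if (!leader_ok) notes <- c(notes, "leader check failed")
  if (!v_ok) notes <- c(notes, "V-REGION check failed")
  if (vcheck$stop_after_cys104)
    notes <- c(notes, "stop codon after IMGT position 104")
  functionality <-
    if (rss_ok && leader_ok && v_ok) "Functional"
    else if (!vcheck$any_stop) "ORF"
    else "pseudogene"
  list(functionality = functionality, notes = notes)
}

# Full V candidate annotation: RSS, leader, IMGT checks, classification.
annotate_v_candidate <- function(assembly, candidate, pwms, config, refset) {
  notes <- character(0L)
  if (nzchar(candidate$note)) notes <- c(notes, candidate$note)
  res <- locate_v_rss(assembly, candidate, pwms, config)
  notes <- c(notes, res$notes)
  v_start <- candidate$start
  v_end <- res$v_end
  leader <- locate_leader(assembly, candidate, pwms, config, v_start = v_start)
  if (is.null(leader)) notes <- c(notes, "leader not found")
  v_seq <- substr0(assembly$seq, v_start, v_end)
  vcheck <- map_to_imgt_positions(v_seq, refset, candidate$allele)
  notes <- c(notes, vcheck$notes)
  cls <- classify_v(leader, res$rss, vcheck)
  notes <- unique(c(notes, cls$notes))

  feats <- list(v_region = list(start = v_start, end = v_end, seq = v_seq))
  ll <- 0
  if (!is.null(res$rss)) {
    hp <- res$rss$left; np <- res$rss$right
    feats$heptamer_3 <- list(start = hp$position, end = hp$position + 7L,
                             seq = hp$sequence)
    feats$spacer_3 <- list(start = hp$position + 7L, end = np$position,
                           seq = res$rss$spacer_seq)
    feats$nonamer_3 <- list(start = np$position, end = np$position + 9L,
                            seq = np$sequence)
    ll <- ll + res$rss$joint_log_likelihood
  } else ll <- ll - 1e5
  if (!is.null(leader)) {
    feats$l_part1 <- list(start = leader$l_part1[1L], end = leader$l_part1[2L],
                          seq = leader$l_part1_hit$sequence)
    feats$l_part2 <- list(start = leader$l_part2[1L], end = leader$l_part2[2L],
                          seq = leader$l_part2_hit$sequence)
    ll <- ll + leader$joint_log_likelihood
  } else ll <- ll - 1e5
  new_annotation(assembly, "V", feats, candidate, cls$functionality, ll, notes)
}
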