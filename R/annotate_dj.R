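# D and J gene annotation: RSS localisation at both D ends and the J 5' end,
# J-motif and donor splice detection, and functionality classification.

#' Locate both RSS of a D candidate
#'
#' Finds the best nonamer-spacer-heptamer placement upstream (heptamer
#' abutting the D-REGION start) and heptamer-spacer-nonamer placement
#' downstream, each with the configured spacer (12 nt by default), allowing
#' the D-REGION boundaries to move by up to `d_end_adjust_max` nt to meet
#' the heptamers.
#'
#' @param assembly Working-sense [assembly()].
#' @param candidate One-row extended candidate (`gene_type == "D"`).
#' @param pwms Named PWM list with `D5_NONAMER`, `D5_HEPTAMER`,
#'   `D3_HEPTAMER`, `D3_NONAMER`.
#' @param config A [locus_config()].
#' @return A D call (list with `d_region` interval, `rss5`, `rss3` motif
#'   pairs, `joint_log_likelihood`) or `NULL` when either end has no
#'   placement.
#' @export
locate_d_rss_pair <- function(assembly, candidate, pwms, config) {
  stopifnot(candidate$gene_type == "D")
  adj <- config$d_end_adjust_max
  s <- candidate$start; e <- candidate$end
  # upstream: nonamer start such that heptamer end lands within s +/- adj
  up_off <- 9L + config$d5_spacer + 7L
  rss5 <- find_best_motif_pair(
    assembly$seq, pwms$D5_NONAMER, pwms$D5_HEPTAMER,
    spacer = config$d5_spacer, tolerance = config$spacer_tolerance,
    window = c(s - up_off - adj, s - up_off + adj))
  if (is.null(rss5)) return(NULL)
  rss3 <- find_best_motif_pair(
    assembly$seq, pwms$D3_HEPTAMER, pwms$D3_NONAMER,
    spacer = config$d3_spacer, tolerance = config$spacer_tolerance,
    window = c(e - adj, e + adj))
  if (is.null(rss3)) return(NULL)
  d_start <- rss5$right$position + 7L   # 5' heptamer end
  d_end <- rss3$left$position           # 3' heptamer start
  if (d_end <= d_start) return(NULL)
  list(d_region = c(d_start, d_end), rss5 = rss5, rss3 = rss3,
       joint_log_likelihood = rss5$joint_log_likelihood +
         rss3$joint_log_likelihood)
}

#' Classify a D gene
#'
#' A D candidate is retained only if all four RSS motifs (both nonamers and
#' both heptamers) pass their PWM thresholds — the RSS criterion is the only
#' check available for D genes.  Retained candidates are Functional when
#' every motif also matches the canonical consensus (where one is defined),
#' otherwise ORF.  D genes are never classified pseudogene: a D-REGION has
#' no reading frame of its own before rearrangement.
#'
#' @param dcall Result of [locate_d_rss_pair()].
#' @return List with `retained` (logical), `functionality`
#'   (`NA` when dropped), `notes`.
#' @export
classify_d <- function(dcall) {
  hits <- list(dcall$rss5$left, dcall$rss5$right,
               dcall$rss3$left, dcall$rss3$right)
  passes <- vapply(hits, `[[`, logical(1L), "passes_threshold")
  if (!all(passes))
    return(list(retained = FALSE, functionality = NA_character_,
                notes = "RSS motif below PWM threshold"))
  cons <- vapply(hits, `[[`, logical(1L), "matches_consensus")
  if (any(!cons, na.rm = TRUE))
    list(retained = TRUE, functionality = "ORF",
         notes = "RSS motif does not match canonical consensus")
  else
    list(retained = TRUE, functionality = "Functional", notes = character(0L))
}

#' Locate the 5' RSS of a J candidate
#'
#' Searches for the best nonamer-spacer-heptamer placement with the heptamer
#' end within `j_start_adjust_max` nt of the matched J start; the J-REGION
#' start is moved to the heptamer end.  The candidate is retained when at
#' least one of the two motifs passes its PWM threshold.
#'
#' @inheritParams locate_d_rss_pair
#' @return List with `rss` (motif pair), `j_start` (adjusted) or `NULL`
#'   when no placement fits or neither motif passes.
#' @export
locate_j_rss <- function(assembly, candidate, pwms, config) {
  stopifnot(candidate$gene_type == "J")
  adj <- config$j_start_adjust_max
  s <- candidate$start
  up_off <- 9L + config$j_spacer + 7L
  rss <- find_best_motif_pair(
    assembly$seq, pwms$J_NONAMER, pwms$J_HEPTAMER,
    spacer = config$j_spacer, tolerance = config$spacer_tolerance,
    window = c(s - up_off - adj, s - up_off + adj))
  if (is.null(rss)) return(NULL)
  if (!rss$left$passes_threshold && !rss$right$passes_threshold) return(NULL)
  list(rss = rss, j_start = rss$right$position + 7L)
}

#' Locate the J-motif and donor splice of a J gene
#'
#' The J-motif (IUPAC pattern, default `TKGGGG`, the nucleotide start of the
#' conserved [W/F]-G-X-G) is sought at `j_motif_offset` nt upstream of the
#' J-REGION 3' end, allowing frame-preserving shifts (multiples of 3) within
#' `j_motif_tolerance`.  The donor splice is the GT dinucleotide immediately
#' after the J-REGION end.
#'
#' @param assembly Working-sense [assembly()].
#' @param j_region 0-based half-open J-REGION interval.
#' @param config A [locus_config()].
#' @return List with `j_motif` interval or `NULL`, `donor_splice` position
#'   or `NULL`, `notes`.
#' @export
locate_j_motif_and_splice <- function(assembly, j_region, config) {
  seq <- assembly$seq
  js <- j_region[1L]; je <- j_region[2L]
  plen <- nchar(config$j_motif_pattern)
  shifts <- seq(-3L * (config$j_motif_tolerance %/% 3L),
                3L * (config$j_motif_tolerance %/% 3L), by = 3L)
  motif <- NULL
  notes <- character(0L)
  for (sh in shifts[order(abs(shifts))]) {
    p <- je - config$j_motif_offset + sh
    if (p < js || p + plen > je) next
    if (matches_consensus(substr0(seq, p, p + plen),
                          config$j_motif_pattern)) {
      motif <- c(p, p + plen)
      break
    }
  }
  if (is.null(motif)) notes <- c(notes, "J-motif not found")
  donor <- NULL
  if (je + 2L <= nchar(seq) && substr0(seq, je, je + 2L) == "GT")
    donor <- je
  else notes <- c(notes, "donor splice not found")
  list(j_motif = motif, donor_splice = donor, notes = notes)
}

#' Classify a J gene
#'
#' Functional requires both RSS motifs to pass their PWM thresholds (and
#' match the canonical consensus when defined), the J-motif at its expected
#' position and the donor splice present.  Stop codons in frame upstream of
#' the J-motif do not block Functional (they may be excised during junction
#' formation) but are noted; a stop at or after the J-motif makes the gene a
#' pseudogene.  Non-functional, stop-free candidates are ORF.
#'
#' @param jcall List with `rss` (motif pair), `j_region` interval,
#'   `j_motif`, `donor_splice`, and `seq` (working-sense assembly string).
#' @return List with `functionality` and `notes`.
#' @export
classify_j <- function(jcall) {
  notes <- character(0L)
  rss_ok <- jcall$rss$left$passes_threshold &&
    jcall$rss$right$passes_threshold &&
    !isFALSE(jcall$rss$left$matches_consensus) &&
    !isFALSE(jcall$rss$right$matches_consensus)
  if (!rss_ok) notes <- c(notes, "RSS check failed")
  motif_ok <- !is.null(jcall$j_motif)
  donor_ok <- !is.null(jcall$donor_splice)
  js <- jcall$j_region[1L]; je <- jcall$j_region[2L]
  # reading frame anchored at the J-motif (or its expected position)
  anchor <- if (motif_ok) jcall$j_motif[1L]
            else je - jcall$expected_motif_offset
  anchor <- max(js, min(anchor, je))
  up_starts <- if (anchor - 3L >= js) seq(anchor - 3L, js, by = -3L)
               else integer(0L)
  down_starts <- if (anchor <= je - 3L) seq(anchor, je - 3L, by = 3L)
                 else integer(0L)
  codon_at <- function(p) substr0(jcall$seq, p, p + 3L)
  stop_up <- any(vapply(up_starts, codon_at, "") %in% .STOPS)
  stop_down <- any(vapply(down_starts, codon_at, "") %in% .STOPS)
  if (stop_up)
    notes <- c(notes, "stop codon upstream of J-motif")
  if (!motif_ok) notes <- c(notes, "J-motif not found")
  if (!donor_ok) notes <- c(notes, "donor splice not found")
  functionality <-
    if (rss_ok && motif_ok && donor_ok && !stop_down) "Functional"
    else if (!stop_down) "ORF"
    else "pseudogene"
  list(functionality = functionality, notes = notes)
}

# Full D candidate annotation; NULL when the candidate is dropped.
annotate_d_candidate <- function(assembly, candidate, pwms, config) {
  dcall <- locate_d_rss_pair(assembly, candidate, pwms, config)
  if (is.null(dcall)) return(NULL)
  cls <- classify_d(dcall)
  if (!cls$retained) return(NULL)
  notes <- cls$notes
  if (nzchar(candidate$note)) notes <- c(candidate$note, notes)
  ds <- dcall$d_region[1L]; de <- dcall$d_region[2L]
  feats <- list(
    nonamer_5 = hit_feature(dcall$rss5$left, 9L),
    spacer_5 = list(start = dcall$rss5$left$position + 9L,
                    end = dcall$rss5$right$position,
                    seq = dcall$rss5$spacer_seq),
    heptamer_5 = hit_feature(dcall$rss5$right, 7L),
    d_region = list(start = ds, end = de,
                    seq = substr0(assembly$seq, ds, de)),
    heptamer_3 = hit_feature(dcall$rss3$left, 7L),
    spacer_3 = list(start = dcall$rss3$left$position + 7L,
                    end = dcall$rss3$right$position,
                    seq = dcall$rss3$spacer_seq),
    nonamer_3 = hit_feature(dcall$rss3$right, 9L))
  new_annotation(assembly, "D", feats, candidate, cls$functionality,
                 dcall$joint_log_likelihood, notes)
}

# Full J candidate annotation; NULL when the candidate is dropped.
annotate_j_candidate <- function(assembly, candidate, pwms, config) {
  jr <- locate_j_rss(assembly, candidate, pwms, config)
  if (is.null(jr)) return(NULL)
  j_region <- c(jr$j_start, candidate$end)
  ms <- locate_j_motif_and_splice(assembly, j_region, config)
  jcall <- list(rss = jr$rss, j_region = j_region, j_motif = ms$j_motif,
                donor_splice = ms$donor_splice, seq = assembly$seq,
                expected_motif_offset = config$j_motif_offset)
  cls <- classify_j(jcall)
  notes <- unique(c(if (nzchar(candidate$note)) candidate$note, ms$notes,
                    cls$notes))
  feats <- list(
    nonamer_5 = hit_feature(jr$rss$left, 9L),
    spacer_5 = list(start = jr$rss$left$position + 9L,
                    end = jr$rss$right$position, seq = jr$rss$spacer_seq),
    heptamer_5 = hit_feature(jr$rss$right, 7L),
    j_region = list(start = j_region[1L], end = j_region[2L],
                    seq = substr0(assembly$seq, j_region[1L], j_region[2L])))
  if (!is.null(ms$j_motif))
    feats$j_motif <- list(start = ms$j_motif[1L], end = ms$j_motif[2L],
                          seq = substr0(assembly$seq, ms$j_motif[1L],
                                        ms$j_motif[2L]))
  if (!is.null(ms$donor_splice))
    feats$donor_splice <- list(start = ms$donor_splice,
                               end = ms$donor_splice + 2L,
                               seq = substr0(assembly$seq, ms$donor_splice,
                                             ms$donor_splice + 2L))
  new_annotation(assembly, "J", feats, candidate, cls$functionality,
                 jr$rss$joint_log_likelihood, notes)
}

hit_feature <- function(hit, len) {
  list(start = hit$position, end = hit$position + len, seq = hit$sequence)
}
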