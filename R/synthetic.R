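# Synthetic locus simulator: assemblies with implanted, fully specified
# V/D/J genes and a ground-truth table, so every pipeline stage is testable
# without external data.
#
# The shipped motif training sets are synthetic: canonical RSS
# heptamer/nonamer sequences plus single-mismatch variants, and invented
# leader exons modelled on heavy-chain leaders.  They define a miniature
# IGH-like locus (V genes with 23-nt spacers, D genes with 12-nt spacers on
# both sides, J genes with 23-nt spacers), not any real species' parameters.

#' Synthetic motif training sequences
#'
#' Canonical RSS motifs with single-mismatch variants (so that PWM
#' thresholds admit slightly divergent motifs while the consensus pattern
#' stays strict), plus invented 46-nt L-PART1 and 11-nt L-PART2 exons whose
#' every pairing splices to a 57-nt, ATG-initiated, stop-free leader.
#'
#' @return Named list per motif with `seqs` and optional `consensus`.
#' @export
default_motif_training <- function() {
  hept_fwd <- c("CACAGTG", "CACAGTG", "CACAGTG",
                "CACAGTA", "CACAATG", "CACTGTG")
  nona_fwd <- c("ACAAAAACC", "ACAAAAACC", "ACAAAAACC",
                "ACAAAAACT", "ACATAAACC", "GCAAAAACC")
  hept_rc <- vapply(hept_fwd, rc, "", USE.NAMES = FALSE)
  nona_rc <- vapply(nona_fwd, rc, "", USE.NAMES = FALSE)
  l1 <- c("ATGGACTGGACCTGGAGGATCCTCTTCTTGGTGGCAGCAGCCACAG",
          "ATGGACTGGGCCTGGAGGATCCTCTTCTTGGTGGCAGCAGCCACAG",
          "ATGGACTGGACCTGGAAGATCCTCTTCTTGGTGGCAGCAGCCACAG",
          "ATGGACTGGACCTGGAGGATCCTCTTCTTGCTGGCAGCAGCCACAG")
  l2 <- c("GTGTCCAGTGT", "GTGTCCATTGT", "GTATCCAGTGT", "GTGTCCAGTCT")
  list(V_HEPTAMER = list(seqs = hept_fwd, consensus = "CACAGTG"),
       V_NONAMER = list(seqs = nona_fwd, consensus = "ACAAAAACC"),
       D3_HEPTAMER = list(seqs = hept_fwd, consensus = "CACAGTG"),
       D3_NONAMER = list(seqs = nona_fwd, consensus = "ACAAAAACC"),
       D5_HEPTAMER = list(seqs = hept_rc, consensus = "CACTGTG"),
       D5_NONAMER = list(seqs = nona_rc, consensus = "GGTTTTTGT"),
       J_HEPTAMER = list(seqs = hept_rc, consensus = "CACTGTG"),
       J_NONAMER = list(seqs = nona_rc, consensus = "GGTTTTTGT"),
       L_PART1 = list(seqs = l1, consensus = NULL),
       L_PART2 = list(seqs = l2, consensus = NULL))
}

#' Build the synthetic motif set
#'
#' @param pseudocount Passed to [build_pwm()].
#' @return List with `pwms` (named PWMs), `config` (a [locus_config()])
#'   and `training` (the training sequences).
#' @export
synthetic_motif_set <- function(pseudocount = 0.1) {
  training <- default_motif_training()
  pwms <- lapply(names(training), function(nm)
    build_pwm(training[[nm]]$seqs, pseudocount = pseudocount,
              consensus = training[[nm]]$consensus, name = nm))
  names(pwms) <- names(training)
  list(pwms = pwms, config = locus_config(), training = training)
}

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

random_codons <- function(n) paste(sample(.NONSTOP_CODONS, n, replace = TRUE),
                                   collapse = "")

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Generate a synthetic germline reference set
#'
#' V alleles are 318 nt (106 codons) of random non-stop codons with
#' conserved cysteines at IMGT positions 23 (TGT) and 104 (TGC); their
#' gapped sequences equal the ungapped ones (a gap-free IMGT alignment).
#' D alleles are short random sequences (the first is 8 nt, the documented
#' minimum; the rest 12-25 nt).  J alleles are 52 nt with the J-motif
#' (TGGGGG, Trp-Gly) 34 nt upstream of their 3' end and no stop codon in
#' the motif reading frame.
#'
#' @param n_v,n_d,n_j Number of alleles per gene type.
#' @param seed RNG seed.
#' @return A [reference_set()].
#' @export
synthetic_reference_set <- function(n_v = 12L, n_d = 6L, n_j = 6L,
                                    seed = 1L) {
  set.seed(seed)
  v_seqs <- vapply(seq_len(n_v), function(i) {
    s <- random_codons(106L)
    substr(s, 67L, 69L) <- "TGT"    # Cys23
    substr(s, 310L, 312L) <- "TGC"  # Cys104
    s
  }, character(1L))
  d_len <- c(8L, sample(12:25, max(0L, n_d - 1L), replace = TRUE))[seq_len(n_d)]
  d_seqs <- vapply(d_len, random_nt, character(1L))
  j_seqs <- vapply(seq_len(n_j), function(i) {
    paste0(random_codons(6L), "TGGGGG", random_codons(9L), random_nt(1L))
  }, character(1L))
  reference_set(
    name = c(sprintf("IGHV1-%d*01", seq_len(n_v)),
             sprintf("IGHD1-%d*01", seq_len(n_d)),
             sprintf("IGHJ%d*01", seq_len(n_j))),
    gene_type = rep(c("V", "D", "J"), c(n_v, n_d, n_j)),
    seq = c(v_seqs, d_seqs, j_seqs),
    gapped = c(v_seqs, rep(NA_character_, n_d + n_j)),
    species = "synthetic")
}

# sample a motif from a PWM, rejecting draws that fail the PWM's own
# threshold or consensus; falls back to the per-position argmax (which by
# construction scores maximally and matches the consensus)
sample_motif <- function(pwm, tries = 50L) {
  b <- c("A", "C", "G", "T")
  L <- pwm_length(pwm)
  for (t in seq_len(tries)) {
    s <- paste(vapply(seq_len(L), function(i)
      sample(b, 1L, prob = pwm$mat[i, ]), character(1L)), collapse = "")
    hit <- score_pwm(pwm, s)
    if (hit$passes_threshold && !isFALSE(hit$matches_consensus)) return(s)
  }
  paste(b[apply(pwm$mat, 1L, which.max)], collapse = "")
}

# sample a leader pair that splices to an ATG-initiated, stop-free,
# in-frame leader with both parts passing their thresholds
sample_leader <- function(pwms, tries = 100L) {
  for (t in seq_len(tries)) {
    l1 <- sample_motif(pwms$L_PART1, tries = 1L)
    l2 <- sample_motif(pwms$L_PART2, tries = 1L)
    spliced <- paste0(l1, l2)
    if (score_pwm(pwms$L_PART1, l1)$passes_threshold &&
        score_pwm(pwms$L_PART2, l2)$passes_threshold &&
        substr(spliced, 1L, 3L) == "ATG" &&
        !has_stop(spliced) && nchar(spliced) %% 3L == 0L)
      return(list(l1 = l1, l2 = l2))
  }
  b <- c("A", "C", "G", "T")
  list(l1 = paste(b[apply(pwms$L_PART1$mat, 1L, which.max)], collapse = ""),
       l2 = paste(b[apply(pwms$L_PART2$mat, 1L, which.max)], collapse = ""))
}

# build one gene segment; returns seq plus features as 0-based half-open
# intervals relative to the segment start
build_v_segment <- function(allele, pwms, config) {
  leader <- sample_leader(pwms)
  intron_mid <- random_nt(sample(60:120, 1L))
  hept <- sample_motif(pwms$V_HEPTAMER)
  spacer <- random_nt(config$v_spacer)
  nona <- sample_motif(pwms$V_NONAMER)
  l1_len <- nchar(leader$l1); l2_len <- nchar(leader$l2)
  intron <- paste0("GT", intron_mid, "AG")
  seq <- paste0(leader$l1, intron, leader$l2, allele$seq, hept, spacer, nona)
  p <- 0L
  f <- list()
  f$l_part1 <- c(0L, l1_len); p <- l1_len + nchar(intron)
  f$l_part2 <- c(p, p + l2_len); p <- p + l2_len
  f$v_region <- c(p, p + nchar(allele$seq)); p <- p + nchar(allele$seq)
  f$heptamer_3 <- c(p, p + 7L); p <- p + 7L
  f$spacer_3 <- c(p, p + config$v_spacer); p <- p + config$v_spacer
  f$nonamer_3 <- c(p, p + 9L)
  list(seq = seq, features = f)
}

build_d_segment <- function(allele, pwms, config) {
  nona5 <- sample_motif(pwms$D5_NONAMER)
  sp5 <- random_nt(config$d5_spacer)
  hept5 <- sample_motif(pwms$D5_HEPTAMER)
  hept3 <- sample_motif(pwms$D3_HEPTAMER)
  sp3 <- random_nt(config$d3_spacer)
  nona3 <- sample_motif(pwms$D3_NONAMER)
  seq <- paste0(nona5, sp5, hept5, allele$seq, hept3, sp3, nona3)
  p <- 0L
  f <- list()
  f$nonamer_5 <- c(0L, 9L); p <- 9L
  f$spacer_5 <- c(p, p + config$d5_spacer); p <- p + config$d5_spacer
  f$heptamer_5 <- c(p, p + 7L); p <- p + 7L
  f$d_region <- c(p, p + nchar(allele$seq)); p <- p + nchar(allele$seq)
  f$heptamer_3 <- c(p, p + 7L); p <- p + 7L
  f$spacer_3 <- c(p, p + config$d3_spacer); p <- p + config$d3_spacer
  f$nonamer_3 <- c(p, p + 9L)
  list(seq = seq, features = f)
}

build_j_segment <- function(allele, pwms, config) {
  nona <- sample_motif(pwms$J_NONAMER)
  sp <- random_nt(config$j_spacer)
  hept <- sample_motif(pwms$J_HEPTAMER)
  jlen <- nchar(allele$seq)
  seq <- paste0(nona, sp, hept, allele$seq, "GT")
  p <- 0L
  f <- list()
  f$nonamer_5 <- c(0L, 9L); p <- 9L
  f$spacer_5 <- c(p, p + config$j_spacer); p <- p + config$j_spacer
  f$heptamer_5 <- c(p, p + 7L); p <- p + 7L
  f$j_region <- c(p, p + jlen)
  f$j_motif <- c(p + jlen - config$j_motif_offset,
                 p + jlen - config$j_motif_offset +
                   nchar(config$j_motif_pattern))
  f$donor_splice <- c(p + jlen, p + jlen + 2L)
  list(seq = seq, features = f)
}

#' Generate a synthetic locus with ground truth
#'
#' Genes are placed in locus order (V cluster, then D, then J, as in a
#' heavy-chain locus) separated by i.i.d. uniform random intergenic
#' sequence.  Each V gene gets an ATG-initiated stop-free leader with
#' enforced GT/AG splice dinucleotides, a V-REGION copied from a random
#' reference allele, and an RSS sampled from the PWMs with the consensus
#' enforced; D genes get RSS on both sides, J genes an RSS plus the J-motif
#' at the configured offset and a trailing GT donor.
#'
#' @param refset A [reference_set()] (e.g. [synthetic_reference_set()]).
#' @param motifs A motif set from [synthetic_motif_set()] or
#'   [read_motif_params()].
#' @param config A [locus_config()]; defaults to `motifs$config`.
#' @param n_v,n_d,n_j Implants per gene type.
#' @param intergenic Either a length-2 range from which intergenic lengths
#'   are drawn uniformly, or a function of one argument returning that many
#'   lengths.
#' @param seed RNG seed; output is reproducible byte-for-byte.
#' @param decoy_heptamers If `TRUE`, each intergenic stretch is salted with
#'   a lone consensus heptamer (no nonamer), stressing false-positive
#'   behaviour.
#' @param name Assembly name.
#' @return List with `assembly` (an [assembly()]) and `truth`, a
#'   `data.frame` of one row per implant: `implant_id`, `gene_type`,
#'   `allele`, `functionality`, `defect`, gene `start`/`end` and
#'   per-feature start/end/seq columns, all 1-based inclusive forward
#'   coordinates as in the annotation report.
#' @export
generate_locus <- function(refset, motifs, config = NULL,
                           n_v = 10L, n_d = 5L, n_j = 5L,
                           intergenic = c(2500L, 7000L), seed = 1L,
                           decoy_heptamers = FALSE,
                           name = sprintf("synthetic_locus_seed%d", seed)) {
  set.seed(seed)
  config <- config %||% motifs$config %||% locus_config()
  pwms <- motifs$pwms
  n_genes <- n_v + n_d + n_j
  if (n_genes == 0L) stop("no genes requested")
  ig_lengths <- if (is.function(intergenic)) intergenic(n_genes + 1L)
  else if (length(intergenic) == 2L)
    sample(intergenic[1L]:intergenic[2L], n_genes + 1L, replace = TRUE)
  else rep_len(intergenic, n_genes + 1L)

  pick <- function(g) {
    alleles <- refset$alleles[refset$alleles$gene_type == g, , drop = FALSE]
    if (nrow(alleles) == 0L) stop("reference set has no ", g, " alleles")
    alleles[sample(nrow(alleles), 1L), ]
  }
  plan <- rep(c("V", "D", "J"), c(n_v, n_d, n_j))
  pieces <- character(0L)
  truth_rows <- list()
  pos <- 0L
  add_intergenic <- function(len) {
    s <- random_nt(len)
    if (decoy_heptamers && len > 20L) {
      at <- sample(len - 7L, 1L)
      substr(s, at, at + 6L) <- "CACAGTG"
    }
    s
  }
  for (gi in seq_len(n_genes)) {
    ig <- add_intergenic(ig_lengths[gi])
    pieces <- c(pieces, ig)
    pos <- pos + nchar(ig)
    g <- plan[gi]
    al <- pick(g)
    seg <- switch(g,
                  V = build_v_segment(al, pwms, config),
                  D = build_d_segment(al, pwms, config),
                  J = build_j_segment(al, pwms, config))
    pieces <- c(pieces, seg$seq)
    row <- list(implant_id = sprintf("implant%03d", gi), gene_type = g,
                allele = al$name, functionality = "Functional",
                defect = "none")
    fstart <- vapply(seg$features, `[`, numeric(1L), 1L)
    fend <- vapply(seg$features, `[`, numeric(1L), 2L)
    row$start <- pos + min(fstart) + 1L
    row$end <- pos + max(fend)
    for (f in .FEATURES) {
      if (f %in% names(seg$features)) {
        iv <- seg$features[[f]]
        row[[paste0(f, "_start")]] <- pos + iv[1L] + 1L
        row[[paste0(f, "_end")]] <- pos + iv[2L]
        row[[paste0(f, "_seq")]] <- substr0(seg$seq, iv[1L], iv[2L])
      } else {
        row[[paste0(f, "_start")]] <- NA_integer_
        row[[paste0(f, "_end")]] <- NA_integer_
        row[[paste0(f, "_seq")]] <- NA_character_
      }
    }
    truth_rows[[gi]] <- as.data.frame(row, stringsAsFactors = FALSE)
    pos <- pos + nchar(seg$seq)
  }
  pieces <- c(pieces, add_intergenic(ig_lengths[n_genes + 1L]))
  list(assembly = assembly(name, paste(pieces, collapse = "")),
       truth = do.call(rbind, truth_rows))
}

# expected classification for each applicable (gene type, defect) pair
.DEFECT_TABLE <- list(
  V = c(rss_heptamer_break = "ORF", rss_nonamer_break = "ORF",
        leader_stop = "ORF", leader_frameshift = "ORF",
        cys104_loss = "ORF", early_stop = "pseudogene",
        post104_stop = "Functional", missing_donor_GT = "ORF"),
  D = c(rss_heptamer_break = "ORF", rss_nonamer_break = "ORF"),
  J = c(rss_heptamer_break = "ORF", rss_nonamer_break = "ORF",
        early_stop = "Functional", j_motif_shift = "ORF",
        splice_loss = "ORF"))

#' The defect menu
#'
#' @return Named list per gene type of applicable defects and the
#'   classification each dictates under the functionality criteria
#'   (including the rule that a stop codon after IMGT position 104 in a V,
#'   or upstream of the J-motif in a J, still permits Functional).
#' @export
defect_menu <- function() .DEFECT_TABLE

#' Engineer a defect into an implanted gene
#'
#' Applies the minimal edit realising the defect (at most 3 substituted nt,
#' or a single-nt deletion for the frameshift defect) and updates the truth
#' record's expected classification.
#'
#' @param locus Result of [generate_locus()].
#' @param implant_id Truth-table implant to damage.
#' @param defect One of the names in [defect_menu()] for the implant's gene
#'   type.
#' @param seed Unused (edits are deterministic); kept for interface
#'   stability.
#' @return The locus with `assembly` edited and `truth` updated.
#' @export
implant_defect <- function(locus, implant_id, defect, seed = NULL) {
  tr <- locus$truth
  i <- match(implant_id, tr$implant_id)
  if (is.na(i)) stop("unknown implant ", implant_id)
  g <- tr$gene_type[i]
  if (!defect %in% names(.DEFECT_TABLE[[g]]))
    stop("defect '", defect, "' is not applicable to gene type ", g)
  seq <- locus$assembly$seq
  # replace the 1-based inclusive range [at, at+nchar(with)-1] with `with`
  sub_at <- function(at, with) {
    substr(seq, at, at + nchar(with) - 1L) <<- with
  }
  codon_at <- function(region_start, codon) region_start + 3L * (codon - 1L)
  switch(defect,
    rss_heptamer_break = {
      if (g == "V") sub_at(tr$heptamer_3_start[i], "CACAGTA")
      else if (g == "D") sub_at(tr$heptamer_3_start[i], "CACAGTA")
      else sub_at(tr$heptamer_5_start[i], "TACTGTG")
    },
    rss_nonamer_break = {
      if (g == "V") sub_at(tr$nonamer_3_start[i], "ACAAAAACT")
      else sub_at(tr$nonamer_5_start[i], "AGTTTTTGT")
    },
    leader_stop = sub_at(tr$l_part1_start[i] + 6L, "TGA"),
    leader_frameshift = {
      at <- tr$l_part2_start[i] + 4L
      seq <- paste0(substr(seq, 1L, at - 1L), substr(seq, at + 1L,
                                                     nchar(seq)))
      shift <- function(x) ifelse(!is.na(x) & x > at, x - 1L, x)
      for (cl in grep("_start$|_end$|^start$|^end$", names(tr)))
        tr[[cl]] <- shift(tr[[cl]])
      locus$truth <- tr
    },
    cys104_loss = sub_at(codon_at(tr$v_region_start[i], 104L), "AGT"),
    early_stop = {
      if (g == "V") sub_at(codon_at(tr$v_region_start[i], 50L), "TAA")
      else sub_at(tr$j_motif_start[i] - 3L, "TAA")
    },
    post104_stop = sub_at(codon_at(tr$v_region_start[i], 106L), "TAA"),
    missing_donor_GT = sub_at(tr$l_part1_end[i] + 1L, "GC"),
    j_motif_shift = sub_at(tr$j_motif_start[i], "C"),
    splice_loss = sub_at(tr$donor_splice_start[i], "GC"))
  locus$assembly$seq <- seq
  locus$assembly$input_length <- nchar(seq)
  tr <- locus$truth
  tr$functionality[i] <- .DEFECT_TABLE[[g]][[defect]]
  tr$defect[i] <- defect
  locus$truth <- tr
  locus
}
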