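# V gene annotation: RSS localisation, leader detection, IMGT mapping and
# classification.

# one clean V locus shared by several tests
v_locus <- generate_locus(test_refset, test_motifs, n_v = 1, n_d = 0,
                          n_j = 0, intergenic = c(300, 400), seed = 30)
v_truth <- v_locus$truth[1, ]
v_cand <- data.frame(gene_type = "V",
                     start = v_truth$v_region_start - 1L,
                     end = v_truth$v_region_end,
                     allele = v_truth$allele, evalue = 0, match_frac = 1,
                     pident = 100, q_start = 0L, q_end = 318L, length = 318L,
                     note = "", stringsAsFactors = FALSE)

test_that("locate_v_rss finds a planted RSS abutting the V-REGION", {
  res <- locate_v_rss(v_locus$assembly, v_cand, test_motifs$pwms,
                      test_motifs$config)
  expect_false(is.null(res$rss))
  expect_equal(res$v_end, v_cand$end)          # heptamer abuts V end
  expect_equal(res$rss$left$position, v_cand$end)
  expect_equal(res$rss$right$position, v_cand$end + 7L + 23L)
  expect_true(res$rss$left$passes_threshold)
  expect_true(res$rss$right$passes_threshold)
})

test_that("locate_v_rss pulls back an overshooting V end to the heptamer", {
  over <- v_cand
  over$end <- over$end + 3L   # match overshoots into the heptamer
  res <- locate_v_rss(v_locus$assembly, over, test_motifs$pwms,
                      test_motifs$config)
  expect_equal(res$v_end, v_cand$end)
  # brute-force check of the chosen placement
  bf <- bf_motif_pair(v_locus$assembly$seq, test_motifs$pwms$V_HEPTAMER,
                      test_motifs$pwms$V_NONAMER, 23, 0,
                      c(over$end - 10, over$end + 40))
  expect_equal(res$rss$left$position, bf$start)
})

test_that("an all-N RSS window is reported as absent with a note", {
  asm <- assembly("n", paste0(substr(v_locus$assembly$seq, 1,
                                     v_cand$end - 10L),
                              strrep("N", 150)))
  res <- locate_v_rss(asm, v_cand, test_motifs$pwms, test_motifs$config)
  expect_null(res$rss)
  expect_equal(res$v_end, v_cand$end)
  expect_match(res$notes, "N")
})

test_that("locate_leader recovers the planted leader, in frame and stop-free", {
  lead <- locate_leader(v_locus$assembly, v_cand, test_motifs$pwms,
                        test_motifs$config)
  expect_equal(lead$l_part1[1], v_truth$l_part1_start - 1L)
  expect_equal(lead$l_part1[2], v_truth$l_part1_end)
  expect_equal(lead$l_part2[1], v_truth$l_part2_start - 1L)
  expect_true(lead$valid)
  expect_true(lead$in_frame_with_v)
  expect_true(lead$stop_free)
  expect_equal(substr(lead$leader_peptide, 1, 1), "M")
  expect_equal(nchar(lead$leader_peptide), 19L)
})

test_that("a stop-free in-frame leader beats a higher-likelihood invalid one", {
  # placement A: consensus L-PART1 with a single-nt TGG->TGA stop
  # (higher PWM likelihood); placement B: a two-variant training combination
  # (valid but lower likelihood).  The valid one must win.
  l1 <- default_motif_training()$L_PART1$seqs
  lA <- l1[1]; substr(lA, 9, 9) <- "A"         # ATG GAC TGA ...
  lB <- l1[1]; substr(lB, 5, 5) <- "T"         # GAC -> GTC (untrained base)
  substr(lB, 10, 10) <- "G"                    # plus a trained variant base
  seq <- paste0("CC", lA, "GT", rnt(40), "CC", lB, "GT", rnt(30), "AG",
                "GTGTCCAGTGT", test_refset$alleles$seq[1], strrep("C", 20))
  v_start <- 2 + 46 + 2 + 40 + 2 + 46 + 2 + 30 + 2 + 11
  cand <- v_cand; cand$start <- v_start; cand$end <- v_start + 318L
  set.seed(31)
  lead <- locate_leader(assembly("two", seq), cand, test_motifs$pwms,
                        test_motifs$config)
  sA <- score_pwm(test_motifs$pwms$L_PART1, lA)$log_likelihood
  sB <- score_pwm(test_motifs$pwms$L_PART1, lB)$log_likelihood
  expect_gt(sA, sB)                     # the invalid one scores higher
  expect_equal(lead$l_part1[1], 2 + 46 + 2 + 40 + 2)
  expect_true(lead$valid)
})

test_that("locate_leader returns NULL without an AG acceptor", {
  seq2 <- v_locus$assembly$seq
  at <- v_truth$l_part2_start - 2L             # the acceptor AG
  substr(seq2, at, at + 1L) <- "CC"
  # remove other chance AGs at the fixed acceptor position upstream
  lead <- locate_leader(assembly("noag", seq2), v_cand, test_motifs$pwms,
                        test_motifs$config)
  expect_null(lead)
})

test_that("IMGT mapping reads conserved cysteines and stop positions", {
  al <- test_refset$alleles[test_refset$alleles$gene_type == "V", ][1, ]
  # identity: both cysteines present, in frame
  chk <- map_to_imgt_positions(al$seq, test_refset, al$name)
  expect_true(chk$in_frame)
  expect_true(chk$cys23_present)
  expect_true(chk$cys104_present)
  expect_false(chk$stop_before_cys104)
  expect_false(chk$any_stop)

  # TGC -> TGA at position 104: cysteine lost, stop counts as before/at 104
  mut <- al$seq
  substr(mut, 310, 312) <- "TGA"
  chk2 <- map_to_imgt_positions(mut, test_refset, al$name)
  expect_false(chk2$cys104_present)
  expect_true(chk2$stop_before_cys104)
  expect_false(chk2$stop_after_cys104)

  # 3-nt in-frame deletion upstream: positions still resolved via alignment
  del <- paste0(substr(al$seq, 1, 27), substr(al$seq, 31, 318))
  chk3 <- map_to_imgt_positions(del, test_refset, al$name)
  expect_true(chk3$in_frame)
  expect_true(chk3$cys23_present)
  expect_true(chk3$cys104_present)

  # single-nt deletion: frameshift detected
  fs <- paste0(substr(al$seq, 1, 99), substr(al$seq, 101, 318))
  chk4 <- map_to_imgt_positions(fs, test_refset, al$name)
  expect_false(chk4$in_frame)
})

test_that("IMGT gap patterns transfer through the alignment", {
  # reference with two gap codons after codon 10: ungapped codon 102 sits at
  # IMGT position 104
  base <- test_refset$alleles[test_refset$alleles$gene_type == "V", ][2, ]
  ungapped <- substr(base$seq, 1, 306)         # 102 codons
  substr(ungapped, 304, 306) <- "TGC"          # Cys at ungapped codon 102
  gapped <- paste0(substr(ungapped, 1, 30), strrep(".", 6),
                   substr(ungapped, 31, 306))
  rs <- reference_set("IGHVG-1*01", "V", ungapped, gapped)
  chk <- map_to_imgt_positions(ungapped, rs, "IGHVG-1*01")
  expect_true(chk$cys104_present)
  expect_true(chk$in_frame)

  # without a gapped reference the ungapped fallback is used, with a note
  rs2 <- reference_set("IGHVU-1*01", "V", ungapped)
  chk2 <- map_to_imgt_positions(ungapped, rs2, "IGHVU-1*01")
  expect_match(paste(chk2$notes, collapse = " "), "ungapped")
  expect_false(chk2$cys104_present)   # Cys sits at 102 without the gaps
})

make_vcheck <- function(in_frame = TRUE, cys23 = TRUE, cys104 = TRUE,
                        stop_before = FALSE, stop_after = FALSE) {
  list(in_frame = in_frame, cys23_present = cys23, cys104_present = cys104,
       stop_before_cys104 = stop_before, stop_after_cys104 = stop_after,
       any_stop = stop_before || stop_after, gapped_alignment_used = "x",
       notes = character(0))
}
make_rss <- function(pass = TRUE, consensus = TRUE) {
  hit <- list(position = 0L, log_likelihood = -1,
              passes_threshold = pass, matches_consensus = consensus,
              sequence = "CACAGTG")
  list(left = hit, right = hit, spacer_used = 23,
       joint_log_likelihood = -2, spacer_seq = "")
}
make_leader <- function(valid = TRUE, pass = TRUE) {
  hit <- list(position = 0L, log_likelihood = -1, passes_threshold = pass,
              matches_consensus = NA, sequence = "A")
  list(l_part1 = c(0, 46), l_part2 = c(100, 111), intron = c(46, 100),
       l_part1_hit = hit, l_part2_hit = hit, donor_present = TRUE,
       acceptor_present = TRUE, leader_peptide = "M", in_frame_with_v = valid,
       stop_free = valid, starts_with_atg = valid, valid = valid,
       joint_log_likelihood = -2)
}

test_that("classify_v applies the functionality criteria", {
  expect_equal(classify_v(make_leader(), make_rss(), make_vcheck())$functionality,
               "Functional")
  # RSS below threshold, stop-free V: ORF
  expect_equal(classify_v(make_leader(), make_rss(pass = FALSE),
                          make_vcheck())$functionality, "ORF")
  # consensus violation alone: ORF
  expect_equal(classify_v(make_leader(), make_rss(consensus = FALSE),
                          make_vcheck())$functionality, "ORF")
  # stop before the second cysteine: pseudogene
  expect_equal(classify_v(make_leader(), make_rss(),
                          make_vcheck(stop_before = TRUE))$functionality,
               "pseudogene")
  # stop strictly after position 104: Functional with a note
  res <- classify_v(make_leader(), make_rss(), make_vcheck(stop_after = TRUE))
  expect_equal(res$functionality, "Functional")
  expect_match(paste(res$notes, collapse = " "), "104")
  # missing leader, stop-free V: ORF
  expect_equal(classify_v(NULL, make_rss(), make_vcheck())$functionality,
               "ORF")
})

test_that("classify_v is monotone in its checks", {
  rank <- c(pseudogene = 1, ORF = 2, Functional = 3)
  grid <- expand.grid(rss_pass = c(FALSE, TRUE), rss_cons = c(FALSE, TRUE),
                      leader_valid = c(FALSE, TRUE),
                      cys104 = c(FALSE, TRUE), stop_before = c(TRUE, FALSE))
  call_cls <- function(g) {
    classify_v(make_leader(valid = g$leader_valid),
               make_rss(pass = g$rss_pass, consensus = g$rss_cons),
               make_vcheck(cys104 = g$cys104,
                           stop_before = g$stop_before))$functionality
  }
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    base <- rank[call_cls(g)]
    for (col in names(grid)) {
      better <- if (col == "stop_before") FALSE else TRUE
      if (identical(g[[col]], better)) next
      g2 <- g; g2[[col]] <- better
      expect_gte(rank[call_cls(g2)], base,
                 label = paste("flipping", col, "at row", r))
    }
  }
})
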