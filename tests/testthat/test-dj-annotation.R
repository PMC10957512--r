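# D and J gene annotation: RSS pairs, the J-motif and donor splice, and
# functionality classification.

d_locus <- generate_locus(test_refset, test_motifs, n_v = 0, n_d = 2,
                          n_j = 0, intergenic = c(200, 300), seed = 40)
d_truth <- d_locus$truth[1, ]
d_cand <- data.frame(gene_type = "D",
                     start = d_truth$d_region_start - 1L,
                     end = d_truth$d_region_end,
                     allele = d_truth$allele, evalue = 0, match_frac = 1,
                     pident = 100, q_start = 0L,
                     q_end = d_truth$d_region_end - d_truth$d_region_start + 1L,
                     length = 10L, note = "", stringsAsFactors = FALSE)

test_that("locate_d_rss_pair recovers both planted RSS exactly", {
  dc <- locate_d_rss_pair(d_locus$assembly, d_cand, test_motifs$pwms,
                          test_motifs$config)
  expect_false(is.null(dc))
  expect_equal(dc$d_region[1], d_cand$start)
  expect_equal(dc$d_region[2], d_cand$end)
  expect_equal(dc$rss5$left$position, d_truth$nonamer_5_start - 1L)
  expect_equal(dc$rss3$right$position, d_truth$nonamer_3_start - 1L)
  # 5' heptamer abuts the D-REGION start; 3' heptamer its end
  expect_equal(dc$rss5$right$position + 7L, dc$d_region[1])
  expect_equal(dc$rss3$left$position, dc$d_region[2])
})

test_that("an 8-nt D-REGION flanked by intact RSS is recovered", {
  short_ref <- reference_set("IGHD7-1*01", "D",
                             test_refset$alleles$seq[
                               test_refset$alleles$gene_type == "D"][1])
  expect_equal(nchar(short_ref$alleles$seq), 8L)
  loc <- generate_locus(short_ref, test_motifs, n_v = 0, n_d = 1, n_j = 0,
                        intergenic = c(150, 250), seed = 41)
  ann <- annotate_assembly(loc$assembly, short_ref, test_motifs,
                           gene_types = "D")
  expect_length(ann, 1L)
  expect_equal(ann[[1]]$functionality, "Functional")
  expect_equal(ann[[1]]$features$d_region$start,
               loc$truth$d_region_start - 1L)
  expect_equal(nchar(ann[[1]]$features$d_region$seq), 8L)
})

test_that("a candidate with no room for the upstream RSS footprint is dropped", {
  edge <- d_cand
  edge$start <- 5L   # too close to the assembly edge for nonamer+spacer+heptamer
  edge$end <- edge$start + 12L
  expect_null(locate_d_rss_pair(d_locus$assembly, edge, test_motifs$pwms,
                                test_motifs$config))
})

test_that("classify_d requires thresholds to retain, consensus for Functional", {
  dc <- locate_d_rss_pair(d_locus$assembly, d_cand, test_motifs$pwms,
                          test_motifs$config)
  expect_equal(classify_d(dc)$functionality, "Functional")

  # one heptamer violating the consensus (but passing threshold): ORF
  dc_orf <- dc
  dc_orf$rss3$left$matches_consensus <- FALSE
  cls <- classify_d(dc_orf)
  expect_true(cls$retained)
  expect_equal(cls$functionality, "ORF")

  # any motif below threshold: candidate dropped
  dc_drop <- dc
  dc_drop$rss5$left$passes_threshold <- FALSE
  expect_false(classify_d(dc_drop)$retained)

  # no consensus defined: thresholds alone give Functional
  dc_nc <- dc
  for (f in c("rss5", "rss3"))
    for (s in c("left", "right")) dc_nc[[f]][[s]]$matches_consensus <- NA
  expect_equal(classify_d(dc_nc)$functionality, "Functional")
})

j_locus <- generate_locus(test_refset, test_motifs, n_v = 0, n_d = 0,
                          n_j = 2, intergenic = c(200, 300), seed = 42)
j_truth <- j_locus$truth[1, ]
j_cand <- data.frame(gene_type = "J",
                     start = j_truth$j_region_start - 1L,
                     end = j_truth$j_region_end,
                     allele = j_truth$allele, evalue = 0, match_frac = 1,
                     pident = 100, q_start = 0L, q_end = 52L, length = 52L,
                     note = "", stringsAsFactors = FALSE)

test_that("locate_j_rss finds the planted RSS and applies the retention rule", {
  jr <- locate_j_rss(j_locus$assembly, j_cand, test_motifs$pwms,
                     test_motifs$config)
  expect_false(is.null(jr))
  expect_equal(jr$j_start, j_cand$start)
  expect_true(jr$rss$left$passes_threshold)
  expect_true(jr$rss$right$passes_threshold)

  # heptamer degraded below threshold, nonamer intact: retained
  seq1 <- j_locus$assembly$seq
  substr(seq1, j_truth$heptamer_5_start, j_truth$heptamer_5_end) <- "TTTTTTT"
  jr1 <- locate_j_rss(assembly("h", seq1), j_cand, test_motifs$pwms,
                      test_motifs$config)
  expect_false(is.null(jr1))

  # both degraded: dropped
  substr(seq1, j_truth$nonamer_5_start, j_truth$nonamer_5_end) <- "CCCCCCCCC"
  jr2 <- locate_j_rss(assembly("hn", seq1), j_cand, test_motifs$pwms,
                      test_motifs$config)
  expect_null(jr2)
})

test_that("locate_j_motif_and_splice finds the planted motif and GT donor", {
  ms <- locate_j_motif_and_splice(j_locus$assembly,
                                  c(j_cand$start, j_cand$end),
                                  test_motifs$config)
  expect_equal(ms$j_motif[1], j_truth$j_motif_start - 1L)
  expect_equal(ms$donor_splice, j_truth$donor_splice_start - 1L)

  # donor GT mutated to GC: splice absent
  seq1 <- j_locus$assembly$seq
  substr(seq1, j_truth$donor_splice_start, j_truth$donor_splice_start + 1L) <-
    "GC"
  ms1 <- locate_j_motif_and_splice(assembly("gc", seq1),
                                   c(j_cand$start, j_cand$end),
                                   test_motifs$config)
  expect_null(ms1$donor_splice)
  expect_match(paste(ms1$notes, collapse = " "), "donor")
})

test_that("the J-motif scan agrees with an exhaustive pattern scan", {
  cfg <- test_motifs$config
  set.seed(43)
  for (i in 1:200) {
    jlen <- sample(40:60, 1)
    seq <- rnt(jlen + 20)
    js <- 5L; je <- js + jlen
    ms <- locate_j_motif_and_splice(assembly("f", seq), c(js, je), cfg)
    # oracle: frame-preserving offsets within the tolerance, nearest first
    found <- NULL
    for (sh in c(0L, -3L, 3L)) {
      p <- je - cfg$j_motif_offset + sh
      if (p < js || p + 6L > je) next
      if (bf_matches(substr(seq, p + 1, p + 6), cfg$j_motif_pattern)) {
        found <- p; break
      }
    }
    if (is.null(found)) expect_null(ms$j_motif)
    else expect_equal(ms$j_motif[1], found)
    expect_equal(is.null(ms$donor_splice),
                 substr(seq, je + 1, je + 2) != "GT")
  }
})

test_that("a motif shifted beyond the tolerance is not found", {
  # rebuild the J-REGION with the motif moved 5 nt downstream
  al_seq <- test_refset$alleles$seq[test_refset$alleles$name ==
                                      j_truth$allele]
  shifted <- al_seq
  substr(shifted, 19, 24) <- "CATCAG"              # erase planted motif
  substr(shifted, 24, 29) <- "TGGGGG"              # +5 nt, out of frame
  seq1 <- j_locus$assembly$seq
  substr(seq1, j_truth$j_region_start, j_truth$j_region_end) <- shifted
  ms <- locate_j_motif_and_splice(assembly("sh", seq1),
                                  c(j_cand$start, j_cand$end),
                                  test_motifs$config)
  expect_null(ms$j_motif)
})

test_that("classify_j applies the functionality criteria", {
  jr <- locate_j_rss(j_locus$assembly, j_cand, test_motifs$pwms,
                     test_motifs$config)
  ms <- locate_j_motif_and_splice(j_locus$assembly,
                                  c(j_cand$start, j_cand$end),
                                  test_motifs$config)
  jcall <- list(rss = jr$rss, j_region = c(j_cand$start, j_cand$end),
                j_motif = ms$j_motif, donor_splice = ms$donor_splice,
                seq = j_locus$assembly$seq,
                expected_motif_offset = test_motifs$config$j_motif_offset)
  expect_equal(classify_j(jcall)$functionality, "Functional")

  # J-motif absent, no stops downstream: ORF
  jc1 <- jcall; jc1$j_motif <- NULL
  expect_equal(classify_j(jc1)$functionality, "ORF")

  # donor absent: ORF
  jc2 <- jcall; jc2$donor_splice <- NULL
  expect_equal(classify_j(jc2)$functionality, "ORF")

  # stop codon in frame upstream of the motif: Functional with a note
  seq1 <- j_locus$assembly$seq
  substr(seq1, j_truth$j_motif_start - 3L, j_truth$j_motif_start - 1L) <- "TAA"
  jc3 <- jcall; jc3$seq <- seq1
  res <- classify_j(jc3)
  expect_equal(res$functionality, "Functional")
  expect_match(paste(res$notes, collapse = " "), "upstream")

  # stop codon in frame downstream of the motif: pseudogene
  seq2 <- j_locus$assembly$seq
  substr(seq2, j_truth$j_motif_start + 6L, j_truth$j_motif_start + 8L) <- "TAA"
  jc4 <- jcall; jc4$seq <- seq2
  expect_equal(classify_j(jc4)$functionality, "pseudogene")
})

test_that("emitted D and J annotations keep heptamers abutting the region", {
  loc <- generate_locus(test_refset, test_motifs, n_v = 0, n_d = 3, n_j = 3,
                        intergenic = c(200, 500), seed = 44)
  ann <- annotate_assembly(loc$assembly, test_refset, test_motifs)
  expect_gte(length(ann), 6L)
  for (a in ann) {
    f <- a$features
    if (a$gene_type == "D") {
      expect_equal(f$heptamer_5$end, f$d_region$start)
      expect_equal(f$d_region$end, f$heptamer_3$start)
    } else if (a$gene_type == "J") {
      expect_equal(f$heptamer_5$end, f$j_region$start)
    }
  }
})
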