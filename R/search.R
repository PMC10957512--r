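# Candidate discovery by similarity to reference alleles.
#
# Two interchangeable backends produce RawHit tables:
#   * "external": makeblastdb/blastn (BLAST+), parsed from tabular outfmt 6;
#   * "internal": a k-mer seed-and-extend aligner using the same word sizes
#     and penalties, with a Karlin-Altschul-style e-value surrogate.  Only
#     the ordering of e-values matters downstream; surrogate values are
#     approximate.
# Hits are then consolidated (one best candidate per overlapping location)
# and extended to full allele length.

#' Default per-gene-type search parameters
#'
#' V searches use word size 11 with gap open 5, gap extend 5 and mismatch
#' penalty -1; D and J searches reduce the word size to 7 for the shorter
#' sequences, and D raises the e-value cutoff from 10 to 100 to widen the
#' search.
#'
#' @return Named list (`V`, `D`, `J`) of parameter lists with fields
#'   `word_size`, `gap_open`, `gap_extend`, `penalty`, `evalue`.
#' @export
default_search_params <- function() {
  base <- list(word_size = 11L, gap_open = 5L, gap_extend = 5L,
               penalty = -1L, reward = 1L, evalue = 10)
  d <- base; d$word_size <- 7L; d$evalue <- 100
  j <- base; j$word_size <- 7L
  list(V = base, D = d, J = j)
}

# Karlin-Altschul surrogate constants for the +1/-1 scoring pair
# (ungapped lambda solves 0.25*e^lambda + 0.75*e^-lambda = 1 => lambda = ln 3)
.KA_LAMBDA <- log(3)
.KA_K <- 0.33

surrogate_evalue <- function(score, m, n) {
  .KA_K * as.numeric(m) * as.numeric(n) * exp(-.KA_LAMBDA * score)
}

#' Search an assembly for matches to reference alleles
#'
#' Hits are reported on the working sense only; reverse-sense genes are
#' found by rerunning the pipeline on the reverse complement (see
#' [annotate_assembly()]).
#'
#' @param assembly An [assembly()] object (working sense).
#' @param refset A [reference_set()].
#' @param params Per-gene-type parameters, see [default_search_params()].
#' @param backend `"internal"` (pure R seed-and-extend) or `"external"`
#'   (BLAST+ `blastn`, which must be on the PATH).
#' @param gene_types Gene types to search.
#' @return `data.frame` of raw hits with columns `allele`, `gene_type`,
#'   `a_start`, `a_end` (assembly interval, 0-based half-open, working
#'   sense), `q_start`, `q_end` (allele interval), `pident`, `length`
#'   (aligned length), `evalue`.  Zero rows when nothing is found.
#' @export
run_similarity_search <- function(assembly, refset,
                                  params = default_search_params(),
                                  backend = c("internal", "external"),
                                  gene_types = c("V", "D", "J")) {
  backend <- match.arg(backend)
  gene_types <- intersect(gene_types, unique(refset$alleles$gene_type))
  if (length(gene_types) == 0L) return(empty_hits())
  for (g in gene_types)
    if (!any(refset$alleles$gene_type == g))
      stop("reference set has no alleles of type ", g)
  hits <- switch(backend,
                 internal = internal_search(assembly, refset, params,
                                            gene_types),
                 external = external_search(assembly, refset, params,
                                            gene_types))
  hits[order(hits$gene_type, hits$a_start, hits$a_end, hits$allele), ,
       drop = FALSE]
}

empty_hits <- function() {
  data.frame(allele = character(0L), gene_type = character(0L),
             a_start = integer(0L), a_end = integer(0L),
             q_start = integer(0L), q_end = integer(0L),
             pident = numeric(0L), length = integer(0L),
             evalue = numeric(0L), stringsAsFactors = FALSE)
}

# --- internal backend ------------------------------------------------------

internal_search <- function(assembly, refset, params, gene_types) {
  seq <- assembly$seq
  n <- nchar(seq)
  out <- list()
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  asm_tabs <- list()   # k-mer tables cached per word size
  for (g in gene_types) {
    p <- params[[g]]
    k <- p$word_size
    if (n < k) next
    kc <- as.character(k)
    if (is.null(asm_tabs[[kc]])) {
      starts <- seq_len(n - k + 1L)
      tab <- data.table::data.table(kmer = substring(seq, starts,
                                                     starts + k - 1L),
                                    apos = starts - 1L)
      data.table::setkey(tab, kmer)
      asm_tabs[[kc]] <- tab
    }
    asm_dt <- asm_tabs[[kc]]
    alleles <- refset$alleles[refset$alleles$gene_type == g, , drop = FALSE]
    for (i in seq_len(nrow(alleles))) {
      al <- alleles[i, ]
      qlen <- nchar(al$seq)
      if (qlen < k) next
      qstarts <- seq_len(qlen - k + 1L)
      q_dt <- data.table::data.table(kmer = substring(al$seq, qstarts,
                                                      qstarts + k - 1L),
                                     qpos = qstarts - 1L)
      seeds <- asm_dt[q_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(seeds) == 0L) next
      out[[length(out) + 1L]] <-
        align_seed_clusters(seeds, al, seq, n, p, submat, g)
    }
  }
  if (length(out) == 0L) return(empty_hits())
  do.call(rbind, out)
}

# group seeds into diagonal bands and align each band's assembly window
# against the allele in one vectorised pairwiseAlignment call
align_seed_clusters <- function(seeds, al, seq, n, p, submat, gene_type) {
  qlen <- nchar(al$seq)
  seeds[, diag := apos - qpos]
  data.table::setorder(seeds, diag, apos)
  band <- 15L
  grp <- cumsum(c(TRUE, diff(seeds$diag) > band |
                          diff(seeds$apos) > qlen + band))
  w_lo <- integer(0L); w_hi <- integer(0L)
  for (gidx in unique(grp)) {
    s <- seeds[grp == gidx]
    lo <- max(0L, min(s$apos - s$qpos) - band)
    hi <- min(n, max(s$apos + (qlen - s$qpos)) + band)
    if (hi - lo < p$word_size) next
    w_lo <- c(w_lo, lo); w_hi <- c(w_hi, hi)
  }
  if (length(w_lo) == 0L) return(empty_hits())
  dup <- duplicated(paste(w_lo, w_hi))
  w_lo <- w_lo[!dup]; w_hi <- w_hi[!dup]
  wins <- Biostrings::DNAStringSet(substring(seq, w_lo + 1L, w_hi))
  aln <- Biostrings::pairwiseAlignment(wins, Biostrings::DNAString(al$seq),
                                       type = "local",
                                       substitutionMatrix = submat,
                                       gapOpening = p$gap_open,
                                       gapExtension = p$gap_extend)
  sc <- Biostrings::score(aln)
  ev <- surrogate_evalue(sc, qlen, n)
  keep <- ev <= p$evalue
  if (!any(keep)) return(empty_hits())
  prng <- aln@pattern@range[keep]   # within-window coordinates
  srng <- aln@subject@range[keep]   # allele coordinates
  nmat <- Biostrings::nmatch(aln)[keep]
  nmis <- Biostrings::nmismatch(aln)[keep]
  # alignment length: longer of the two aligned spans (equals the gapped
  # alignment length unless both sequences gap at the same columns)
  alen <- pmax(BiocGenerics::width(prng), BiocGenerics::width(srng))
  hits <- data.frame(
    allele = al$name, gene_type = gene_type,
    a_start = w_lo[keep] + BiocGenerics::start(prng) - 1L,
    a_end = w_lo[keep] + BiocGenerics::end(prng),
    q_start = BiocGenerics::start(srng) - 1L,
    q_end = BiocGenerics::end(srng),
    pident = 100 * nmat / (nmat + nmis),
    length = alen, evalue = ev[keep], stringsAsFactors = FALSE)
  unique(hits)
}

# --- external backend ------------------------------------------------------

external_search <- function(assembly, refset, params, gene_types) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("BLAST+ (blastn/makeblastdb) not found on PATH; ",
         "use backend = \"internal\" instead")
  td <- tempfile("vdjblast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "assembly.fasta")
  write_assembly_fasta(assembly, qf)
  out <- list()
  for (g in gene_types) {
    p <- params[[g]]
    alleles <- refset$alleles[refset$alleles$gene_type == g, , drop = FALSE]
    db <- file.path(td, paste0("ref_", g, ".fasta"))
    writeLines(paste0(">", alleles$name, "\n", alleles$seq), db)
    system2("makeblastdb", c("-in", db, "-dbtype", "nucl"),
            stdout = FALSE, stderr = FALSE)
    tab <- file.path(td, paste0("hits_", g, ".tsv"))
    status <- system2("blastn",
            c("-query", qf, "-db", db, "-task", "blastn",
              "-word_size", p$word_size, "-gapopen", p$gap_open,
              "-gapextend", p$gap_extend, "-penalty", p$penalty,
              "-reward", p$reward, "-evalue", p$evalue,
              "-outfmt", "6", "-out", tab),
            stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("blastn failed for gene type ", g)
    hits <- parse_blast_tabular(tab)
    if (nrow(hits) == 0L) next
    # query is the assembly, subject the allele; keep plus-strand hits only
    plus <- hits$sstart <= hits$send
    hits <- hits[plus, , drop = FALSE]
    if (nrow(hits) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      allele = hits$subject, gene_type = g,
      a_start = hits$qstart - 1L, a_end = hits$qend,
      q_start = hits$sstart - 1L, q_end = hits$send,
      pident = hits$pident, length = hits$length, evalue = hits$evalue,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_hits())
  do.call(rbind, out)
}

#' Parse BLAST tabular (outfmt 6) output
#'
#' @param path File of tab-separated BLAST hits with the standard 12
#'   columns (query, subject, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore).
#' @return `data.frame` with those columns; zero rows for an empty file.
#' @export
parse_blast_tabular <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!file.exists(path) || file.size(path) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0L)), 12L), cols))
    return(df)
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 BLAST tabular columns in ", path)
  df <- df[, 1:12]
  names(df) <- cols
  df
}

# --- consolidation and extension -------------------------------------------

#' Consolidate raw hits into one best candidate per location
#'
#' Hits of the same gene type whose assembly intervals overlap (transitively)
#' are grouped; within a group the winner maximises the ordered key
#' (match fraction rounded to 2 decimals, then lower e-value, then longer
#' aligned length, then allele name), preferring matches that cover more of
#' their allele.
#'
#' @param hits Raw hit table from [run_similarity_search()].
#' @param refset The [reference_set()] searched (for allele lengths).
#' @return Candidate `data.frame`: `gene_type`, `start`, `end` (assembly
#'   interval of the winning hit), `allele`, `evalue`, `match_frac`,
#'   `pident`, `q_start`, `q_end`, `length`.
#' @export
consolidate_hits <- function(hits, refset) {
  if (nrow(hits) == 0L) return(empty_candidates())
  allele_len <- nchar(refset$alleles$seq)[match(hits$allele,
                                                refset$alleles$name)]
  hits$match_frac <- (hits$q_end - hits$q_start) / allele_len
  out <- list()
  for (g in unique(hits$gene_type)) {
    h <- hits[hits$gene_type == g, , drop = FALSE]
    h <- h[order(h$a_start, h$a_end), , drop = FALSE]
    # transitive overlap grouping by running maximum end
    grp <- cumsum(c(TRUE, h$a_start[-1L] >= cummax(h$a_end)[-nrow(h)]))
    for (gi in unique(grp)) {
      sub <- h[grp == gi, , drop = FALSE]
      i <- order(-round(sub$match_frac, 2L), sub$evalue, -sub$length,
                 sub$allele)[1L]
      out[[length(out) + 1L]] <- sub[i, , drop = FALSE]
    }
  }
  cand <- do.call(rbind, out)
  data.frame(gene_type = cand$gene_type, start = cand$a_start,
             end = cand$a_end, allele = cand$allele, evalue = cand$evalue,
             match_frac = cand$match_frac, pident = cand$pident,
             q_start = cand$q_start, q_end = cand$q_end,
             length = cand$length, note = "", stringsAsFactors = FALSE)
}

empty_candidates <- function() {
  data.frame(gene_type = character(0L), start = integer(0L),
             end = integer(0L), allele = character(0L), evalue = numeric(0L),
             match_frac = numeric(0L), pident = numeric(0L),
             q_start = integer(0L), q_end = integer(0L),
             length = integer(0L), note = character(0L),
             stringsAsFactors = FALSE)
}

#' Extend a candidate to full allele length
#'
#' Grows the assembly interval on both ends by the unmatched allele prefix
#' and suffix (ungapped extension), clamping at assembly edges with a
#' truncation note.
#'
#' @param cand One-row candidate `data.frame` from [consolidate_hits()].
#' @param assembly The searched [assembly()].
#' @param refset The [reference_set()].
#' @return The candidate row with `start`, `end`, `q_start`, `q_end`
#'   updated (and `note` set when truncated).
#' @export
extend_candidate <- function(cand, assembly, refset) {
  al <- ref_allele(refset, cand$allele)
  qlen <- nchar(al$seq)
  new_start <- cand$start - cand$q_start
  new_end <- cand$end + (qlen - cand$q_end)
  notes <- character(0L)
  if (new_start < 0L) {
    new_start <- 0L
    notes <- c(notes, "5' truncated")
  }
  if (new_end > nchar(assembly$seq)) {
    new_end <- nchar(assembly$seq)
    notes <- c(notes, "3' truncated")
  }
  cand$start <- new_start
  cand$end <- new_end
  cand$q_start <- 0L
  cand$q_end <- qlen
  cand$note <- paste(notes, collapse = "; ")
  cand
}

extend_candidates <- function(cands, assembly, refset) {
  if (nrow(cands) == 0L) return(cands)
  out <- lapply(seq_len(nrow(cands)), function(i)
    extend_candidate(cands[i, , drop = FALSE], assembly, refset))
  do.call(rbind, out)
}
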