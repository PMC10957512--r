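# Orchestration: full annotation of an assembly (optionally both senses),
# overlap resolution across gene types, and report emission.

# Build one gene annotation record.  Feature coordinates are 0-based
# half-open on the working sense; the input-coordinate span is precomputed
# so that overlap resolution can merge senses.
new_annotation <- function(assembly, gene_type, features, candidate,
                           functionality, joint_log_likelihood, notes) {
  starts <- vapply(features, `[[`, numeric(1L), "start")
  ends <- vapply(features, `[[`, numeric(1L), "end")
  span <- work_to_input(min(starts), max(ends), assembly$sense,
                        assembly$input_length)
  if (any(vapply(features, function(f) grepl("N", f$seq, fixed = TRUE),
                 logical(1L))))
    notes <- c(notes, "feature window contains N")
  structure(list(gene_type = gene_type,
                 sense = assembly$sense,
                 input_length = assembly$input_length,
                 features = features,
                 closest_reference = candidate$allele,
                 percent_identity = candidate$pident,
                 functionality = functionality,
                 joint_log_likelihood = joint_log_likelihood,
                 input_start = span[1L], input_end = span[2L],
                 notes = notes),
            class = "vdj_annotation")
}

#' @export
print.vdj_annotation <- function(x, ...) {
  cat(sprintf("%s gene [%d-%d]%s %s (closest %s, %.1f%% id)\n",
              x$gene_type, x$input_start, x$input_end,
              if (x$sense == "reverse") " (-)" else "", x$functionality,
              x$closest_reference, x$percent_identity))
  invisible(x)
}

#' Resolve overlapping annotations
#'
#' Every Functional annotation is retained, with a note when Functional
#' annotations overlap each other.  Non-functional annotations overlapping a
#' Functional one are discarded.  Mutually overlapping non-functional
#' annotations are resolved greedily by joint motif log-likelihood (ties:
#' longer span, then leftmost, then closest-reference name): a
#' non-functional annotation survives only if it overlaps no
#' already-retained annotation, so within any set of mutually overlapping
#' non-functionals only the highest-likelihood one remains, while disjoint
#' annotations that merely share a low-scoring neighbour are both kept.
#' Overlap is assessed on input-sequence coordinates, across gene types and
#' senses.
#'
#' @param annotations List of gene annotations from one assembly.
#' @return Filtered list, ordered by input start coordinate.
#' @export
resolve_overlaps <- function(annotations) {
  if (length(annotations) <= 1L) return(annotations)
  st <- vapply(annotations, `[[`, numeric(1L), "input_start")
  en <- vapply(annotations, `[[`, numeric(1L), "input_end")
  n <- length(annotations)
  fun <- vapply(annotations, `[[`, "", "functionality") == "Functional"
  keep <- fun
  ll <- vapply(annotations, `[[`, numeric(1L), "joint_log_likelihood")
  nm <- vapply(annotations, `[[`, "", "closest_reference")
  nf <- which(!fun)
  nf <- nf[order(-ll[nf], -(en[nf] - st[nf]), st[nf], nm[nf])]
  for (i in nf) {
    others <- which(keep)
    keep[i] <- !any(st[i] <= en[others] & st[others] <= en[i])
  }
  o <- order(st[keep], en[keep])
  out <- annotations[keep][o]
  st <- st[keep][o]; en <- en[keep][o]
  # annotate mutual functional overlaps
  for (i in seq_along(out)) {
    if (out[[i]]$functionality != "Functional") next
    others <- setdiff(seq_along(out), i)
    others <- others[vapply(out[others], `[[`, "", "functionality") ==
                       "Functional"]
    ov <- others[iv_overlaps(st[i], en[i] + 1L, st[others], en[others] + 1L)]
    if (length(ov))
      out[[i]]$notes <- unique(c(out[[i]]$notes,
                                 "overlaps another functional gene"))
  }
  out
}

#' Annotate an assembly
#'
#' Runs the full directed-annotation pipeline: similarity search against the
#' reference set, consolidation of overlapping hits into one candidate per
#' location, extension to full allele length, per-gene-type feature
#' annotation (RSS, leader, J-motif, splice sites) and functionality
#' classification, optionally on both senses, followed by overlap
#' resolution on input coordinates.
#'
#' @param assembly An [assembly()] (forward sense) or FASTA path (first
#'   record).
#' @param refset A [reference_set()].
#' @param motifs List with `pwms` and optionally `config`, as returned by
#'   [read_motif_params()] or [synthetic_motif_set()].
#' @param config A [locus_config()]; defaults to `motifs$config` when
#'   present.
#' @param gene_types Subset of `c("V", "D", "J")` to annotate.
#' @param senses `"forward"`, or `c("forward", "reverse")` to also annotate
#'   genes on the reverse strand (the pipeline is rerun on the reverse
#'   complement; hits are never mixed across senses).
#' @param params Search parameters, see [default_search_params()].
#' @param backend `"internal"` or `"external"` (BLAST+).
#' @return List of gene annotations (class `vdj_annotation`), overlap
#'   resolved, ordered by input coordinate.
#' @export
annotate_assembly <- function(assembly, refset, motifs,
                              config = NULL,
                              gene_types = c("V", "D", "J"),
                              senses = "forward",
                              params = default_search_params(),
                              backend = c("internal", "external")) {
  backend <- match.arg(backend)
  if (is.character(assembly)) assembly <- read_assembly(assembly)[[1L]]
  stopifnot(inherits(assembly, "vdj_assembly"),
            length(senses) >= 1L, all(senses %in% c("forward", "reverse")),
            length(gene_types) >= 1L)
  config <- config %||% motifs$config %||% locus_config()
  pwms <- motifs$pwms %||% motifs
  annotations <- list()
  for (sense in senses) {
    work <- if (sense == "forward") assembly else reverse_assembly(assembly)
    hits <- run_similarity_search(work, refset, params, backend, gene_types)
    cands <- consolidate_hits(hits, refset)
    cands <- extend_candidates(cands, work, refset)
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, , drop = FALSE]
      ann <- switch(cand$gene_type,
                    V = annotate_v_candidate(work, cand, pwms, config, refset),
                    D = annotate_d_candidate(work, cand, pwms, config),
                    J = annotate_j_candidate(work, cand, pwms, config))
      if (!is.null(ann)) annotations[[length(annotations) + 1L]] <- ann
    }
  }
  resolve_overlaps(annotations)
}
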