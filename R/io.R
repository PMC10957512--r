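# Input/output: FASTA assemblies and reference sets, motif parameter
# directories, and the CSV / GFF3 annotation reports.

#' Construct an assembly object
#'
#' @param name Record name.
#' @param seq Nucleotide string (A/C/G/T/N after normalisation).
#' @param sense `"forward"`, or `"reverse"` when `seq` is the reverse
#'   complement of the input record.
#' @return Object of class `vdj_assembly` with fields `name`, `seq`,
#'   `sense`, `input_length`.
#' @export
assembly <- function(name, seq, sense = "forward") {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("assembly '", name, "' has an empty sequence")
  if (grepl("[^ACGTN]", seq))
    stop("assembly '", name, "' contains non-nucleotide characters")
  stopifnot(sense %in% c("forward", "reverse"))
  structure(list(name = name, seq = seq, sense = sense,
                 input_length = nchar(seq)),
            class = "vdj_assembly")
}

#' @export
print.vdj_assembly <- function(x, ...) {
  cat(sprintf("Assembly %s: %d nt, %s sense\n", x$name, nchar(x$seq), x$sense))
  invisible(x)
}

#' Reverse-complement an assembly
#'
#' Flips the working sense; applying it twice restores the original.
#' @param a A [assembly()] object.
#' @return The assembly with `seq` reverse-complemented and `sense` toggled.
#' @export
reverse_assembly <- function(a) {
  a$seq <- rc(a$seq)
  a$sense <- if (a$sense == "forward") "reverse" else "forward"
  a
}

#' Read genomic assemblies from a FASTA file
#'
#' Sequences are uppercased, U is mapped to T, and IUPAC ambiguity codes
#' other than N are mapped to N (they carry no information the annotator
#' uses).  Characters outside the IUPAC nucleotide set are an error.
#'
#' @param path FASTA file.
#' @return List of [assembly()] objects in file order, all forward sense.
#' @export
read_assembly <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(recs))
  lapply(seq_along(recs), function(i) {
    s <- toupper(as.character(recs[[i]]))
    s <- chartr("U", "T", s)
    if (grepl("[^ACGTNRYSWKMBDHV]", s)) {
      ch <- regmatches(s, regexpr("[^ACGTNRYSWKMBDHV]", s))
      stop("record '", nm[i], "' contains non-nucleotide character '",
           ch, "'")
    }
    s <- gsub("[RYSWKMBDHV]", "N", s)
    assembly(nm[i], s, "forward")
  })
}

#' Write assemblies to FASTA
#' @param assemblies List of [assembly()] objects.
#' @param path Output file.
#' @export
write_assembly_fasta <- function(assemblies, path) {
  if (inherits(assemblies, "vdj_assembly")) assemblies <- list(assemblies)
  set <- Biostrings::DNAStringSet(vapply(assemblies, `[[`, "", "seq"))
  names(set) <- vapply(assemblies, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a germline reference set
#'
#' @param name Allele names (unique; IMGT-style names such as `IGHV1-2*02`
#'   have the gene type as their fourth character).
#' @param gene_type `"V"`, `"D"` or `"J"` per allele.
#' @param seq Ungapped nucleotide strings.
#' @param gapped Optional IMGT-gap-aligned strings (V only); each must equal
#'   its ungapped sequence once gap characters (`.` or `-`) are removed.
#' @param species Species label.
#' @return Object of class `vdj_reference_set`.
#' @export
reference_set <- function(name, gene_type, seq, gapped = NA_character_,
                          species = "synthetic") {
  if (anyDuplicated(name))
    stop("duplicate allele name: ", name[duplicated(name)][1L])
  stopifnot(all(gene_type %in% c("V", "D", "J")))
  seq <- toupper(seq)
  gapped <- toupper(gapped)
  ok <- is.na(gapped) | gsub("[.-]", "", gapped) == seq
  if (!all(ok))
    stop("gapped sequence does not match ungapped for allele ",
         name[!ok][1L])
  structure(list(alleles = data.frame(name = name, gene_type = gene_type,
                                      seq = seq,
                                      gapped = rep_len(gapped, length(name)),
                                      stringsAsFactors = FALSE),
                 species = species),
            class = "vdj_reference_set")
}

#' @export
print.vdj_reference_set <- function(x, ...) {
  cat(sprintf("Reference set (%s): %s\n", x$species,
              paste(sprintf("%s=%d", names(table(x$alleles$gene_type)),
                            table(x$alleles$gene_type)), collapse = " ")))
  invisible(x)
}

ref_allele <- function(refset, name) {
  i <- match(name, refset$alleles$name)
  if (is.na(i)) stop("allele ", name, " not in reference set")
  refset$alleles[i, ]
}

#' Read a germline reference set from FASTA files
#'
#' @param paths Named character vector or list mapping gene type (`V`, `D`,
#'   `J`) to a FASTA file of ungapped core coding-region alleles.
#' @param gapped_v_path Optional FASTA of IMGT-gap-aligned V alleles (gaps
#'   `.` or `-`); names must match alleles in the V file and the ungapped
#'   content must agree.
#' @param species Species label.
#' @return A [reference_set()].
#' @export
read_reference_set <- function(paths, gapped_v_path = NULL,
                               species = "unknown") {
  paths <- as.list(paths)
  stopifnot(all(names(paths) %in% c("V", "D", "J")), length(paths) >= 1L)
  nm <- character(0L); gt <- character(0L); sq <- character(0L)
  for (g in names(paths)) {
    recs <- Biostrings::readBStringSet(paths[[g]])
    nm <- c(nm, sub("\\s.*$", "", names(recs)))
    gt <- c(gt, rep(g, length(recs)))
    sq <- c(sq, toupper(as.character(recs)))
  }
  gp <- rep(NA_character_, length(nm))
  if (!is.null(gapped_v_path)) {
    grecs <- Biostrings::readBStringSet(gapped_v_path)
    gnm <- sub("\\s.*$", "", names(grecs))
    gsq <- toupper(as.character(grecs))
    miss <- setdiff(gnm, nm[gt == "V"])
    if (length(miss))
      stop("gapped allele without ungapped counterpart: ", miss[1L])
    gp[match(gnm, nm)] <- gsq
  }
  reference_set(nm, gt, sq, gp, species = species)
}

# ---------------------------------------------------------------------------
# Locus configuration

#' Per-locus motif geometry configuration
#'
#' Defaults describe an IGH-like heavy-chain locus: V genes carry a 23-nt
#' spacer in their 3' RSS, D genes 12-nt spacers on both sides, and J genes a
#' 23-nt spacer in their 5' RSS.
#'
#' @param locus Locus label (e.g. `"IGH"`).
#' @param v_spacer,d5_spacer,d3_spacer,j_spacer RSS spacer lengths in nt
#'   (each 12 or 23).
#' @param spacer_tolerance Allowed deviation from the canonical spacer (nt).
#' @param rss_search_window How far beyond the matched gene end to search for
#'   an RSS heptamer (nt).
#' @param v_end_adjust_max,d_end_adjust_max,j_start_adjust_max Maximum
#'   adjustment of a region boundary to meet the located heptamer (nt).
#' @param leader_search_window How far upstream of the V-REGION to search for
#'   L-PART1 (nt).
#' @param l_part2_length L-PART2 length in nt (canonically 11).
#' @param j_motif_pattern IUPAC pattern for the start of the conserved
#'   J-motif ([W/F]-G-X-G at the amino-acid level).
#' @param j_motif_offset Offset of the J-motif start upstream of the
#'   J-REGION 3' end (nt).
#' @param j_motif_tolerance Allowed shift of the J-motif from that offset
#'   (nt); shifts are constrained to the reading frame implied by the
#'   J-REGION end, so only multiples of 3 within the tolerance are tried.
#' @return Object of class `vdj_locus_config`.
#' @export
locus_config <- function(locus = "IGH",
                         v_spacer = 23L, d5_spacer = 12L, d3_spacer = 12L,
                         j_spacer = 23L, spacer_tolerance = 0L,
                         rss_search_window = 40L,
                         v_end_adjust_max = 10L,
                         d_end_adjust_max = 5L,
                         j_start_adjust_max = 5L,
                         leader_search_window = 500L,
                         l_part2_length = 11L,
                         j_motif_pattern = "TKGGGG",
                         j_motif_offset = 34L,
                         j_motif_tolerance = 3L) {
  cfg <- list(locus = locus, v_spacer = as.integer(v_spacer),
              d5_spacer = as.integer(d5_spacer),
              d3_spacer = as.integer(d3_spacer),
              j_spacer = as.integer(j_spacer),
              spacer_tolerance = as.integer(spacer_tolerance),
              rss_search_window = as.integer(rss_search_window),
              v_end_adjust_max = as.integer(v_end_adjust_max),
              d_end_adjust_max = as.integer(d_end_adjust_max),
              j_start_adjust_max = as.integer(j_start_adjust_max),
              leader_search_window = as.integer(leader_search_window),
              l_part2_length = as.integer(l_part2_length),
              j_motif_pattern = j_motif_pattern,
              j_motif_offset = as.integer(j_motif_offset),
              j_motif_tolerance = as.integer(j_motif_tolerance))
  for (f in c("v_spacer", "d5_spacer", "d3_spacer", "j_spacer"))
    if (!cfg[[f]] %in% c(12L, 23L))
      stop(f, " must be 12 or 23 nt")
  for (f in c("rss_search_window", "leader_search_window", "l_part2_length"))
    if (cfg[[f]] <= 0L) stop(f, " must be positive")
  structure(cfg, class = "vdj_locus_config")
}

# ---------------------------------------------------------------------------
# Motif parameter directories

# required motif names per searched gene type
required_motifs <- function(gene_types) {
  req <- c(if ("V" %in% gene_types)
             c("V_HEPTAMER", "V_NONAMER", "L_PART1", "L_PART2"),
           if ("D" %in% gene_types)
             c("D5_HEPTAMER", "D5_NONAMER", "D3_HEPTAMER", "D3_NONAMER"),
           if ("J" %in% gene_types) c("J_HEPTAMER", "J_NONAMER"))
  unique(req)
}

#' Read PWMs and locus configuration from a motif parameter directory
#'
#' The directory holds one `<MOTIF>.pwm` file per motif and a `config.yaml`.
#' A `.pwm` file is whitespace-separated, one row per motif position with
#' columns A C G T holding probabilities (rows must sum to 1 within 1e-6);
#' `#`-prefixed metadata lines carry `name`, `threshold` and optional
#' `consensus`.
#'
#' @param dir Directory path.
#' @param gene_types Gene types that will be searched; their required motifs
#'   must be present.
#' @return List with `pwms` (named list of PWMs) and `config`
#'   (a [locus_config()]).
#' @export
read_motif_params <- function(dir, gene_types = c("V", "D", "J")) {
  files <- list.files(dir, pattern = "\\.pwm$", full.names = TRUE)
  pwms <- lapply(files, read_pwm_file)
  names(pwms) <- vapply(pwms, `[[`, "", "name")
  miss <- setdiff(required_motifs(gene_types), names(pwms))
  if (length(miss))
    stop("missing required motif file(s) for requested gene types: ",
         paste(miss, collapse = ", "))
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path))
    do.call(locus_config, yaml::read_yaml(cfg_path))
  else locus_config()
  list(pwms = pwms, config = config)
}

read_pwm_file <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", m), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (identical(toupper(strsplit(trimws(body[1L]), "\\s+")[[1L]]),
                c("A", "C", "G", "T")))
    body <- body[-1L]
  mat <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  if (ncol(mat) != 4L) stop("PWM file ", path, " must have 4 columns A C G T")
  colnames(mat) <- c("A", "C", "G", "T")
  bad <- which(abs(rowSums(mat) - 1) > 1e-6)
  if (length(bad))
    stop("PWM file ", path, ": row ", bad[1L], " does not sum to 1")
  nm <- meta$name %||% sub("\\.pwm$", "", basename(path))
  thr <- if (!is.null(meta$threshold)) as.numeric(meta$threshold) else -Inf
  new_pwm(nm, mat, pseudocount = as.numeric(meta$pseudocount %||% 0),
          threshold = thr, consensus = meta$consensus)
}

#' Write PWMs and locus configuration to a motif parameter directory
#' @param pwms Named list of PWMs.
#' @param config A [locus_config()].
#' @param dir Output directory (created if needed).
#' @export
write_motif_params <- function(pwms, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pwms) {
    lines <- c(paste0("# name=", p$name),
               paste0("# threshold=", format(p$threshold, digits = 17)),
               if (!is.null(p$consensus)) paste0("# consensus=", p$consensus),
               paste0("# pseudocount=", p$pseudocount),
               "A C G T",
               apply(p$mat, 1L, function(r)
                 paste(format(r, digits = 17), collapse = " ")))
    writeLines(lines, file.path(dir, paste0(p$name, ".pwm")))
  }
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Annotation report

# fixed feature column order of the CSV report
.FEATURES <- c("l_part1", "l_part2", "v_region", "d_region", "j_region",
               "heptamer_5", "spacer_5", "nonamer_5",
               "heptamer_3", "spacer_3", "nonamer_3",
               "j_motif", "donor_splice")

#' Annotation report columns
#'
#' The CSV report schema is fixed: per-gene summary columns followed by
#' start/end/seq triples for every feature slot.  Coordinates are 1-based
#' inclusive on the input (forward) sequence; feature sequences are given in
#' the working (gene) sense.
#' @return Character vector of column names.
#' @export
report_columns <- function() {
  c("assembly", "gene_type", "functionality", "start", "end", "sense",
    "closest_reference", "percent_identity", "joint_log_likelihood", "notes",
    as.vector(t(outer(.FEATURES, c("start", "end", "seq"), paste, sep = "_"))))
}

#' Tabulate annotations
#'
#' @param annotations List of gene annotations (from [annotate_assembly()]).
#' @param assembly The annotated [assembly()] (used for its name).
#' @return `data.frame` with the [report_columns()] schema, one row per gene.
#' @export
annotation_table <- function(annotations, assembly) {
  cols <- report_columns()
  if (length(annotations) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0L)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  rows <- lapply(annotations, function(a) {
    row <- list(assembly = assembly$name,
                gene_type = a$gene_type,
                functionality = a$functionality,
                start = a$input_start, end = a$input_end,
                sense = if (a$sense == "forward") "+" else "-",
                closest_reference = a$closest_reference,
                percent_identity = a$percent_identity,
                joint_log_likelihood = a$joint_log_likelihood,
                notes = paste(a$notes, collapse = "; "))
    for (f in .FEATURES) {
      fe <- a$features[[f]]
      if (is.null(fe)) {
        row[[paste0(f, "_start")]] <- NA_integer_
        row[[paste0(f, "_end")]] <- NA_integer_
        row[[paste0(f, "_seq")]] <- NA_character_
      } else {
        inp <- work_to_input(fe$start, fe$end, a$sense, a$input_length)
        row[[paste0(f, "_start")]] <- inp[1L]
        row[[paste0(f, "_end")]] <- inp[2L]
        row[[paste0(f, "_seq")]] <- fe$seq
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[, cols]
}

#' Write the CSV annotation report
#'
#' One row per annotated gene; see [report_columns()] for the schema.
#' @param annotations List of gene annotations (consolidated).
#' @param assembly The annotated [assembly()].
#' @param path Output CSV path.
#' @export
write_annotation_report <- function(annotations, assembly, path) {
  utils::write.csv(annotation_table(annotations, assembly), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Write annotations as GFF3
#'
#' Mirrors the CSV features: one `gene` line per annotation plus one line per
#' feature, 1-based inclusive input coordinates, strand from the working
#' sense.
#' @inheritParams write_annotation_report
#' @export
write_annotation_gff3 <- function(annotations, assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  i <- 0L
  for (a in annotations) {
    i <- i + 1L
    strand <- if (a$sense == "forward") "+" else "-"
    gid <- sprintf("gene%03d", i)
    writeLines(sprintf(
      "%s\tvdjannot\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_type=%s;functionality=%s;closest_reference=%s",
      assembly$name, a$input_start, a$input_end, strand, gid, a$gene_type,
      a$functionality, a$closest_reference), con)
    for (f in names(a$features)) {
      fe <- a$features[[f]]
      if (is.null(fe)) next
      inp <- work_to_input(fe$start, fe$end, a$sense, a$input_length)
      writeLines(sprintf(
        "%s\tvdjannot\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
        assembly$name, f, inp[1L], inp[2L], strand, gid), con)
    }
  }
  invisible(path)
}
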