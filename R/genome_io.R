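#' Parse a FASTA description line into a contig id and optional coverage
#'
#' Recognizes the SPAdes dialect `NODE_<n>_length_<L>_cov_<c>`, in which case
#' the x-fold k-mer coverage `c` is extracted (the full header token is kept
#' as the id, matching how such assemblies are usually indexed). Any other
#' header falls back to the first whitespace-delimited token with no
#' coverage. Parsing is total: every header yields an id.
#'
#' @param header description line without the leading `>`.
#' @return list with `id` (string) and `coverage` (number or `NA`).
#' @examples
#' parse_contig_header("NODE_122_length_9071_cov_88.4")$coverage
#' parse_contig_header("scaffold_7 assembled")$id
#' @export
parse_contig_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  tok <- strsplit(trimws(header), "\\s+")[[1]][1]
  if (is.na(tok) || !nzchar(tok)) tok <- ""
  m <- regmatches(tok, regexec("^NODE_[0-9]+_length_[0-9]+_cov_([0-9]*\\.?[0-9]+)$", tok))[[1]]
  cov <- if (length(m) == 2L) as.numeric(m[2]) else NA_real_
  list(id = tok, coverage = cov)
}

#' Read a genome assembly from FASTA
#'
#' One contig per record, sequences uppercased, record order preserved.
#' Characters outside the IUPAC nucleotide alphabet are rejected or mapped to
#' `N` depending on `on_bad_char`; ambiguity codes other than `N` are mapped
#' to `N` (they carry no information for the downstream exact-match repeat
#' and telomere detectors, which skip `N`). Per-contig coverage is taken from
#' SPAdes-style headers or, if supplied, from a two-column sidecar TSV
#' (contig id, coverage) which takes precedence.
#'
#' @param path FASTA file.
#' @param species species name; defaults to the file base name.
#' @param coverage_tsv optional sidecar TSV with columns contig id, coverage.
#' @param on_bad_char `"error"` or `"mask"` (map to N, with a message).
#' @return A `mat_assembly`: list with `species`, `contigs`
#'   (named `DNAStringSet`), `coverage` (named numeric, `NA` when unknown).
#' @export
read_assembly <- function(path, species = NULL, coverage_tsv = NULL,
                          on_bad_char = c("error", "mask")) {
  on_bad_char <- match.arg(on_bad_char)
  if (!file.exists(path)) stop("assembly file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty assembly: ", path)
  headers <- names(raw)
  parsed <- lapply(headers, parse_contig_header)
  ids <- vapply(parsed, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  seqs <- toupper(as.character(raw))
  # uppercase IUPAC: keep ACGTN, map other ambiguity codes to N
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_bad_char == "error")
      stop("non-nucleotide characters in contig(s): ",
           paste(ids[bad], collapse = ", "))
    message("masking non-nucleotide characters to N in ",
            sum(bad), " contig(s)")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  coverage <- vapply(parsed, `[[`, 0, "coverage")
  names(coverage) <- ids
  if (!is.null(coverage_tsv)) {
    side <- utils::read.table(coverage_tsv, sep = "\t", header = FALSE,
                              col.names = c("contig", "coverage"),
                              stringsAsFactors = FALSE)
    hit <- match(ids, side$contig)
    coverage[!is.na(hit)] <- side$coverage[hit[!is.na(hit)]]
  }
  if (any(coverage < 0, na.rm = TRUE)) stop("negative coverage values")
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- ids
  new_assembly(species = species %||% sub("\\.(fa|fasta|fna)$", "", basename(path)),
               contigs = contigs, coverage = coverage)
}

#' Construct an assembly object from sequences already in memory
#'
#' @param species species name.
#' @param contigs named `DNAStringSet` (or named character vector).
#' @param coverage named numeric vector of x-fold depths (`NA` allowed).
#' @return A `mat_assembly`.
#' @export
new_assembly <- function(species, contigs, coverage = NULL) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names")
  if (sum(Biostrings::width(contigs)) == 0L) stop("empty assembly")
  if (is.null(coverage)) coverage <- rep(NA_real_, length(contigs))
  coverage <- coverage[match(names(contigs), names(coverage) %||% names(contigs))]
  names(coverage) <- names(contigs)
  structure(list(species = species, contigs = contigs, coverage = coverage),
            class = "mat_assembly")
}

#' @export
print.mat_assembly <- function(x, ...) {
  cat("<mat_assembly> ", x$species, ": ", length(x$contigs), " contig(s), ",
      sum(Biostrings::width(x$contigs)), " bp",
      if (!all(is.na(x$coverage)))
        paste0(", median coverage ", signif(median_coverage(x), 4)), "\n", sep = "")
  invisible(x)
}

#' Length-weighted median contig coverage
#'
#' The median of per-contig coverage values weighted by contig length,
#' over contigs that carry coverage; `NA` when none does. The weighting makes
#' the statistic robust to many short repeat-inflated contigs.
#'
#' @param assembly a `mat_assembly`.
#' @export
median_coverage <- function(assembly) {
  cov <- assembly$coverage
  len <- Biostrings::width(assembly$contigs)
  keep <- !is.na(cov)
  if (!any(keep)) return(NA_real_)
  cov <- cov[keep]; len <- len[keep]
  o <- order(cov)
  cov <- cov[o]; len <- len[o]
  cw <- cumsum(len) / sum(len)
  unname(cov[which(cw >= 0.5)[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- coordinate conventions ---------------------------------------------
# Internally every interval is 0-based half-open [start, end) on the forward
# strand. GFF3 is 1-based inclusive; conversion happens only at this boundary.

to_gff3_coords <- function(start0, end0) list(start = start0 + 1L, end = end0)
from_gff3_coords <- function(start1, end1) list(start = start1 - 1L, end = end1)

#' Export annotated features as GFF3
#'
#' Writes loci, repeat copies, telomeres and rDNA hits as GFF3 features
#' (types `mat_locus`, `repeat_pair`, `telomere`, `rdna_hit`). Internal
#' 0-based half-open spans are converted to the 1-based inclusive GFF3
#' convention at this boundary only.
#'
#' @param annotation result of [annotate_assembly()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_annotation_gff3 <- function(annotation, path) {
  grs <- list()
  loci <- annotation$loci
  if (length(loci)) {
    grs$loci <- GenomicRanges::GRanges(
      vapply(loci, `[[`, "", "contig"),
      IRanges::IRanges(vapply(loci, `[[`, 0L, "start") + 1L,
                       vapply(loci, `[[`, 0L, "end")),
      type = "mat_locus",
      ID = paste0("mat_locus_", seq_along(loci)),
      idiomorph = vapply(loci, `[[`, "", "idiomorph"))
  }
  rp <- annotation$repeats
  if (!is.null(rp) && nrow(rp)) {
    long <- data.frame(
      contig = c(rp$contigA, rp$contigB),
      start = c(rp$startA, rp$startB), end = c(rp$endA, rp$endB),
      ID = rep(paste0("repeat_pair_", seq_len(nrow(rp))), 2L),
      copy = rep(c("A", "B"), each = nrow(rp)),
      orientation = rep(rp$orientation, 2L), role = rep(rp$role, 2L),
      identity = rep(rp$identity, 2L))
    grs$repeats <- GenomicRanges::GRanges(
      long$contig, IRanges::IRanges(long$start + 1L, long$end),
      type = "repeat_pair", ID = paste0(long$ID, "_", long$copy),
      orientation = long$orientation, role = long$role,
      identity = long$identity)
  }
  tel <- annotation$telomeres
  if (!is.null(tel) && nrow(tel)) {
    grs$tel <- GenomicRanges::GRanges(
      tel$contig, IRanges::IRanges(tel$start + 1L, tel$end),
      type = "telomere", ID = paste0("telomere_", seq_len(nrow(tel))),
      unit = tel$unit, copies = tel$copies, contig_end = tel$contig_end)
  }
  rd <- annotation$rdna
  if (!is.null(rd) && nrow(rd)) {
    grs$rdna <- GenomicRanges::GRanges(
      rd$contig, IRanges::IRanges(rd$start + 1L, rd$end),
      type = "rdna_hit", ID = paste0("rdna_", seq_len(nrow(rd))))
  }
  if (!length(grs)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Export pipeline results
#'
#' Writes (a) the per-species calls as TSV (columns species, category,
#' ploidy_note, provisional, evidence), (b) loci and repeats as GFF3 per
#' species, (c) the transition summary as JSON, and (d) the state-labelled
#' tree as Newick, into `outdir`.
#'
#' @param calls named list of `mating_system_call` objects (names = species).
#' @param annotations named list of [annotate_assembly()] results (optional).
#' @param summary a `transition_summary` or `NULL`.
#' @param tree a state-labelled `phylo` (node labels = resolved states) or `NULL`.
#' @param outdir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
export_results <- function(calls, annotations = NULL, summary = NULL,
                           tree = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (length(calls)) {
    if (!is.null(annotations)) {
      missing_ann <- setdiff(names(calls), names(annotations))
      if (length(missing_ann))
        warning("calls without annotations: ", paste(missing_ann, collapse = ", "))
    }
    df <- data.frame(
      species = names(calls),
      category = vapply(calls, `[[`, "", "category"),
      ploidy_note = vapply(calls, `[[`, "", "ploidy_note"),
      provisional = vapply(calls, `[[`, TRUE, "provisional"),
      evidence = vapply(calls, function(x) paste(x$evidence, collapse = ";"), ""),
      row.names = NULL)
    f <- file.path(outdir, "calls.tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  for (sp in names(annotations %||% list())) {
    f <- file.path(outdir, paste0(gsub("[^A-Za-z0-9._-]", "_", sp), ".gff3"))
    export_annotation_gff3(annotations[[sp]], f)
    written <- c(written, f)
  }
  f <- file.path(outdir, "transition_summary.json")
  jsonlite::write_json(summary_to_list(summary), f, auto_unbox = TRUE,
                       digits = NA, null = "null")
  written <- c(written, f)
  if (!is.null(tree)) {
    f <- file.path(outdir, "state_labelled_tree.nwk")
    ape::write.tree(tree, f)
    written <- c(written, f)
  }
  invisible(written)
}

summary_to_list <- function(summary) {
  if (is.null(summary)) {
    return(list(events = list(), counts = list(),
                to_homothallism = 0L, to_heterothallism = 0L,
                switching_origins = 0L))
  }
  counts <- summary$counts
  cl <- as.list(counts$n)
  if (nrow(counts)) names(cl) <- paste0(counts$from, "->", counts$to)
  else cl <- stats::setNames(list(), character())
  list(events = summary$events, counts = cl,
       to_homothallism = summary$to_homothallism,
       to_heterothallism = summary$to_heterothallism,
       switching_origins = summary$switching_origins)
}
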