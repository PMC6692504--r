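# Genomic-context detectors: telomeric tandem arrays at contig ends, rDNA
# landmark hits, allelism of diploid locus pairs, and collapsed-repeat
# contigs inferred from coverage plus exact end overlaps.

# lexicographically smallest rotation of a repeat unit
canonical_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1, i - 1L)), "")
  sort(rots)[1]
}

#' Detect telomeric tandem arrays at the ends of a contig
#'
#' A telomere is reported at an end iff a tandem array of a unit with length
#' in `[unit_min, unit_max]` and at least `min_copies` copies lies within
#' `end_window` of that end. The unit is reported in canonical (lexicographic
#' minimal) rotation, so detection does not depend on the phase in which the
#' array was assembled. Positions containing `N` never match.
#'
#' @param seq contig sequence (string or `DNAString`).
#' @param cfg configuration (telomere_* fields).
#' @return data.frame with columns `contig_end` ("left"/"right"), `start`,
#'   `end` (0-based half-open), `unit`, `copies`; zero rows when no array
#'   qualifies.
#' @export
detect_telomere <- function(seq, cfg = default_config()) {
  s <- as.character(seq)
  L <- nchar(s)
  empty <- data.frame(contig_end = character(), start = integer(),
                      end = integer(), unit = character(), copies = integer())
  if (L < cfg$telomere_unit_min * cfg$telomere_min_copies) return(empty)
  v <- utf8ToInt(s); nval <- utf8ToInt("N")
  found <- list()
  for (u in cfg$telomere_unit_min:cfg$telomere_unit_max) {
    if (L < u * cfg$telomere_min_copies) break
    i <- seq_len(L - u)
    eq <- v[i] == v[i + u] & v[i] != nval
    r <- rle(eq)
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    ok <- which(r$values & r$lengths >= u * (cfg$telomere_min_copies - 1L))
    for (w in ok) {
      a0 <- starts_at[w] - 1L          # 0-based array start
      a1 <- ends_at[w] + u             # 0-based exclusive array end
      side <- NULL
      if (a0 <= cfg$telomere_end_window) side <- c(side, "left")
      if (L - a1 <= cfg$telomere_end_window) side <- c(side, "right")
      for (sd in side) {
        found[[length(found) + 1L]] <- data.frame(
          contig_end = sd, start = a0, end = a1, u = u,
          unit = canonical_rotation(substr(s, a0 + 1L, a0 + u)),
          copies = (a1 - a0) %/% u)
      }
    }
  }
  if (!length(found)) return(empty)
  df <- do.call(rbind, found)
  # per end keep the minimal-period array; among equal periods the longest
  df <- df[order(df$contig_end, df$u, -(df$end - df$start)), , drop = FALSE]
  df <- df[!duplicated(df$contig_end), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("contig_end", "start", "end", "unit", "copies")]
}

telomeres_of_assembly <- function(assembly, cfg) {
  out <- lapply(names(assembly$contigs), function(id) {
    tel <- detect_telomere(assembly$contigs[[id]], cfg)
    if (nrow(tel)) tel$contig <- id
    tel
  })
  out <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  if (is.null(out))
    return(data.frame(contig = character(), contig_end = character(),
                      start = integer(), end = integer(), unit = character(),
                      copies = integer()))
  out[, c("contig", "contig_end", "start", "end", "unit", "copies")]
}

#' Locate an rDNA landmark in an assembly
#'
#' Nucleotide matching of a user-supplied rDNA sequence by k-mer seeding and
#' diagonal extension, both orientations.
#'
#' @param assembly a `mat_assembly`.
#' @param landmark `DNAStringSet`/string of the rDNA unit.
#' @param cfg configuration.
#' @return data.frame with `contig`, `start`, `end` (0-based half-open).
#' @export
detect_rdna <- function(assembly, landmark, cfg = default_config()) {
  lm <- as.character(landmark)[1]
  min_len <- min(cfg$min_repeat_len, max(50L, floor(nchar(lm) / 2)))
  rows <- list()
  for (id in names(assembly$contigs)) {
    cs <- as.character(assembly$contigs[[id]])
    for (qry in c(lm, rc_string(lm))) {
      seg <- diagonal_segments(cs, qry, cfg$repeat_seed_k,
                               cfg$repeat_merge_gap, min_len,
                               cfg$min_repeat_identity)
      if (is.null(seg)) next
      rows[[length(rows) + 1L]] <- data.frame(
        contig = id, start = seg$a_start, end = seg$a_end)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  df <- do.call(rbind, rows)
  # merge overlapping hits (forward and reverse of the same array)
  out <- do.call(rbind, lapply(split(df, df$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(contig = d$contig[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  }))
  rownames(out) <- NULL
  out
}

local_dna_align <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  w <- Biostrings::width(Biostrings::subject(aln))
  list(width = if (Biostrings::score(aln) > 0) w else 0L,
       identity = if (Biostrings::score(aln) > 0) Biostrings::pid(aln) else 0)
}

#' Test whether two MAT loci are alleles of one diploid locus
#'
#' Diploid assemblies represent the two haplotypes of one heterothallic MAT
#' locus as two contigs with opposite idiomorphs whose flanking sequence is
#' shared on BOTH sides. The verdict is `allelic` when both flanks share at
#' least ~`flank_len` aligned bases at `flank_min_identity` (in either
#' relative orientation of the two contigs), `ambiguous` when exactly one
#' side does, `non_allelic` otherwise.
#'
#' @param assembly a `mat_assembly`.
#' @param locusA,locusB loci with opposite idiomorphs.
#' @param cfg configuration (`flank_len`, `flank_min_identity`).
#' @return list with `left_flank`, `right_flank` (shared length, identity)
#'   for the better orientation, `orientation`, and `verdict`.
#' @export
detect_allelism <- function(assembly, locusA, locusB, cfg = default_config()) {
  if (locusA$contig == locusB$contig &&
      locusA$start < locusB$end && locusB$start < locusA$end)
    stop("overlapping loci on one contig are malformed input")
  fl <- cfg$flank_len
  ext <- function(lc, side) {
    s <- assembly$contigs[[lc$contig]]
    if (side == "left")
      as.character(Biostrings::subseq(s, start = max(1L, lc$start - fl + 1L),
                                      end = max(1L, lc$start)))
    else
      as.character(Biostrings::subseq(s, start = min(length(s), lc$end + 1L),
                                      end = min(length(s), lc$end + fl)))
  }
  aL <- ext(locusA, "left"); aR <- ext(locusA, "right")
  bL <- ext(locusB, "left"); bR <- ext(locusB, "right")
  side_stats <- function(x, y) local_dna_align(x, y)
  shared <- function(st) st$width >= 0.95 * fl &&
    st$identity >= cfg$flank_min_identity
  direct <- list(left = side_stats(aL, bL), right = side_stats(aR, bR))
  flipped <- list(left = side_stats(aL, rc_string(bR)),
                  right = side_stats(aR, rc_string(bL)))
  n_dir <- sum(shared(direct$left), shared(direct$right))
  n_flip <- sum(shared(flipped$left), shared(flipped$right))
  use <- if (n_flip > n_dir) flipped else direct
  n <- max(n_dir, n_flip)
  list(left_flank = use$left, right_flank = use$right,
       orientation = if (n_flip > n_dir) "flipped" else "direct",
       verdict = c("non_allelic", "ambiguous", "allelic")[n + 1L])
}

#' Infer collapsed repeat contigs from coverage and exact end overlaps
#'
#' Two near-identical repeat copies (IR or X/Z regions) often co-assemble
#' into a single contig at about twice the median coverage, sharing exact
#' end overlaps of the assembler's longest k-mer length with the contigs
#' flanking each copy. A link is emitted for every contig whose coverage
#' ratio lies in `[cov_lo, cov_hi]` of the length-weighted median and that
#' shares an exact `k`-base end overlap (either orientation) with at least
#' two other contigs.
#'
#' @param assembly a `mat_assembly` with coverage values.
#' @param cfg configuration (`cov_lo`, `cov_hi`, `spades_k`).
#' @return data.frame with `repeat_contig`, `neighbors` (comma-joined),
#'   `n_neighbors`, `overlap_len`, `coverage_ratio`.
#' @export
infer_collapsed_repeats <- function(assembly, cfg = default_config()) {
  empty <- data.frame(repeat_contig = character(), neighbors = character(),
                      n_neighbors = integer(), overlap_len = integer(),
                      coverage_ratio = numeric())
  med <- median_coverage(assembly)
  if (is.na(med) || med <= 0) {
    warning("no coverage available; collapsed-repeat inference skipped")
    return(empty)
  }
  k <- cfg$spades_k
  ids <- names(assembly$contigs)
  lens <- Biostrings::width(assembly$contigs)
  seq_chr <- as.character(assembly$contigs)
  first_k <- ifelse(lens >= k, substr(seq_chr, 1L, k), NA_character_)
  last_k <- ifelse(lens >= k, substr(seq_chr, lens - k + 1L, lens),
                   NA_character_)
  ratio <- assembly$coverage / med
  cand <- which(!is.na(ratio) & ratio >= cfg$cov_lo & ratio <= cfg$cov_hi &
                  lens >= k)
  rows <- list()
  for (i in cand) {
    ms <- first_k[i]; me <- last_k[i]
    nb <- character()
    for (j in seq_along(ids)) {
      if (j == i || lens[j] < k) next
      cs <- first_k[j]; ce <- last_k[j]
      if (identical(me, cs) || identical(ce, ms) ||
          identical(me, rc_string(ce)) || identical(ms, rc_string(cs)))
        nb <- c(nb, ids[j])
    }
    if (length(nb) >= 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_contig = ids[i], neighbors = paste(sort(nb), collapse = ","),
        n_neighbors = length(nb), overlap_len = k,
        coverage_ratio = ratio[i])
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
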