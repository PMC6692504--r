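# Repeat detection by exact k-mer seeding on shared diagonals followed by
# identity scoring over the seeded segment. Geared to the substitution-level
# divergence seen between MAT-flanking repeat copies (90-100% identity);
# indel-rich repeats would fragment into several diagonal segments and are
# re-joined by the family merging step.

rc_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

# Shared-diagonal segments between two strings. Returns 0-based half-open
# intervals in a and b with percent identity (positions where either side is
# N are excluded from the identity denominator).
diagonal_segments <- function(a, b, k, merge_gap, min_len, min_identity,
                              max_kmer_occ = 50L) {
  ka <- seq_kmers(a, k); kb <- seq_kmers(b, k)
  if (!length(ka) || !length(kb)) return(NULL)
  okb <- !grepl("N", kb, fixed = TRUE)
  idx_b <- split(seq_along(kb)[okb], kb[okb])
  idx_b <- idx_b[lengths(idx_b) <= max_kmer_occ]
  oka <- which(!grepl("N", ka, fixed = TRUE) & ka %in% names(idx_b))
  if (!length(oka)) return(NULL)
  pb_list <- idx_b[ka[oka]]
  pa <- rep.int(oka, lengths(pb_list))
  pb <- unlist(pb_list, use.names = FALSE)
  d <- pb - pa
  av <- utf8ToInt(a); bv <- utf8ToInt(b); nval <- utf8ToInt("N")
  segs <- list()
  for (dd in unique(d)) {
    p <- sort(pa[d == dd])
    grp <- cumsum(c(1L, as.integer(diff(p) > merge_gap)))
    for (g in split(p, grp)) {
      s0 <- g[1] - 1L                      # 0-based start in a
      e0 <- g[length(g)] - 1L + k          # 0-based end (exclusive) in a
      if (e0 - s0 < min_len) next
      ia <- (s0 + 1L):e0
      ib <- ia + dd
      keep <- av[ia] != nval & bv[ib] != nval
      if (!sum(keep)) next
      ident <- 100 * sum(av[ia][keep] == bv[ib][keep]) / sum(keep)
      if (ident < min_identity) next
      segs[[length(segs) + 1L]] <- data.frame(
        a_start = s0, a_end = e0, b_start = s0 + dd, b_end = e0 + dd,
        length = e0 - s0, identity = ident)
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

# Repeat pairs between two genomic regions (same or different contigs).
# For inverted pairs, b-side coordinates are reported on the forward strand.
scan_region_pair <- function(seqA, seqB, self, cfg) {
  out <- list()
  dir <- diagonal_segments(seqA, seqB, cfg$repeat_seed_k, cfg$repeat_merge_gap,
                           cfg$min_repeat_len, cfg$min_repeat_identity)
  if (!is.null(dir)) {
    if (self) {
      dir <- dir[dir$b_start > dir$a_start & dir$b_start >= dir$a_end, ,
                 drop = FALSE]   # drop the trivial diagonal and overlaps
    }
    if (nrow(dir)) { dir$orientation <- "direct"; out$dir <- dir }
  }
  LB <- nchar(seqB)
  inv <- diagonal_segments(seqA, rc_string(seqB), cfg$repeat_seed_k,
                           cfg$repeat_merge_gap, cfg$min_repeat_len,
                           cfg$min_repeat_identity)
  if (!is.null(inv)) {
    bs <- LB - inv$b_end; be <- LB - inv$b_start
    inv$b_start <- bs; inv$b_end <- be
    if (self) {
      inv <- inv[inv$b_start >= inv$a_end, , drop = FALSE]  # dedupe mirrored + overlaps
    }
    if (nrow(inv)) { inv$orientation <- "inverted"; out$inv <- inv }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

merge_pair_families <- function(rp, merge_gap) {
  if (!nrow(rp)) return(rp)
  key <- paste(rp$contigA, rp$contigB, rp$orientation, sep = "\r")
  near <- function(s1, e1, s2, e2) s1 <= e2 + merge_gap & s2 <= e1 + merge_gap
  out <- lapply(split(seq_len(nrow(rp)), key), function(idx) {
    m <- rp[idx, , drop = FALSE]
    comp <- seq_len(nrow(m))
    repeat {                       # union-find by repeated sweeps (tiny n)
      changed <- FALSE
      for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
        if (comp[i] != comp[j] &&
            near(m$startA[i], m$endA[i], m$startA[j], m$endA[j]) &&
            near(m$startB[i], m$endB[i], m$startB[j], m$endB[j])) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    do.call(rbind, lapply(split(seq_len(nrow(m)), comp), function(jj) {
      g <- m[jj, , drop = FALSE]
      w <- g$length
      data.frame(contigA = g$contigA[1], startA = min(g$startA),
                 endA = max(g$endA), contigB = g$contigB[1],
                 startB = min(g$startB), endB = max(g$endB),
                 length = max(g$endA) - min(g$startA),
                 identity = sum(g$identity * w) / sum(w),
                 orientation = g$orientation[1])
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Find repeated sequences in the vicinity of MAT-like loci
#'
#' Compares windows around each locus (and between loci across contigs)
#' all-vs-all in both orientations and reports repeat families meeting the
#' length and identity thresholds. Roles are assigned from topology:
#' `IR` for an inverted family on one contig whose two copies bound a span
#' containing opposite idiomorphs (or, nested within such a span, a second
#' inverted family); `XZ_like` for a direct family whose copies each sit at
#' a cassette boundary; `unknown` otherwise.
#'
#' @param assembly a `mat_assembly`.
#' @param loci list of loci from [assemble_mat_loci()].
#' @param cfg configuration; see [default_config()].
#' @return data.frame of repeat pairs (0-based half-open copy coordinates,
#'   canonical copy order) with columns `contigA/startA/endA`,
#'   `contigB/startB/endB`, `length`, `identity`, `orientation`, `role`,
#'   `reachesA`, `reachesB`, `artifact`.
#' @export
find_flanking_repeats <- function(assembly, loci, cfg = default_config()) {
  empty <- data.frame(contigA = character(), startA = integer(),
                      endA = integer(), contigB = character(),
                      startB = integer(), endB = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character(), role = character(),
                      reachesA = logical(), reachesB = logical(),
                      artifact = logical())
  if (!length(loci)) return(empty)
  clen <- Biostrings::width(assembly$contigs)
  names(clen) <- names(assembly$contigs)
  # scan regions: union of windows around loci, per contig
  reg <- do.call(rbind, lapply(loci, function(lc) data.frame(
    contig = lc$contig,
    start = max(0L, lc$start - cfg$repeat_window),
    end = min(clen[[lc$contig]], lc$end + cfg$repeat_window))))
  regions <- do.call(rbind, lapply(split(reg, reg$contig), function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    data.frame(contig = r$contig[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  }))
  rownames(regions) <- NULL
  seqs <- vapply(seq_len(nrow(regions)), function(i)
    as.character(Biostrings::subseq(
      assembly$contigs[[regions$contig[i]]],
      start = regions$start[i] + 1L, end = regions$end[i])), "")
  pairs <- list()
  for (i in seq_len(nrow(regions))) for (j in i:nrow(regions)) {
    hits <- scan_region_pair(seqs[i], seqs[j], self = (i == j), cfg)
    if (is.null(hits) || !nrow(hits)) next
    hits$contigA <- regions$contig[i]
    hits$contigB <- regions$contig[j]
    hits$startA <- hits$a_start + regions$start[i]
    hits$endA <- hits$a_end + regions$start[i]
    hits$startB <- hits$b_start + regions$start[j]
    hits$endB <- hits$b_end + regions$start[j]
    pairs[[length(pairs) + 1L]] <-
      hits[, c("contigA", "startA", "endA", "contigB", "startB", "endB",
               "length", "identity", "orientation")]
  }
  if (!length(pairs)) return(empty)
  rp <- do.call(rbind, pairs)
  # canonical copy order
  flip <- rp$contigA > rp$contigB |
    (rp$contigA == rp$contigB & rp$startA > rp$startB)
  if (any(flip)) {
    tmp <- rp[flip, c("contigB", "startB", "endB")]
    rp[flip, c("contigB", "startB", "endB")] <-
      rp[flip, c("contigA", "startA", "endA")]
    rp[flip, c("contigA", "startA", "endA")] <- tmp
  }
  rp <- merge_pair_families(rp, cfg$repeat_merge_gap)
  rp$role <- assign_repeat_roles(rp, loci)
  rp$reachesA <- rp$startA <= cfg$end_margin |
    rp$endA >= clen[rp$contigA] - cfg$end_margin
  rp$reachesB <- rp$startB <= cfg$end_margin |
    rp$endB >= clen[rp$contigB] - cfg$end_margin
  rp$artifact <- vapply(seq_len(nrow(rp)), function(i)
    flag_assembly_artifact(rp[i, ], cfg), TRUE)
  rp <- rp[order(rp$contigA, rp$startA, rp$contigB, rp$startB), , drop = FALSE]
  rownames(rp) <- NULL
  rp
}

assign_repeat_roles <- function(rp, loci) {
  if (!nrow(rp)) return(character())
  ldf <- do.call(rbind, lapply(loci, function(lc) data.frame(
    contig = lc$contig, start = lc$start, end = lc$end,
    idiomorph = lc$idiomorph)))
  role <- rep("unknown", nrow(rp))
  for (i in seq_len(nrow(rp))) {
    same <- rp$contigA[i] == rp$contigB[i]
    if (rp$orientation[i] == "inverted" && same) {
      inner <- ldf[ldf$contig == rp$contigA[i] &
                     ldf$start >= rp$endA[i] & ldf$end <= rp$startB[i], ,
                   drop = FALSE]
      idio <- unique(inner$idiomorph)
      if (("a" %in% idio || "both" %in% idio) &&
          ("alpha" %in% idio || "both" %in% idio)) {
        role[i] <- "IR"
        next
      }
      # nested inner IR of a two-family flip/flop arrangement
      outer_ok <- any(rp$orientation == "inverted" &
                        rp$contigA == rp$contigA[i] &
                        rp$contigB == rp$contigB[i] &
                        rp$endA <= rp$startA[i] & rp$startB >= rp$endB[i] &
                        seq_len(nrow(rp)) != i)
      if (outer_ok) role[i] <- "IR"
    } else if (rp$orientation[i] == "direct") {
      nearA <- any(ldf$contig == rp$contigA[i] &
                     (abs(ldf$start - rp$endA[i]) <= 1000 |
                        abs(rp$startA[i] - ldf$end) <= 1000))
      nearB <- any(ldf$contig == rp$contigB[i] &
                     (abs(ldf$start - rp$endB[i]) <= 1000 |
                        abs(rp$startB[i] - ldf$end) <= 1000))
      if (nearA && nearB) role[i] <- "XZ_like"
    }
  }
  role
}

#' Diagnose a repeat pair as a likely assembler artifact
#'
#' Very long inverted repeats whose copies are nearly identical and extend
#' to the ends of their contig are characteristic of how some assemblers
#' (notably DISCOVAR) represent unresolved flip/flop regions: the repeat is
#' real but its assembled length is not trustworthy. The gates are: length
#' at least `artifact_min_len`, at most `artifact_max_mismatch` mismatching
#' positions, and both copies reaching a contig end.
#'
#' @param pair one row of a repeat-pair table.
#' @param cfg configuration.
#' @return logical.
#' @export
flag_assembly_artifact <- function(pair, cfg = default_config()) {
  if (is.null(pair$reachesA) || is.null(pair$reachesB))
    stop("repeat pair must carry reachesA/reachesB flags")
  mism <- round(pair$length * (1 - pair$identity / 100))
  isTRUE(pair$length >= cfg$artifact_min_len &&
           mism <= cfg$artifact_max_mismatch &&
           pair$reachesA && pair$reachesB)
}
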