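# TBLASTN-surrogate: six-frame translated local alignment of protein queries
# against an assembly, retaining weak hits (E < e_max) and chaining split
# HSPs of one gene before coverage computation.

.matsys_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.matsys_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .matsys_env$BLOSUM62 <- e$BLOSUM62
  }
  .matsys_env$BLOSUM62
}

empty_hits <- function() {
  data.frame(query = character(), source = character(), family = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), raw_score = numeric(),
             bit_score = numeric(), e_value = numeric(),
             query_cover = numeric(), n_internal_stops = integer(),
             q_start = integer(), q_end = integer())
}

#' Translated search for MAT and landmark genes in an assembly
#'
#' Aligns every protein query against all six reading frames of every contig
#' (Smith-Waterman, BLOSUM62), converts raw scores to E-values with the
#' Karlin-Altschul model over a search space of six times the assembly
#' length, and keeps every hit with `E < e_max` (weak hits included by
#' design: diverged MAT genes and gene fragments inside repeats must be
#' seen). Secondary hits on a frame are found by masking earlier hits and
#' re-aligning, so duplicated cassettes yield one hit per copy.
#'
#' Hits of the same query, contig and strand separated by at most
#' `max_chain_gap` are chained (tolerating frameshifts or introns that split
#' a gene across frames) before query coverage is computed. Genomic regions
#' hit by more than one distinct MAT-core query within `region_join_window`
#' are flagged as candidate MAT regions.
#'
#' @param assembly a `mat_assembly`.
#' @param queries query set data.frame (see [toy_queries()]).
#' @param code genetic code tag (`standard`, `cug_ser`, `cug_ala`).
#' @param cfg threshold configuration, see [default_config()].
#' @return list with `hits` (one row per retained HSP), `chains` (chained
#'   hits with combined query coverage), `candidates` (regions hit by >1
#'   distinct MAT query), and `searched = TRUE`.
#' @export
search_mat_genes <- function(assembly, queries, code = "standard",
                             cfg = default_config()) {
  stopifnot(inherits(assembly, "mat_assembly"), nrow(queries) > 0)
  code <- match.arg(code, c("standard", "cug_ser", "cug_ala"))
  mat <- blosum62()
  n_space <- 6 * sum(Biostrings::width(assembly$contigs))
  rows <- list()
  for (ci in seq_along(assembly$contigs)) {
    contig_id <- names(assembly$contigs)[ci]
    cseq <- assembly$contigs[[ci]]
    if (length(cseq) < 3L) next
    frames <- six_frame_translate(cseq, code)
    qset <- Biostrings::AAStringSet(queries$seq)
    for (fr in frames) {
      if (!nzchar(fr$peptide)) next
      # one batched pass scores every query against this frame; only
      # queries whose best score already beats the E cutoff are re-aligned
      # individually (for spans, and iteratively after masking)
      batch <- Biostrings::pairwiseAlignment(
        qset, Biostrings::AAString(fr$peptide), type = "local",
        substitutionMatrix = mat, gapOpening = cfg$blosum_gap_open,
        gapExtension = cfg$blosum_gap_extend, scoreOnly = TRUE)
      pass <- which(estimate_evalue(batch, nchar(queries$seq), n_space,
                                    K = cfg$ka_K,
                                    lambda = cfg$ka_lambda) < cfg$e_max)
      for (qi in pass) {
        qseq <- queries$seq[qi]
        qlen <- nchar(qseq)
        pep <- fr$peptide
        for (iter in seq_len(cfg$max_hits_per_frame)) {
          al <- local_align(qseq, pep, matrix = mat,
                            gap_open = cfg$blosum_gap_open,
                            gap_extend = cfg$blosum_gap_extend)
          if (al$raw_score <= 0) break
          ev <- estimate_evalue(al$raw_score, qlen, n_space,
                                K = cfg$ka_K, lambda = cfg$ka_lambda)
          if (ev >= cfg$e_max) break
          gspan <- frame_to_genomic(fr, al$t_start, al$t_end)
          tgt <- substr(fr$peptide, al$t_start, al$t_end)
          rows[[length(rows) + 1L]] <- data.frame(
            query = queries$name[qi], source = queries$source[qi],
            family = queries$family[qi], contig = contig_id,
            start = gspan$start, end = gspan$end,
            strand = fr$strand, frame = fr$frame,
            raw_score = al$raw_score,
            bit_score = bit_score(al$raw_score, cfg$ka_K, cfg$ka_lambda),
            e_value = ev,
            query_cover = (al$q_end - al$q_start + 1L) / qlen,
            n_internal_stops = lengths(gregexpr("\\*", tgt)) *
              grepl("*", tgt, fixed = TRUE),
            q_start = al$q_start, q_end = al$q_end)
          # mask and re-search for further copies of this query
          substr(pep, al$t_start, al$t_end) <-
            strrep("X", al$t_end - al$t_start + 1L)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits <- hits[order(hits$contig, hits$start, hits$query, hits$source), ,
               drop = FALSE]
  rownames(hits) <- NULL
  chains <- chain_hits(hits, queries, cfg$max_chain_gap)
  list(hits = hits, chains = chains,
       candidates = candidate_regions(hits, cfg$region_join_window),
       searched = TRUE)
}

#' Chain split HSPs of one query into gene-level hits
#'
#' Hits of the same query (symbol and source), contig and strand whose
#' genomic intervals are within `max_gap` of each other are merged. Query
#' coverage of a chain is the fraction of the query covered by the union of
#' member query intervals; internal stop codons are summed over members.
#'
#' @param hits hit table from [search_mat_genes()].
#' @param queries the query set used (for query lengths).
#' @param max_gap chaining gap in bp.
#' @return data.frame of chains.
#' @export
chain_hits <- function(hits, queries, max_gap = 1500) {
  if (!nrow(hits)) {
    return(data.frame(query = character(), source = character(),
                      family = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      e_value = numeric(), query_cover = numeric(),
                      n_internal_stops = integer(), n_members = integer()))
  }
  qlen <- nchar(queries$seq)
  names(qlen) <- paste(queries$name, queries$source, sep = "\r")
  key <- paste(hits$query, hits$source, hits$contig, hits$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1] > h$end[-nrow(h)] + max_gap)))
    do.call(rbind, lapply(split(seq_len(nrow(h)), grp), function(j) {
      m <- h[j, , drop = FALSE]
      ql <- qlen[[paste(m$query[1], m$source[1], sep = "\r")]]
      qcov <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(m$q_start, m$q_end)))) / ql
      data.frame(query = m$query[1], source = m$source[1],
                 family = m$family[1], contig = m$contig[1],
                 start = min(m$start), end = max(m$end),
                 strand = m$strand[1],
                 raw_score = sum(m$raw_score),
                 bit_score = max(m$bit_score),
                 e_value = min(m$e_value),
                 query_cover = min(1, qcov),
                 n_internal_stops = sum(m$n_internal_stops),
                 n_members = nrow(m))
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start, out$query, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Regions hit by more than one distinct MAT-core query within `join_window`.
candidate_regions <- function(hits, join_window = 2000) {
  core <- hits[hits$family == "mat_core", , drop = FALSE]
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), queries = character())
  if (!nrow(core)) return(empty)
  out <- lapply(split(seq_len(nrow(core)), core$contig), function(idx) {
    h <- core[idx, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      h$start[-1] > cummax(h$end[-nrow(h)]) + join_window)))
    do.call(rbind, lapply(split(seq_len(nrow(h)), grp), function(j) {
      m <- h[j, , drop = FALSE]
      qs <- sort(unique(m$query))
      if (length(qs) < 2L) return(NULL)
      data.frame(contig = m$contig[1], start = min(m$start),
                 end = max(m$end), queries = paste(qs, collapse = ","))
    }))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
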