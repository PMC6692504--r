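# Gene-level calls from chained hits, and assembly of MAT loci with their
# neighbor distances and genomic-context flags.

#' Call genes from chained translated-search hits
#'
#' Status is a total function of query coverage and internal stop codons:
#' `intact` needs coverage of at least `intact_min_cover` with no internal
#' stops, `pseudogene` has that coverage but contains stops, anything
#' shorter is a `fragment` (repeat copies often contain duplicated parts of
#' MAT genes, so distinguishing intact genes from fragments is what keeps
#' cassette counts honest). When chains of the same gene overlap (multiple
#' query sources, or opposite strands over one locus), the highest
#' bit-score chain wins.
#'
#' @param search result of [search_mat_genes()] (or a compatible `chains`
#'   data.frame).
#' @param cfg configuration.
#' @return data.frame of gene calls with columns `gene`, `family`, `contig`,
#'   `start`, `end`, `strand`, `status`, `query_cover`, `n_internal_stops`,
#'   `bit_score`.
#' @export
call_genes <- function(search, cfg = default_config()) {
  chains <- if (is.data.frame(search)) search else search$chains
  empty <- data.frame(gene = character(), family = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      status = character(), query_cover = numeric(),
                      n_internal_stops = integer(), bit_score = numeric())
  if (is.null(chains) || !nrow(chains)) return(empty)
  st <- ifelse(chains$query_cover >= cfg$intact_min_cover,
               ifelse(chains$n_internal_stops > 0, "pseudogene", "intact"),
               "fragment")
  calls <- data.frame(gene = chains$query, family = chains$family,
                      contig = chains$contig, start = chains$start,
                      end = chains$end, strand = chains$strand, status = st,
                      query_cover = chains$query_cover,
                      n_internal_stops = chains$n_internal_stops,
                      bit_score = chains$bit_score)
  # deduplicate overlapping calls of one gene: best bit score wins
  out <- lapply(split(seq_len(nrow(calls)),
                      paste(calls$gene, calls$contig, sep = "\r")),
                function(idx) {
    m <- calls[idx, , drop = FALSE]
    m <- m[order(-m$bit_score), , drop = FALSE]
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m))) {
      if (!keep[i]) next
      if (i < nrow(m)) for (j in (i + 1L):nrow(m)) {
        if (keep[j] && m$start[j] < m$end[i] && m$start[i] < m$end[j])
          keep[j] <- FALSE
      }
    }
    m[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

idiomorph_of <- function(genes) {
  has_a <- any(genes %in% A_GENES)
  has_alpha <- any(genes %in% ALPHA_GENES)
  if (has_a && has_alpha) "both" else if (has_a) "a" else "alpha"
}

#' Assemble MAT loci from gene calls
#'
#' Intact MAT-core genes on one contig within `max_locus_gap` of each other
#' form one locus. A locus containing an intact a1 and/or a2 gene is a MATa
#' locus, one with an intact alpha1 and/or alpha2 a MATalpha locus (both
#' genes of a pair are not required); a locus with intact genes of both
#' types has idiomorph `both`. Signed distances to the nearest intact
#' neighbor genes (SLA2, DIC1, APN2) are recorded, along with context
#' flags: distance to the nearest contig end, proximity to a detected
#' telomeric end, and proximity to an rDNA hit.
#'
#' @param calls gene calls from [call_genes()].
#' @param assembly the assembly (for contig lengths).
#' @param telomeres telomere table from [telomeres_of_assembly()] (optional).
#' @param rdna rDNA hit table from [detect_rdna()] (optional).
#' @param cfg configuration.
#' @return list of `mat_locus` objects.
#' @export
assemble_mat_loci <- function(calls, assembly, telomeres = NULL, rdna = NULL,
                              cfg = default_config()) {
  core <- calls[calls$family == "mat_core" & calls$status == "intact", ,
                drop = FALSE]
  if (!nrow(core)) return(list())
  clen <- Biostrings::width(assembly$contigs)
  names(clen) <- names(assembly$contigs)
  nb <- calls[calls$family == "neighbor" & calls$status == "intact", ,
              drop = FALSE]
  loci <- list()
  for (ct in unique(core$contig)) {
    m <- core[core$contig == ct, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      m$start[-1] > cummax(m$end[-nrow(m)]) + cfg$max_locus_gap)))
    for (g in split(seq_len(nrow(m)), grp)) {
      gm <- m[g, , drop = FALSE]
      lc <- list(contig = ct, start = min(gm$start), end = max(gm$end),
                 idiomorph = idiomorph_of(gm$gene), genes = gm)
      # signed neighbor distances (negative: neighbor upstream of locus)
      nbc <- nb[nb$contig == ct, , drop = FALSE]
      dists <- sapply(unique(nbc$gene), function(gn) {
        x <- nbc[nbc$gene == gn, , drop = FALSE]
        d_after <- x$start - lc$end      # >= 0 when downstream
        d_before <- x$end - lc$start     # <= 0 when upstream
        d <- ifelse(x$start >= lc$end, d_after,
                    ifelse(x$end <= lc$start, d_before, 0L))
        d[which.min(abs(d))]
      })
      lc$neighbors <- if (length(dists)) dists else
        stats::setNames(integer(), character())
      L <- clen[[ct]]
      lc$contig_end_distance <- min(lc$start, L - lc$end)
      lc$telomere_proximal <- FALSE
      if (!is.null(telomeres) && nrow(telomeres)) {
        tct <- telomeres[telomeres$contig == ct, , drop = FALSE]
        for (i in seq_len(nrow(tct))) {
          d <- if (tct$contig_end[i] == "left") lc$start - tct$end[i]
               else tct$start[i] - lc$end
          if (d <= cfg$telomere_proximal_window) lc$telomere_proximal <- TRUE
        }
      }
      lc$rdna_proximal <- FALSE
      if (!is.null(rdna) && nrow(rdna)) {
        rct <- rdna[rdna$contig == ct, , drop = FALSE]
        if (nrow(rct)) {
          gap <- pmax(0L, pmax(rct$start - lc$end, lc$start - rct$end))
          if (any(gap <= cfg$rdna_window)) lc$rdna_proximal <- TRUE
        }
      }
      loci[[length(loci) + 1L]] <- structure(lc, class = "mat_locus")
    }
  }
  loci
}

#' @export
print.mat_locus <- function(x, ...) {
  cat("<mat_locus> ", x$contig, ":", x$start, "-", x$end,
      " idiomorph=", x$idiomorph,
      " genes=", paste(x$genes$gene, collapse = ","),
      if (x$telomere_proximal) " [telomere]",
      if (x$rdna_proximal) " [rDNA]", "\n", sep = "")
  invisible(x)
}

# Clusters of non-intact MAT-core calls away from intact loci; candidate
# silent/degenerate cassettes for three-locus systems.
fragment_cassettes <- function(calls, loci, cfg) {
  fr <- calls[calls$family == "mat_core" & calls$status != "intact" &
                calls$query_cover >= cfg$fragment_min_cover &
                calls$bit_score >= cfg$fragment_min_bits, ,
              drop = FALSE]
  if (!nrow(fr)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), genes = character()))
  }
  in_locus <- vapply(seq_len(nrow(fr)), function(i) {
    any(vapply(loci, function(lc)
      lc$contig == fr$contig[i] && fr$start[i] < lc$end + 1000 &&
        lc$start - 1000 < fr$end[i], TRUE))
  }, TRUE)
  fr <- fr[!in_locus, , drop = FALSE]
  if (!nrow(fr)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), genes = character()))
  }
  out <- lapply(split(fr, fr$contig), function(m) {
    m <- m[order(m$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      m$start[-1] > cummax(m$end[-nrow(m)]) + 2000)))
    do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(j) {
      g <- m[j, , drop = FALSE]
      data.frame(contig = g$contig[1], start = min(g$start),
                 end = max(g$end),
                 genes = paste(sort(unique(g$gene)), collapse = ","))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
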