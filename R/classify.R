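# The seven-way decision rules. Rules are evaluated in a fixed order and the
# first match decides; every gate evaluated is recorded in the evidence
# trail so a call can be audited back to the measurements that fired it.

new_call <- function(category, ploidy = "unknown", provisional = FALSE,
                     evidence = character()) {
  structure(list(category = category, ploidy_note = ploidy,
                 provisional = provisional, evidence = evidence),
            class = "mating_system_call")
}

#' @export
print.mating_system_call <- function(x, ...) {
  cat("<mating_system_call> ", x$category,
      " (ploidy: ", x$ploidy_note, ")",
      if (x$provisional) " [provisional]", "\n  evidence: ",
      paste(x$evidence, collapse = "; "), "\n", sep = "")
  invisible(x)
}

locus_has_a <- function(lc) lc$idiomorph %in% c("a", "both")
locus_has_alpha <- function(lc) lc$idiomorph %in% c("alpha", "both")

#' Classify one species' annotated evidence into a mating system
#'
#' Applies the decision rules in fixed order; the first matching rule
#' decides:
#'
#' 1. no intact MAT genes anywhere -> `NOMAT`;
#' 2. only one idiomorph present -> `HET` (haploid);
#' 3. both idiomorphs, every opposite-idiomorph locus pair allelic ->
#'    `HET` (diploid assembly);
#' 4. three or more non-allelic cassettes (intact loci plus degenerate
#'    cassettes bounded by X/Z-like repeats or sitting on collapsed-repeat
#'    contigs) -> `3LOC`;
#' 5. both idiomorphs non-allelic with inverted-repeat evidence spanning
#'    them: exactly one IR family -> `FF1`, two or more -> `FF2`. IR
#'    families are counted from same-contig inverted pairs, from repeat
#'    families whose copies connect the two locus-bearing contigs (relative
#'    orientation then unknowable: the call is flagged provisional), and
#'    from collapsed-repeat links joining opposite-idiomorph contigs.
#'    Artifact-flagged repeats still count but also set the provisional
#'    flag. Repeats trump distance: a repeat-linked pair is never primary
#'    homothallic;
#' 6. both idiomorphs, no qualifying repeats: nearest a-gene/alpha-gene
#'    distance on one contig below `phc_max_gap` -> `PHC`, otherwise
#'    (including different contigs) -> `PHN`.
#'
#' @param annotation a `mat_annotation` from [annotate_assembly()], or a
#'   list with elements `loci`, `repeats`, `allelism`, `links`,
#'   `fragments`, `searched`.
#' @param cfg configuration.
#' @return a `mating_system_call`.
#' @export
classify_species <- function(annotation, cfg = default_config()) {
  loci <- annotation$loci %||% list()
  repeats <- annotation$repeats
  allelism <- annotation$allelism
  links <- annotation$links
  fragments <- annotation$fragments
  ev <- character()

  # rule 1: NOMAT
  if (!length(loci)) {
    if (!isTRUE(annotation$searched)) stop("species not searched")
    return(new_call("NOMAT",
                    evidence = "rule1:no_intact_MAT_gene_in_assembly"))
  }
  ev <- c(ev, sprintf("rule1:intact_loci=%d", length(loci)))

  # rule 2: single idiomorph
  has_a <- any(vapply(loci, locus_has_a, TRUE))
  has_alpha <- any(vapply(loci, locus_has_alpha, TRUE))
  if (!(has_a && has_alpha)) {
    idio <- if (has_a) "a" else "alpha"
    return(new_call("HET", ploidy = "haploid",
                    evidence = c(ev, sprintf("rule2:single_idiomorph=%s", idio))))
  }
  ev <- c(ev, "rule2:both_idiomorphs_present")

  # rule 3: all opposite-idiomorph pairs allelic -> diploid HET
  opp <- opposite_pairs(loci)
  n_allelic <- 0L
  if (nrow(opp)) {
    verdicts <- apply(opp, 1L, function(p) {
      v <- allelism$verdict[allelism$locusA == p[1] & allelism$locusB == p[2]]
      if (length(v)) v[1] else "non_allelic"
    })
    n_allelic <- sum(verdicts == "allelic")
    ev <- c(ev, sprintf("rule3:opposite_pairs=%d,allelic=%d",
                        nrow(opp), n_allelic))
    if (all(verdicts == "allelic")) {
      return(new_call("HET", ploidy = "diploid",
                      evidence = c(ev, "rule3:all_pairs_allelic")))
    }
  }

  # rule 4: three or more non-allelic cassettes
  n_frag <- qualifying_fragment_cassettes(fragments, repeats, links)
  n_cassettes <- length(loci) - n_allelic + n_frag
  ev <- c(ev, sprintf("rule4:cassettes=%d(intact=%d,degenerate=%d,allelic_merged=%d)",
                      n_cassettes, length(loci), n_frag, n_allelic))
  if (n_cassettes >= 3L) {
    return(new_call("3LOC", evidence = c(ev, "rule4:three_locus_layout")))
  }

  # rule 5: inverted-repeat families spanning the idiomorphs
  fam <- ir_family_evidence(loci, repeats, links)
  ev <- c(ev, sprintf("rule5:ir_families=%d(same_contig=%d,cross_contig=%d,coverage_links=%d,artifact=%d)",
                      fam$n, fam$n_same, fam$n_cross, fam$n_links, fam$n_artifact))
  if (fam$n >= 1L) {
    cat_ <- if (fam$n == 1L) "FF1" else "FF2"
    prov <- fam$n_cross > 0L || fam$n_artifact > 0L
    return(new_call(cat_, provisional = prov,
                    evidence = c(ev, sprintf("rule5:%s", cat_))))
  }

  # rule 6: primary homothallism, contiguous vs non-contiguous
  gap <- min_idiomorph_gap(loci)
  if (is.finite(gap) && gap < cfg$phc_max_gap) {
    new_call("PHC", evidence = c(ev, sprintf("rule6:gap=%d<%d", gap,
                                             cfg$phc_max_gap)))
  } else {
    g <- if (is.finite(gap)) sprintf("gap=%d", gap) else "different_contigs"
    new_call("PHN", evidence = c(ev, sprintf("rule6:%s", g)))
  }
}

opposite_pairs <- function(loci) {
  out <- list()
  n <- length(loci)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ai <- loci[[i]]$idiomorph; aj <- loci[[j]]$idiomorph
    if ((ai == "a" && aj == "alpha") || (ai == "alpha" && aj == "a"))
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(), ncol = 2L))
  do.call(rbind, out)
}

qualifying_fragment_cassettes <- function(fragments, repeats, links) {
  if (is.null(fragments) || !nrow(fragments)) return(0L)
  link_contigs <- character()
  if (!is.null(links) && nrow(links)) {
    link_contigs <- unique(c(links$repeat_contig,
                             unlist(strsplit(links$neighbors, ","))))
  }
  ok <- vapply(seq_len(nrow(fragments)), function(i) {
    if (fragments$contig[i] %in% link_contigs) return(TRUE)
    if (is.null(repeats) || !nrow(repeats)) return(FALSE)
    d <- repeats[repeats$orientation == "direct", , drop = FALSE]
    if (!nrow(d)) return(FALSE)
    any((d$contigA == fragments$contig[i] &
           pmax(d$startA - fragments$end[i],
                fragments$start[i] - d$endA) <= 1000) |
          (d$contigB == fragments$contig[i] &
             pmax(d$startB - fragments$end[i],
                  fragments$start[i] - d$endB) <= 1000))
  }, TRUE)
  sum(ok)
}

ir_family_evidence <- function(loci, repeats, links) {
  a_contigs <- unique(vapply(Filter(locus_has_a, loci), `[[`, "", "contig"))
  alpha_contigs <- unique(vapply(Filter(locus_has_alpha, loci), `[[`, "",
                                 "contig"))
  locus_contigs <- union(a_contigs, alpha_contigs)
  n_same <- n_cross <- n_links <- n_artifact <- 0L
  if (!is.null(repeats) && nrow(repeats)) {
    same <- repeats$orientation == "inverted" &
      repeats$contigA == repeats$contigB
    cross <- repeats$contigA != repeats$contigB &
      repeats$contigA %in% locus_contigs &
      repeats$contigB %in% locus_contigs
    n_same <- sum(same)
    n_cross <- sum(cross)
    n_artifact <- sum(repeats$artifact[same | cross])
  }
  if (!is.null(links) && nrow(links)) {
    for (i in seq_len(nrow(links))) {
      nb <- strsplit(links$neighbors[i], ",")[[1]]
      if (any(nb %in% a_contigs) && any(nb %in% alpha_contigs))
        n_links <- n_links + 1L
    }
  }
  list(n = n_same + n_cross + n_links, n_same = n_same, n_cross = n_cross,
       n_links = n_links, n_artifact = n_artifact)
}

min_idiomorph_gap <- function(loci) {
  genes <- do.call(rbind, lapply(loci, `[[`, "genes"))
  a <- genes[genes$gene %in% A_GENES, , drop = FALSE]
  al <- genes[genes$gene %in% ALPHA_GENES, , drop = FALSE]
  gap <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(al))) {
    if (a$contig[i] != al$contig[j]) next
    d <- max(a$start[i], al$start[j]) - min(a$end[i], al$end[j])
    gap <- min(gap, max(0L, d))
  }
  gap
}
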