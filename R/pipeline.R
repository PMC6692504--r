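#' Annotate an assembly: search, gene calls, loci, repeats, context
#'
#' Runs the full evidence-gathering stage for one species: translated
#' homology search, gene calling, locus assembly, repeat detection around
#' loci, telomere and rDNA annotation, allelism tests for opposite-idiomorph
#' locus pairs on different contigs, and coverage-based collapsed-repeat
#' links.
#'
#' @param assembly a `mat_assembly`.
#' @param queries protein query set (default: bundled toy set).
#' @param code genetic code tag for this species.
#' @param rdna_landmark rDNA nucleotide landmark (or `NULL` to skip).
#' @param cfg configuration.
#' @return a `mat_annotation` list with `species`, `search`, `calls`,
#'   `loci`, `repeats`, `telomeres`, `rdna`, `allelism`, `links`,
#'   `fragments`, `searched`.
#' @export
annotate_assembly <- function(assembly, queries = toy_queries(),
                              code = "standard",
                              rdna_landmark = toy_rdna_landmark(),
                              cfg = default_config()) {
  search <- search_mat_genes(assembly, queries, code = code, cfg = cfg)
  calls <- call_genes(search, cfg)
  telomeres <- telomeres_of_assembly(assembly, cfg)
  rdna <- if (is.null(rdna_landmark)) NULL else
    detect_rdna(assembly, rdna_landmark, cfg)
  loci <- assemble_mat_loci(calls, assembly, telomeres, rdna, cfg)
  repeats <- find_flanking_repeats(assembly, loci, cfg)
  fragments <- fragment_cassettes(calls, loci, cfg)
  allelism <- allelism_table(assembly, loci, cfg)
  links <- if (all(is.na(assembly$coverage))) NULL else
    infer_collapsed_repeats(assembly, cfg)
  structure(list(species = assembly$species, search = search, calls = calls,
                 loci = loci, repeats = repeats, telomeres = telomeres,
                 rdna = rdna, allelism = allelism, links = links,
                 fragments = fragments, searched = TRUE),
            class = "mat_annotation")
}

allelism_table <- function(assembly, loci, cfg) {
  opp <- opposite_pairs(loci)
  rows <- list()
  for (r in seq_len(nrow(opp))) {
    i <- opp[r, 1]; j <- opp[r, 2]
    if (loci[[i]]$contig == loci[[j]]$contig) next
    al <- detect_allelism(assembly, loci[[i]], loci[[j]], cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      locusA = i, locusB = j,
      left_len = al$left_flank$width, left_ident = al$left_flank$identity,
      right_len = al$right_flank$width, right_ident = al$right_flank$identity,
      orientation = al$orientation, verdict = al$verdict)
  }
  if (!length(rows)) {
    return(data.frame(locusA = integer(), locusB = integer(),
                      left_len = integer(), left_ident = numeric(),
                      right_len = integer(), right_ident = numeric(),
                      orientation = character(), verdict = character()))
  }
  do.call(rbind, rows)
}

#' Classify an assembly end to end
#'
#' Convenience composition of [annotate_assembly()] and
#' [classify_species()].
#'
#' @inheritParams annotate_assembly
#' @return a `mating_system_call`.
#' @export
classify_assembly <- function(assembly, queries = toy_queries(),
                              code = "standard",
                              rdna_landmark = toy_rdna_landmark(),
                              cfg = default_config()) {
  classify_species(annotate_assembly(assembly, queries, code, rdna_landmark,
                                     cfg), cfg)
}

#' Run the full pipeline over a set of assemblies
#'
#' Search -> annotate -> classify each assembly, apply manual overrides,
#' and, when a tree is supplied, reconstruct ancestral systems and count
#' transitions on the override-merged state map. Overrides exist because
#' some genomes can only be classified by synteny with relatives (broken
#' assemblies); they replace the computed call and are flagged
#' `manual_override` in the evidence.
#'
#' @param assemblies directory of FASTA files, or a named list of
#'   `mat_assembly` objects.
#' @param queries protein query set.
#' @param tree optional rooted `phylo` or Newick file path.
#' @param codes named character vector species -> genetic code tag
#'   (default `standard` for all).
#' @param overrides named character vector species -> category.
#' @param policy tie-break policy for [reconstruct_states()].
#' @param tree_mismatch `"strict"` errors on tree tips without calls;
#'   `"lenient"` prunes them (logged).
#' @param outdir optional output directory for [export_results()].
#' @param rdna_landmark rDNA landmark sequence.
#' @param cfg configuration.
#' @return list with `calls`, `annotations`, `states`, `reconstruction`,
#'   `summary`.
#' @export
run_pipeline <- function(assemblies, queries = toy_queries(), tree = NULL,
                         codes = NULL, overrides = NULL,
                         policy = "default",
                         tree_mismatch = c("strict", "lenient"),
                         outdir = NULL,
                         rdna_landmark = toy_rdna_landmark(),
                         cfg = default_config()) {
  tree_mismatch <- match.arg(tree_mismatch)
  if (is.character(assemblies) && length(assemblies) == 1L) {
    files <- sort(list.files(assemblies, pattern = "\\.(fa|fasta|fna)$",
                             full.names = TRUE))
    if (!length(files)) stop("no FASTA files in ", assemblies)
    assemblies <- lapply(files, read_assembly)
    names(assemblies) <- vapply(assemblies, `[[`, "", "species")
  }
  stopifnot(length(assemblies) >= 1L, !is.null(names(assemblies)))
  annotations <- list()
  calls <- list()
  for (sp in names(assemblies)) {
    code <- if (!is.null(codes) && sp %in% names(codes)) codes[[sp]]
            else "standard"
    ann <- annotate_assembly(assemblies[[sp]], queries, code, rdna_landmark,
                             cfg)
    cl <- classify_species(ann, cfg)
    if (cl$category == "NOMAT")
      message(sp, ": no MAT genes found, proceeding as NOMAT")
    annotations[[sp]] <- ann
    calls[[sp]] <- cl
  }
  if (!is.null(overrides)) {
    bad <- setdiff(unname(overrides), MAT_SYSTEMS)
    if (length(bad)) stop("overrides outside state alphabet: ",
                          paste(bad, collapse = ", "))
    for (sp in names(overrides)) {
      prev <- if (sp %in% names(calls)) calls[[sp]]$category else "none"
      calls[[sp]] <- new_call(overrides[[sp]],
                              evidence = sprintf("manual_override(was=%s)",
                                                 prev))
      message("override: ", sp, " -> ", overrides[[sp]])
    }
  }
  states <- vapply(calls, `[[`, "", "category")
  reconstruction <- NULL
  summary <- NULL
  tree_out <- NULL
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- parse_newick(paste(readLines(tree),
                                                       collapse = ""))
    missing_states <- setdiff(tree$tip.label, names(states))
    if (length(missing_states)) {
      if (tree_mismatch == "strict")
        stop("tree tips without calls: ",
             paste(missing_states, collapse = ", "))
      message("pruning tree tips without calls: ",
              paste(missing_states, collapse = ", "))
      tree <- ape::drop.tip(tree, missing_states)
    }
    reconstruction <- reconstruct_states(tree, states, policy = policy)
    summary <- count_transitions(reconstruction)
    tree_out <- state_labelled_tree(reconstruction)
  }
  if (!is.null(outdir)) {
    export_results(calls, annotations, summary, tree_out, outdir)
  }
  list(calls = calls, annotations = annotations, states = states,
       reconstruction = reconstruction, summary = summary)
}
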