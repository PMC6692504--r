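# Packaged per-clade fixtures: subtrees with per-species mating-system
# categories, plus dataset-level clade tables (switching clades, PHN locus
# locations). Tip sets and categories are transcribed from published
# per-clade descriptions; the branching orders and any *_sp_* placeholder
# names are synthetic stand-ins consistent with the stated clade
# memberships (see inst/extdata/fixtures/README.txt).

fixture_path <- function(file) {
  p <- system.file("extdata", "fixtures", file, package = "matsys")
  if (!nzchar(p)) stop("fixture file missing: ", file)
  p
}

read_state_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$category, df$species)
}

#' Load a packaged per-clade fixture
#'
#' Available tags:
#' * `lipomyces` — 9 species (5 PHC, 3 PHN, 1 HET);
#' * `ogataea` — 21 species of the Ogataea genus clade, with three
#'   separate FF1 clades (one of 12 species);
#' * `saccharomycetaceae` — 71 species, 66 of them 3LOC;
#' * `saturnispora` — 7 species (4 FF2, 3 HET);
#' * `phn_clades` — table of the 12 PHN clades with the genomic location
#'   of the second MAT locus (no tree);
#' * `full` — not packaged: the complete 332-species state map must be
#'   supplied by the user (`full_states_tsv`, `full_tree_nwk`), since only
#'   the per-clade subsets are transcribable from the published text.
#'
#' @param name fixture tag.
#' @param full_tree_nwk,full_states_tsv user-supplied files for `"full"`.
#' @return list with `tree` (`phylo` or `NULL`), `states` (named character
#'   or `NULL`), and for `phn_clades` a `table` data.frame.
#' @export
paper_fixtures <- function(name, full_tree_nwk = NULL,
                           full_states_tsv = NULL) {
  tags <- c("lipomyces", "ogataea", "saccharomycetaceae", "saturnispora",
            "phn_clades", "full")
  if (!name %in% tags)
    stop("unknown fixture tag '", name, "'; valid tags: ",
         paste(tags, collapse = ", "))
  if (name == "full") {
    if (is.null(full_tree_nwk) || is.null(full_states_tsv))
      stop("the 'full' 332-species fixture is not packaged: supply your ",
           "own transcription via full_tree_nwk and full_states_tsv")
    tree <- parse_newick(paste(readLines(full_tree_nwk), collapse = ""))
    return(list(tree = tree, states = read_state_tsv(full_states_tsv)))
  }
  if (name == "phn_clades") {
    tbl <- utils::read.table(fixture_path("phn_clades.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    return(list(tree = NULL, states = NULL, table = tbl))
  }
  tree <- parse_newick(paste(readLines(
    fixture_path(paste0(name, "_tree_synthetic.nwk"))), collapse = ""))
  states <- read_state_tsv(fixture_path(paste0(name, "_states.tsv")))
  stopifnot(setequal(tree$tip.label, names(states)))
  list(tree = tree, states = states)
}

#' Dataset-level table of mating-type switching clades
#'
#' One row per independent clade with a switching system (FF1, FF2 or
#' 3LOC), with its size and whether its assignment is provisional.
#'
#' @return data.frame with columns `clade`, `system`, `n_species`,
#'   `provisional`, `major_clade`.
#' @export
switching_clade_table <- function() {
  utils::read.table(fixture_path("switching_clades.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Counts of switching-system origins from the clade table
#'
#' @param table from [switching_clade_table()].
#' @param include_provisional count provisionally assigned clades too.
#' @return list with `ff1_clades`, `ff2_clades`, `threeloc_clades`,
#'   `to_secondary_homothallism` (total origins of switching systems) and
#'   `switching_origins`.
#' @export
switching_clade_counts <- function(table = switching_clade_table(),
                                   include_provisional = TRUE) {
  t <- if (include_provisional) table else
    table[!table$provisional, , drop = FALSE]
  list(ff1_clades = sum(t$system == "FF1"),
       ff2_clades = sum(t$system == "FF2"),
       threeloc_clades = sum(t$system == "3LOC"),
       to_secondary_homothallism = nrow(t),
       switching_origins = nrow(t))
}

#' Location filter counts over the PHN clades
#'
#' Two dataset-level filters over the clades with non-contiguous primary
#' homothallism: how many involved gain of DNA carrying the opposite MAT
#' allele at a site near a telomere, and how many have a second MAT locus
#' associated with neither a telomere nor the rDNA.
#'
#' @param table from `paper_fixtures("phn_clades")$table`.
#' @return list with `n_clades`, `telomeric_gains`,
#'   `non_telomere_non_rdna`, `rdna_associated`.
#' @export
phn_location_counts <- function(table = paper_fixtures("phn_clades")$table) {
  list(n_clades = nrow(table),
       telomeric_gains = sum(table$second_locus_location == "telomere"),
       non_telomere_non_rdna = sum(table$second_locus_location == "none"),
       rdna_associated = sum(table$second_locus_location == "rdna"))
}
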