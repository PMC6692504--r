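# Shared helpers: constructed evidence objects and an exhaustive parsimony
# oracle used to cross-check the dynamic-programming reconstruction.

# Minimum change count by enumerating every assignment of internal-node
# states. Under a unit cost matrix, states absent from the tips can never
# reduce the change count (replacing an unobserved internal state by any
# observed one changes each incident edge cost by at most 0), so the
# enumeration runs over the observed state set only.
brute_force_min_changes <- function(tree, states) {
  obs <- unique(unname(states[tree$tip.label]))
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  combos <- rep(list(obs), n_int)
  grid <- do.call(expand.grid, c(combos, stringsAsFactors = FALSE))
  e <- tree$edge
  tip_state <- states[tree$tip.label]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(unname(tip_state), as.character(grid[r, ]))
    ch <- sum(lab[e[, 1]] != lab[e[, 2]])
    if (ch < best) best <- ch
  }
  best
}

random_instance <- function(n_tips, n_states = 3, seed = 1) {
  set.seed(seed)
  tree <- ape::rtree(n_tips)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  pool <- sample(MAT_SYSTEMS, n_states)
  states <- stats::setNames(sample(pool, n_tips, replace = TRUE),
                            tree$tip.label)
  list(tree = tree, states = states)
}

# A bare-bones locus object for classifier-level tests (no assembly needed)
make_locus <- function(contig, start, end, idiomorph,
                       genes = NULL) {
  if (is.null(genes)) {
    gn <- switch(idiomorph,
                 a = c("MATa1", "MATa2"),
                 alpha = c("MATalpha1", "MATalpha2"),
                 both = c("MATa1", "MATa2", "MATalpha1", "MATalpha2"))
    w <- (end - start - 20 * (length(gn) - 1)) %/% length(gn)
    genes <- data.frame(gene = gn, family = "mat_core", contig = contig,
                        start = start + (seq_along(gn) - 1) * (w + 20),
                        end = start + (seq_along(gn) - 1) * (w + 20) + w,
                        strand = "+", status = "intact", query_cover = 1,
                        n_internal_stops = 0L, bit_score = 200)
  }
  structure(list(contig = contig, start = start, end = end,
                 idiomorph = idiomorph, genes = genes,
                 neighbors = stats::setNames(integer(), character()),
                 contig_end_distance = start, telomere_proximal = FALSE,
                 rdna_proximal = FALSE),
            class = "mat_locus")
}

make_annotation <- function(loci, repeats = NULL, allelism = NULL,
                            links = NULL, fragments = NULL,
                            searched = TRUE) {
  list(loci = loci, repeats = repeats, allelism = allelism, links = links,
       fragments = fragments, searched = searched)
}

make_repeat_pair <- function(contigA, startA, endA, contigB, startB, endB,
                             identity = 97, orientation = "inverted",
                             role = "IR", reachesA = FALSE,
                             reachesB = FALSE) {
  df <- data.frame(contigA = contigA, startA = startA, endA = endA,
                   contigB = contigB, startB = startB, endB = endB,
                   length = endA - startA, identity = identity,
                   orientation = orientation, role = role,
                   reachesA = reachesA, reachesB = reachesB)
  df$artifact <- vapply(seq_len(nrow(df)), function(i)
    flag_assembly_artifact(df[i, ]), TRUE)
  df
}
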