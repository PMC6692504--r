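# Synthetic genomes with planted MAT configurations, an assembler-collapse
# emulator, and planted transition histories on trees. Everything is seeded
# and reproducible; truth annotations list every planted feature so the
# detectors can be scored against ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random background DNA at a given GC content
#'
#' @param n length in bp.
#' @param gc GC fraction (default 0.40, typical for yeast genomes).
#' @return a string. Uses the current RNG state (seed it at a higher level).
#' @export
random_dna <- function(n, gc = 0.40) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one fixed codon per amino acid; TTA (not CTG) for Leu so planted genes
# translate identically under all three genetic code tags
REV_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "TTA",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "AGA",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(protein) {
  paste0(paste(REV_CODON[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

mutate_dna <- function(seq, identity) {
  if (identity >= 100) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) > identity / 100)
  alt <- c(A = "G", C = "T", G = "A", T = "C", N = "N")
  v[hit] <- alt[v[hit]]
  paste(v, collapse = "")
}

#' Specification of a planted genome
#'
#' Validates parameter consistency with the requested category before any
#' generation happens (e.g. a flip/flop spec whose IR is shorter than the
#' repeat detector's minimum length, or a PHC spec whose cassette gap is
#' not below the contiguity bound, is rejected).
#'
#' @param category one of [MAT_SYSTEMS].
#' @param seed integer seed; the same spec and seed give a byte-identical
#'   genome and truth annotation.
#' @param ir_len IR copy length (FF1/FF2), bp.
#' @param ir_identity percent identity between IR copies.
#' @param inner_ir_len inner IR copy length (FF2), bp.
#' @param locus_gap a-to-alpha cassette gap for PHC, bp.
#' @param inner_span invertible span between the cassettes (FF1/FF2), bp.
#' @param xz_len X/Z direct-repeat length (3LOC), bp.
#' @param telomere_unit telomeric repeat unit planted in PHN genomes.
#' @param plant_rdna plant the second PHN locus beside an rDNA unit instead
#'   of a telomere.
#' @param coverage_mean per-contig x-fold coverage.
#' @param het_idiomorph idiomorph for HET genomes.
#' @return a `planted_genome_spec` list.
#' @export
planted_genome_spec <- function(category, seed = 1L, ir_len = 2000,
                                ir_identity = 97, inner_ir_len = 1500,
                                locus_gap = 5000, inner_span = 12000,
                                xz_len = 300,
                                telomere_unit = "TTTTAGTAGGG",
                                plant_rdna = FALSE, coverage_mean = 50,
                                het_idiomorph = "a") {
  stopifnot(category %in% MAT_SYSTEMS)
  cfg <- default_config()
  if (category %in% c("FF1", "FF2")) {
    if (ir_len < cfg$min_repeat_len)
      stop("inconsistent spec: ir_len below detectable repeat length")
    if (ir_identity < cfg$min_repeat_identity)
      stop("inconsistent spec: ir_identity below detectable repeat identity")
  }
  if (category == "FF2" && inner_ir_len < cfg$min_repeat_len)
    stop("inconsistent spec: inner_ir_len below detectable repeat length")
  if (category == "PHC" && locus_gap >= cfg$phc_max_gap)
    stop("inconsistent spec: PHC requires locus_gap < ", cfg$phc_max_gap)
  if (category == "3LOC" && xz_len < cfg$min_repeat_len)
    stop("inconsistent spec: xz_len below detectable repeat length")
  structure(list(category = category, seed = seed, ir_len = ir_len,
                 ir_identity = ir_identity, inner_ir_len = inner_ir_len,
                 locus_gap = locus_gap, inner_span = inner_span,
                 xz_len = xz_len, telomere_unit = telomere_unit,
                 plant_rdna = plant_rdna, coverage_mean = coverage_mean,
                 het_idiomorph = het_idiomorph),
            class = "planted_genome_spec")
}

# sequential contig builder tracking planted-feature coordinates
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character(); env$features <- list(); env$pos <- 0L
  env
}

badd <- function(b, seq, type = NA, name = NA) {
  n <- nchar(seq)
  start <- b$pos
  b$parts[[length(b$parts) + 1L]] <- seq
  b$pos <- b$pos + n
  if (!is.na(type)) {
    b$features[[length(b$features) + 1L]] <-
      data.frame(type = type, name = name, start = start, end = b$pos)
  }
  invisible(c(start = start, end = b$pos))
}

bseq <- function(b) paste(b$parts, collapse = "")

bfeat <- function(b, contig) {
  if (!length(b$features)) {
    return(data.frame(contig = character(), type = character(),
                      name = character(), start = integer(),
                      end = integer()))
  }
  df <- do.call(rbind, b$features)
  df$contig <- contig
  df[, c("contig", "type", "name", "start", "end")]
}

gene_dna <- function(symbol) {
  reverse_translate(get(paste0("TOY_", toupper(symbol)),
                        envir = asNamespace("matsys")))
}

add_cassette <- function(b, idio) {
  genes <- if (idio == "a") c("MATa1", "MATa2") else
    c("MATalpha1", "MATalpha2")
  s0 <- b$pos
  badd(b, gene_dna(genes[1]), "gene", genes[1])
  badd(b, random_dna(20))
  badd(b, gene_dna(genes[2]), "gene", genes[2])
  b$features[[length(b$features) + 1L]] <-
    data.frame(type = "cassette", name = idio, start = s0, end = b$pos)
  invisible(c(start = s0, end = b$pos))
}

#' Generate a genome assembly with a planted MAT configuration
#'
#' Builds a seeded random-background assembly (40% GC) carrying the MAT
#' architecture of the requested category, using the bundled toy stand-in
#' sequences for the MAT and neighbor genes:
#'
#' * `HET` — one cassette of a single idiomorph in the ancestral
#'   SLA2-MAT-DIC1 context;
#' * `3LOC` — three cassettes (one a-type active locus, silent alpha- and
#'   a-type cassettes) each flanked by shared X and Z direct repeats;
#' * `FF1` — one IR family whose copies bound an invertible span with the a-
#'   and alpha-cassettes just inside the IRs;
#' * `FF2` — an outer IR family plus a nested inner family around the span
#'   between the cassettes;
#' * `PHC` — a- and alpha-cassettes `locus_gap` apart in one ancestral
#'   context, no repeats;
#' * `PHN` — alpha-cassette at the ancestral locus; a-cassette on a second
#'   contig beside a heavily degraded SLA2 pseudogene, near a planted
#'   telomeric tandem array (or an rDNA unit when `plant_rdna`);
#' * `NOMAT` — neighbor genes only, no MAT genes.
#'
#' @param spec a `planted_genome_spec` (or a category string, convenience).
#' @param seed overrides `spec$seed` when not `NULL`.
#' @return list with `assembly` (a `mat_assembly`), `truth` (category,
#'   feature table, IR family coordinates, collapse expectations), and
#'   `spec`.
#' @export
generate_genome <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- planted_genome_spec(spec)
  stopifnot(inherits(spec, "planted_genome_spec"))
  if (!is.null(seed)) spec$seed <- seed
  with_seed(spec$seed, {
    contigs <- list(); feats <- list(); ir_families <- list()
    b <- new_builder()
    if (spec$category == "HET") {
      badd(b, random_dna(4000))
      badd(b, gene_dna("SLA2"), "gene", "SLA2")
      badd(b, random_dna(300))
      add_cassette(b, spec$het_idiomorph)
      badd(b, random_dna(300))
      badd(b, gene_dna("DIC1"), "gene", "DIC1")
      badd(b, random_dna(4000))
      contigs$c1 <- b
    } else if (spec$category == "NOMAT") {
      badd(b, random_dna(3000))
      badd(b, gene_dna("SLA2"), "gene", "SLA2")
      badd(b, random_dna(300))
      badd(b, gene_dna("DIC1"), "gene", "DIC1")
      badd(b, random_dna(6000))
      contigs$c1 <- b
    } else if (spec$category == "PHC") {
      badd(b, random_dna(4000))
      badd(b, gene_dna("SLA2"), "gene", "SLA2")
      badd(b, random_dna(300))
      add_cassette(b, "a")
      badd(b, random_dna(spec$locus_gap))
      add_cassette(b, "alpha")
      badd(b, random_dna(300))
      badd(b, gene_dna("DIC1"), "gene", "DIC1")
      badd(b, random_dna(4000))
      contigs$c1 <- b
    } else if (spec$category == "PHN") {
      badd(b, random_dna(4000))
      badd(b, gene_dna("SLA2"), "gene", "SLA2")
      badd(b, random_dna(300))
      add_cassette(b, "alpha")
      badd(b, random_dna(300))
      badd(b, gene_dna("DIC1"), "gene", "DIC1")
      badd(b, random_dna(4000))
      contigs$c1 <- b
      b2 <- new_builder()
      badd(b2, random_dna(1500))
      # badly degraded SLA2 pseudogene: 5' half, heavily mutated
      sla2 <- gene_dna("SLA2")
      badd(b2, mutate_dna(substr(sla2, 1, nchar(sla2) %/% 2), 70),
           "pseudogene", "SLA2_pseudo")
      badd(b2, random_dna(200))
      add_cassette(b2, "a")
      if (spec$plant_rdna) {
        badd(b2, random_dna(500))
        badd(b2, TOY_RDNA, "rdna", "rDNA")
        badd(b2, random_dna(1500))
      } else {
        badd(b2, random_dna(1000))
        badd(b2, strrep(spec$telomere_unit, 8), "telomere", "telomere")
        badd(b2, random_dna(30))
      }
      contigs$c2 <- b2
    } else if (spec$category == "FF1") {
      ira <- random_dna(spec$ir_len)
      badd(b, random_dna(3000))
      sA <- badd(b, ira, "ir_copy", "IR_A")
      badd(b, random_dna(200))
      badd(b, gene_dna("SLA2"), "gene", "SLA2")
      badd(b, random_dna(100))
      add_cassette(b, "a")
      badd(b, random_dna(spec$inner_span))
      add_cassette(b, "alpha")
      badd(b, random_dna(100))
      badd(b, gene_dna("DIC1"), "gene", "DIC1")
      badd(b, random_dna(200))
      sB <- badd(b, rc_string(mutate_dna(ira, spec$ir_identity)),
                 "ir_copy", "IR_B")
      badd(b, random_dna(3000))
      contigs$c1 <- b
      ir_families$outer <- list(contig = "c1", copyA = sA, copyB = sB,
                                orientation = "inverted")
    } else if (spec$category == "FF2") {
      outa <- random_dna(spec$ir_len)
      ina <- random_dna(spec$inner_ir_len)
      badd(b, random_dna(3000))
      oA <- badd(b, outa, "ir_copy", "OUT_A")
      badd(b, random_dna(150))
      add_cassette(b, "a")
      badd(b, random_dna(150))
      iA <- badd(b, ina, "ir_copy", "IN_A")
      badd(b, random_dna(spec$inner_span))
      iB <- badd(b, rc_string(mutate_dna(ina, spec$ir_identity)),
                 "ir_copy", "IN_B")
      badd(b, random_dna(150))
      add_cassette(b, "alpha")
      badd(b, random_dna(150))
      oB <- badd(b, rc_string(mutate_dna(outa, spec$ir_identity)),
                 "ir_copy", "OUT_B")
      badd(b, random_dna(3000))
      contigs$c1 <- b
      ir_families$outer <- list(contig = "c1", copyA = oA, copyB = oB,
                                orientation = "inverted")
      ir_families$inner <- list(contig = "c1", copyA = iA, copyB = iB,
                                orientation = "inverted")
    } else if (spec$category == "3LOC") {
      zrep <- random_dna(spec$xz_len)
      xrep <- random_dna(spec$xz_len)
      badd(b, random_dna(2500))
      for (cass in list(c("alpha", "HML"), c("a", "MAT"), c("a", "HMR"))) {
        badd(b, zrep, "xz_copy", paste0("Z_", cass[2]))
        add_cassette(b, cass[1])
        badd(b, xrep, "xz_copy", paste0("X_", cass[2]))
        if (cass[2] != "HMR") badd(b, random_dna(12000))
      }
      badd(b, random_dna(2500))
      contigs$c1 <- b
    }
    seqs <- vapply(contigs, bseq, "")
    feats <- do.call(rbind, Map(bfeat, contigs, names(contigs)))
    coverage <- stats::setNames(rep(spec$coverage_mean, length(seqs)),
                                names(seqs))
    assembly <- new_assembly(paste0("sim_", spec$category, "_s", spec$seed),
                             seqs, coverage)
    list(assembly = assembly,
         truth = list(category = spec$category, features = feats,
                      ir_families = ir_families,
                      coverage_mean = spec$coverage_mean),
         spec = spec)
  })
}

#' Emulate how a short-read assembler collapses a two-copy repeat
#'
#' Replaces the two copies of one planted IR family by a single contig at
#' twice the baseline coverage, with exact `k`-base end overlaps shared
#' with the contigs flanking each copy (the junction contigs are split
#' between the cassettes, mirroring assemblies in which the repeat contig
#' overlaps one MATa-bearing and one MATalpha-bearing contig). Genomes with
#' no planted IR family are returned unchanged with a warning.
#'
#' @param genome result of [generate_genome()].
#' @param k overlap length in bp (the assembler's longest k-mer).
#' @param family which planted family to collapse (`"inner"` is used for
#'   FF2 genomes when present, else the first family).
#' @return a genome list like [generate_genome()]'s, with the fragmented
#'   assembly, 2x coverage on the repeat contig, and
#'   `truth$expected_link` describing the planted link.
#' @export
emulate_assembler_collapse <- function(genome, k = 55, family = NULL) {
  fams <- genome$truth$ir_families
  if (!length(fams)) {
    warning("no planted IR family; assembly returned unchanged")
    return(genome)
  }
  fam_name <- family %||% if ("inner" %in% names(fams)) "inner" else
    names(fams)[1]
  fam <- fams[[fam_name]]
  seqchr <- as.character(genome$assembly$contigs[[fam$contig]])
  s1 <- fam$copyA[["start"]]; e1 <- fam$copyA[["end"]]
  s2 <- fam$copyB[["start"]]; e2 <- fam$copyB[["end"]]
  L <- nchar(seqchr)
  M <- substr(seqchr, s1 + 1L, e1)
  ms <- substr(M, 1L, k); me <- substr(M, nchar(M) - k + 1L, nchar(M))
  # split the inter-copy region between the two cassettes when both lie
  # inside it, else at its midpoint
  feats <- genome$truth$features
  cass <- feats[feats$type == "cassette" & feats$contig == fam$contig, ,
                drop = FALSE]
  inside <- cass[cass$start >= e1 & cass$end <= s2, , drop = FALSE]
  m <- if (nrow(inside) >= 2L) {
    inside <- inside[order(inside$start), ]
    (inside$end[1] + inside$start[2]) %/% 2L
  } else (e1 + s2) %/% 2L
  base <- genome$truth$coverage_mean
  seqs <- c(cL = paste0(substr(seqchr, 1L, s1), ms),
            cM = M,
            cI1 = paste0(me, substr(seqchr, e1 + 1L, m)),
            cI2 = paste0(substr(seqchr, m + 1L, s2), rc_string(me)),
            cR = paste0(rc_string(ms), substr(seqchr, e2 + 1L, L)))
  cov <- c(cL = base, cM = 2 * base, cI1 = base, cI2 = base, cR = base)
  # carry over any other contigs unchanged
  others <- setdiff(names(genome$assembly$contigs), fam$contig)
  if (length(others)) {
    seqs <- c(seqs, as.character(genome$assembly$contigs[others]))
    cov <- c(cov, genome$assembly$coverage[others])
  }
  assembly <- new_assembly(genome$assembly$species, seqs, cov)
  truth <- genome$truth
  truth$expected_link <- list(repeat_contig = "cM",
                              neighbors = c("cI1", "cI2", "cL", "cR"),
                              overlap_len = k, family = fam_name)
  truth$collapsed <- TRUE
  # feature coordinates are no longer valid on the fragmented assembly
  truth$features <- NULL
  list(assembly = assembly, truth = truth, spec = genome$spec)
}

#' Simulate a transition history on a tree
#'
#' Propagates a root state down the tree, applying either a fixed list of
#' planted events (branch, new state) or independent per-branch changes
#' with probability `p_change`. With `consistent = TRUE`, random histories
#' are rejection-sampled until the planted change count equals the
#' parsimony minimum of the resulting tip states, so transition counting
#' can be scored exactly against the plant.
#'
#' @param tree rooted `phylo`.
#' @param root_state category at the root.
#' @param events data.frame with columns `child` (tip label or node id
#'   identifying the branch above it) and `to` (new state), or `NULL`.
#' @param p_change per-branch change probability (used when `events` is
#'   `NULL`).
#' @param seed integer seed.
#' @param consistent require parsimony consistency (see above).
#' @param max_tries rejection-sampling cap.
#' @return a `planted_history`: list with `tree`, `root_state`, `events`
#'   (parent, child, from, to), `tip_states`, `seed`.
#' @export
simulate_history <- function(tree, root_state, events = NULL,
                             p_change = NULL, seed = 1L, consistent = TRUE,
                             max_tries = 200L) {
  stopifnot(root_state %in% MAT_SYSTEMS)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  resolve_node <- function(x) {
    if (is.character(x)) {
      i <- match(x, tree$tip.label)
      if (!is.na(i)) return(i)
      if (grepl("^[0-9]+$", x)) x <- as.numeric(x)   # node id as string
      else stop("event on nonexistent branch: ", x)
    }
    {
      if (x < 1L || x > n_all || x == root_node(tree))
        stop("event on nonexistent branch: ", x)
      as.integer(x)
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  preorder_edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  propagate <- function(change_to) {
    st <- character(n_all)
    st[root_node(tree)] <- root_state
    for (e in seq_len(nrow(preorder_edges))) {
      p <- preorder_edges[e, 1]; ch <- preorder_edges[e, 2]
      st[ch] <- if (!is.na(change_to[ch])) change_to[ch] else st[p]
    }
    st
  }
  one_draw <- function() {
    change_to <- rep(NA_character_, n_all)
    if (!is.null(events)) {
      for (i in seq_len(nrow(events)))
        change_to[resolve_node(events$child[i])] <- events$to[i]
    } else if (!is.null(p_change)) {
      hit <- stats::runif(nrow(preorder_edges)) < p_change
      for (e in which(hit)) {
        ch <- preorder_edges[e, 2]
        change_to[ch] <- sample(MAT_SYSTEMS, 1L)
      }
    }
    change_to
  }
  with_seed(seed, {
    for (try in seq_len(if (is.null(events)) max_tries else 1L)) {
      change_to <- one_draw()
      st <- propagate(change_to)
      ev <- edge_events(tree, st)
      ev <- ev[ev$from != ev$to, , drop = FALSE]
      tip_states <- stats::setNames(st[seq_len(n_tip)], tree$tip.label)
      if (!consistent) break
      min_ch <- min(sankoff_up(tree, tip_states, uniform_cost())[
        root_node(tree), ])
      if (nrow(ev) == min_ch) break
      if (!is.null(events))
        stop("planted events are not parsimony-consistent (planted ",
             nrow(ev), ", minimum ", min_ch, ")")
      if (try == max_tries)
        stop("no parsimony-consistent history found in ", max_tries,
             " tries")
    }
    structure(list(tree = tree, root_state = root_state, events = ev,
                   tip_states = tip_states, seed = seed),
              class = "planted_history")
  })
}

#' Write an assembly to FASTA
#'
#' @param assembly a `mat_assembly`.
#' @param path output file.
#' @param dialect `"spades"` writes `NODE_<i>_length_<L>_cov_<c>` headers
#'   carrying the coverage; `"plain"` writes bare contig ids.
#' @export
write_assembly_fasta <- function(assembly, path,
                                 dialect = c("plain", "spades")) {
  dialect <- match.arg(dialect)
  x <- assembly$contigs
  if (dialect == "spades") {
    cov <- ifelse(is.na(assembly$coverage), 0, assembly$coverage)
    names(x) <- sprintf("NODE_%d_length_%d_cov_%s", seq_along(x),
                        Biostrings::width(x), format(cov, trim = TRUE))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
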