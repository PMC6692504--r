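#' Default thresholds for annotation and classification
#'
#' Returns the threshold configuration consumed by the annotation and
#' classification stages. All distances are in base pairs on the forward
#' strand; identities are percentages; coverage ratios are relative to the
#' length-weighted median contig coverage of the assembly.
#'
#' The defaults encode the decision rules of the classification scheme:
#' `e_max = 10` keeps even very weak translated-search hits, and
#' `phc_max_gap = 20000` is the contiguity bound separating PHC from PHN.
#' The remaining values are method parameters chosen to bracket the repeat
#' and telomere structures seen in real yeast MAT regions: the known
#' MAT-flanking repeats range from ~200 bp at 100% identity to multi-kilobase
#' IRs at ~97%, telomeric units from 8 to 11 bp, and assembler-collapsed
#' repeat contigs sit near twice the median coverage with k-mer-length end
#' overlaps.
#'
#' @param ... named overrides for individual thresholds.
#' @return A named list with class `mat_config`.
#' @examples
#' cfg <- default_config(phc_max_gap = 15000)
#' cfg$phc_max_gap
#' @export
default_config <- function(...) {
  cfg <- list(
    # translated homology search
    e_max              = 10,      # E-value cutoff for retaining hits
    blosum_gap_open    = 11,
    blosum_gap_extend  = 1,
    ka_K               = 0.041,   # Karlin-Altschul K (gapped BLOSUM62 defaults)
    ka_lambda          = 0.267,   # Karlin-Altschul lambda
    region_join_window = 2000,    # bp; distinct MAT hits within this join a candidate region
    max_chain_gap      = 1500,    # bp; split HSPs of one gene chained within this gap
    max_hits_per_frame = 6,       # iterative masked re-search depth per query/frame
    # gene calling and locus assembly
    intact_min_cover   = 0.80,    # fraction of query length
    max_locus_gap      = 10000,   # bp; intact MAT genes within this form one locus
    # gates for counting a non-intact MAT call as a degenerate cassette
    # (real cassette fragments are strong partial alignments; the E<10
    # retention rule also keeps spurious weak hits that must not count)
    fragment_min_cover = 0.20,
    fragment_min_bits  = 50,
    # repeat detection
    min_repeat_len      = 200,    # bp
    min_repeat_identity = 90,     # percent
    repeat_window       = 50000,  # bp around each locus
    repeat_seed_k       = 12,     # seed k-mer length
    repeat_merge_gap    = 500,    # bp; merge fragmented segments of one family
    end_margin          = 10,     # bp; a copy within this of a contig end "reaches" it
    # telomeres
    telomere_unit_min   = 5,
    telomere_unit_max   = 30,
    telomere_min_copies = 3,
    telomere_end_window = 2000,   # bp from a contig end
    # context flags
    rdna_window         = 20000,  # bp; locus within this of an rDNA hit
    telomere_proximal_window = 20000, # bp; locus within this of a telomeric end
    # allelism (diploid assemblies)
    flank_len           = 500,    # bp per side
    flank_min_identity  = 95,     # percent
    # collapsed-repeat inference from coverage
    cov_lo              = 1.6,    # ratio to length-weighted median coverage
    cov_hi              = 2.6,
    spades_k            = 55,     # bp; expected exact end-overlap length
    # assembler-artifact diagnosis (very long near-identical IRs to contig ends)
    artifact_min_len       = 50000, # bp
    artifact_max_mismatch  = 3,
    # classification
    phc_max_gap         = 20000   # bp; MATa-MATalpha gap below this is PHC
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$phc_max_gap > 0, cfg$e_max > 0, cfg$min_repeat_len > 0)
  structure(cfg, class = "mat_config")
}

#' Read / write a threshold configuration as YAML
#'
#' Unknown fields in the file are rejected; missing fields take defaults.
#'
#' @param path YAML file path.
#' @rdname config_yaml
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' @param cfg a `mat_config` list.
#' @rdname config_yaml
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
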