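#' Smith-Waterman local alignment of two peptides
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] (type `"local"`)
#' returning the optimal local score and the spans on query and target that
#' achieve it. An empty query or target yields score 0 with empty spans.
#'
#' @param q,t peptide strings.
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalties.
#' @return list with `raw_score`, `q_start`, `q_end`, `t_start`, `t_end`
#'   (1-based residue coordinates, inclusive; 0/-1 style empty spans when
#'   score is 0) and `n_identities`.
#' @export
local_align <- function(q, t, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  if (!nzchar(q) || !nzchar(t)) {
    return(list(raw_score = 0, q_start = 0L, q_end = -1L,
                t_start = 0L, t_end = -1L, n_identities = 0L))
  }
  if (is.character(matrix)) {
    matrix <- get(data(list = matrix, package = "Biostrings",
                       envir = environment()))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(raw_score = 0, q_start = 0L, q_end = -1L,
                t_start = 0L, t_end = -1L, n_identities = 0L))
  }
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  list(raw_score = sc,
       q_start = Biostrings::start(pr), q_end = Biostrings::end(pr),
       t_start = Biostrings::start(sr), t_end = Biostrings::end(sr),
       n_identities = Biostrings::nmatch(aln))
}

#' Karlin-Altschul expected number of hits at a score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected count of distinct local
#' alignments scoring at least `S` between a length-`m` query and a
#' length-`n` search space. The default constants are common gapped BLOSUM62
#' values, which makes an `E < 10` retention rule directly applicable to the
#' built-in translated search.
#'
#' @param raw_score alignment raw score `S`.
#' @param m query length (residues).
#' @param n search-space length (residues; for a six-frame translated search
#'   use 6x the assembly length / 3... i.e. twice the assembly length in
#'   codons; callers pass the value they mean).
#' @param K,lambda Karlin-Altschul constants.
#' @return the E-value (nonnegative; strictly decreasing in `raw_score`,
#'   linear in `m` and `n`).
#' @export
estimate_evalue <- function(raw_score, m, n, K = 0.041, lambda = 0.267) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  K * m * n * exp(-lambda * raw_score)
}

#' Normalized (bit) score for a raw alignment score
#' @inheritParams estimate_evalue
#' @export
bit_score <- function(raw_score, K = 0.041, lambda = 0.267) {
  (lambda * raw_score - log(K)) / log(2)
}
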