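#' Genetic code table for a code tag
#'
#' `standard` is the universal nuclear code; `cug_ser` and `cug_ala`
#' translate the CTG codon as serine or alanine respectively, as in the
#' corresponding yeast clades.
#'
#' @param code one of `"standard"`, `"cug_ser"`, `"cug_ala"`.
#' @return named character vector usable as `genetic.code` in
#'   [Biostrings::translate()].
#' @export
genetic_code_table <- function(code = c("standard", "cug_ser", "cug_ala")) {
  code <- match.arg(code)
  gc <- Biostrings::GENETIC_CODE
  if (code == "cug_ser") gc[["CTG"]] <- "S"
  if (code == "cug_ala") gc[["CTG"]] <- "A"
  gc
}

#' Six-frame translation with coordinate maps
#'
#' Translates a DNA sequence in frames +0, +1, +2 of the forward strand and
#' -0, -1, -2 of the reverse complement. Stop codons are rendered as `*`;
#' codons containing `N` become `X`. Each frame carries the bookkeeping
#' needed to invert peptide coordinates exactly to genomic spans (0-based
#' half-open, forward strand) via [frame_to_genomic()].
#'
#' @param seq DNA as a string or `DNAString`.
#' @param code genetic code tag, see [genetic_code_table()].
#' @return list of six frames, each a list with `strand` (`"+"`/`"-"`),
#'   `frame` (0, 1, 2), `peptide` (string), and `seq_len`.
#' @examples
#' fr <- six_frame_translate("ATGGCC")
#' fr[[1]]$peptide  # "MA"
#' @export
six_frame_translate <- function(seq, code = "standard") {
  dna <- if (methods::is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  L <- length(dna)
  if (L < 3L) stop("sequence shorter than one codon")
  gc <- genetic_code_table(code)
  rc <- Biostrings::reverseComplement(dna)
  one <- function(strand, f, s) {
    n_codon <- (length(s) - f) %/% 3L
    pep <- if (n_codon < 1L) "" else
      as.character(Biostrings::translate(
        Biostrings::subseq(s, start = f + 1L, width = 3L * n_codon),
        genetic.code = gc, if.fuzzy.codon = "X", no.init.codon = TRUE))
    list(strand = strand, frame = f, peptide = pep, seq_len = L)
  }
  c(lapply(0:2, function(f) one("+", f, dna)),
    lapply(0:2, function(f) one("-", f, rc)))
}

#' Map a peptide interval of one frame back to a genomic span
#'
#' Residues `i1..i2` (1-based, inclusive, in the frame's peptide) map to a
#' 0-based half-open interval on the forward strand of the original
#' sequence. The map is exact: re-translating the returned span in the same
#' frame reproduces the peptide interval.
#'
#' @param frame one element of [six_frame_translate()] output.
#' @param i1,i2 first and last residue (1-based) of the peptide interval.
#' @return list with `start` and `end` (0-based half-open, forward strand).
#' @export
frame_to_genomic <- function(frame, i1, i2) {
  stopifnot(i1 >= 1L, i2 >= i1)
  f <- frame$frame; L <- frame$seq_len
  if (frame$strand == "+") {
    list(start = f + 3L * (i1 - 1L), end = f + 3L * i2)
  } else {
    list(start = L - f - 3L * i2, end = L - f - 3L * (i1 - 1L))
  }
}
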