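# Fixed toy stand-in sequences for the MAT core genes, neighbor/landmark
# genes, and an rDNA nucleotide landmark. These are arbitrary protein
# sequences (mutually < 10% identical, so cross-hits between queries cannot
# confound classification tests), generated once with a fixed RNG and frozen
# here. They are NOT real MAT proteins: real analyses must supply their own
# query sets. Synthetic genomes plant reverse-translated copies of these so
# that every stage of the pipeline is testable without any download.

TOY_MATA1 <- "MVFYIDDVVHYTPSQCFKAHIWQYTFGWMSLAEPPRQRTTRDLYCQVYSMDRSDAPKGFYIYKFSPEHAKMKMETDGIKNALPQEYAVWGHSFNMKDQEQWDVPMDLKNSIFEYTWMDGC"
TOY_MATA2 <- "MCDLFIAAMAILDYDGNWCMEEKMIVWKQIFTESIMSISVEVHVSFFLVHGAAGYTSMVRACPDHYMRHPVAYIFGNNSRYPEMLRCGHMHISNCNFYKCEHYEGHKNKKMRRTCDRCSC"
TOY_MATALPHA1 <- "MRHKHWISTKMWTHSAKRICRQNRYPRDENRNEPWFVVWYQGANWVESVEMGAFESMLEVFASVHWQNDNFYREDIQHPQEEGEWTYSWCRADPETVECCLTLMFSTERMASWKYKCQDE"
TOY_MATALPHA2 <- "MVVEHTMECWGAMRAIYVPTQSFYCLNEAKLTWCPMTMNQILGYGSWDRAWTKWFDIGYRLFIFSQVAHVEKPLCSEIHVTQIWIDEPRLSEVPWQRIYEGCKTHNVLLFTRDQFYFFVI"
TOY_SLA2 <- "MENWTWYDDQVEMAVRMLMTVVCAQSVTRNYIFVLPQVCVADGQPVVYNFRRLNHCGNWDIAAPTQCHSGVRTPVIIQCWFRGPAPNCVWIPYKCALWPFEWAHPIDYDMCSAQWFHWWGAGDRKDLTLHILYVRYQYEMLTLLKVPNYTCNSCMTILID"
TOY_DIC1 <- "MIYFIHAVGSGMIPQNVQHTWHNNPLYTCQLVQKCLMGVETTENQEEWRDAYTWHSWWNDHALYHEPQGYIFEKAFLLMNASGVVWYNVTPRPGVTDGENQVRAYVREQYTQRILLMHIWPIPHWCEAELQMVLCDAGACDIFYKHWIKSHQEKPFDSQA"
TOY_APN2 <- "MAWKHQLITLCHEWSTPEIEPRKDGVLCHIHKHQTEHTRCVTLYLETHDKVEFCYKEYMLAIICRWMLMVCGMFESKSWQRCKIMFVQREQLTEIKPQIPGDTSMEYMDTNEIVYFTPAKACMQVVTFFVQKHTSDICSGGMDQSNGAMVMTARVNFKIP"
TOY_RDNA <- "ATCAATACAAGTTCGCCTCTGAATTGAATGAAACGAGGCGATAGTTTAATTGCAAATCATACAGTAAAATGTTATATCGCGATAGCAGAGCACGGGTTTATTCTCCAACGGCATATATCGTTTTGCCGTCAAGATCATATTACAAACATAGTGCAATTTAATGGGCTGGGTTATCGAACAAGTTTTTGCAAAGAATGCATTTCTAGACGAGAACTAGCAATGTCGCTTTCAAGAGAGCCCATGAACTGATATTGTTCGTCTTGAGATTCGTGCTTTGCTTATTCATTTCTGCTCCTCGGGTTAATGTTATTCAATCTTGACAGACGGATAATGATGTACAATTCGAAAAGAGTCATTCAGCTAGCAATGTGTGCTTGTAGTGCTCGTAAAAATCGGCAGTGTTTTATATTCTTGGTAAACTTTAATACAGTTTCATTTAGACTCCAGGAACAGTTTACAGATGATCTAAAAGATGCTCAGATTGGAATGGATTAGATACTGTCCGGGTTTAAACCATAAGCTGGCCCTACTCATCTTTATTCTGTTCTCATGTTACAACCCTAAATCTGGGAGTGACTTAAACCACATGGTCCAAGTATG"

# gene symbol -> family for the bundled set
TOY_FAMILIES <- c(
  MATa1 = "mat_core", MATa2 = "mat_core",
  MATalpha1 = "mat_core", MATalpha2 = "mat_core",
  SLA2 = "neighbor", DIC1 = "neighbor", APN2 = "neighbor"
)

MAT_CORE_GENES <- c("MATa1", "MATa2", "MATalpha1", "MATalpha2")
A_GENES <- c("MATa1", "MATa2")
ALPHA_GENES <- c("MATalpha1", "MATalpha2")

#' Bundled toy protein query set
#'
#' A query set is a data.frame with one row per query sequence: columns
#' `name` (gene symbol), `family` (`mat_core`, `neighbor` or `landmark`),
#' `source` (suffix distinguishing multiple queries for one symbol) and
#' `seq` (amino acids). More than one query per gene symbol is allowed,
#' mirroring searches that use diverse sets of query sequences per gene.
#'
#' @return data.frame query set of the seven bundled toy sequences.
#' @seealso [read_queries()] for loading a real query set from FASTA.
#' @export
toy_queries <- function() {
  nm <- names(TOY_FAMILIES)
  data.frame(
    name = nm,
    family = unname(TOY_FAMILIES[nm]),
    source = "toy",
    seq = vapply(nm, function(g)
      get(paste0("TOY_", toupper(g)), envir = asNamespace("matsys")), ""),
    row.names = NULL
  )
}

#' Toy rDNA nucleotide landmark
#'
#' @return `DNAStringSet` of length one.
#' @export
toy_rdna_landmark <- function() {
  x <- Biostrings::DNAStringSet(TOY_RDNA)
  names(x) <- "RDNA|landmark|toy"
  x
}

#' Read a protein query set from FASTA
#'
#' Headers follow the convention `name|family|source`; a bare `name` is
#' accepted and assigned family `mat_core` if the name is a canonical MAT
#' gene symbol, `neighbor` otherwise.
#'
#' @param path FASTA of amino-acid queries.
#' @return data.frame with columns `name`, `family`, `source`, `seq`.
#' @export
read_queries <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty query set: ", path)
  parts <- strsplit(sub("\\s.*$", "", names(aa)), "|", fixed = TRUE)
  name <- vapply(parts, `[[`, "", 1L)
  family <- vapply(parts, function(p)
    if (length(p) >= 2L) p[2L]
    else if (p[1L] %in% MAT_CORE_GENES) "mat_core" else "neighbor", "")
  source <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "user", "")
  seqs <- as.character(aa)
  if (any(!nzchar(seqs))) stop("empty query sequence in ", path)
  data.frame(name = name, family = family, source = source, seq = seqs,
             row.names = NULL)
}

#' Write a query set to FASTA with the `name|family|source` convention
#'
#' @param queries data.frame query set.
#' @param path output file.
#' @export
write_queries <- function(queries, path) {
  aa <- Biostrings::AAStringSet(queries$seq)
  names(aa) <- paste(queries$name, queries$family, queries$source, sep = "|")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
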