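test_that("six-frame translation follows the selected genetic code", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr[[1]]$peptide, "MA")
  expect_equal(six_frame_translate("CTG", "cug_ser")[[1]]$peptide, "S")
  expect_equal(six_frame_translate("CTG", "cug_ala")[[1]]$peptide, "A")
  expect_equal(six_frame_translate("CTG", "standard")[[1]]$peptide, "L")
  expect_error(six_frame_translate("AC"), "codon")
  # stops as sentinel, fuzzy codons as X
  expect_equal(six_frame_translate("ATGTAAANN")[[1]]$peptide, "M*X")
})

test_that("frame coordinate maps invert exactly to genomic spans", {
  s <- "AATGGCC"
  fr <- six_frame_translate(s)
  # frame +1, residue 1 covers genomic [1, 4)
  expect_equal(frame_to_genomic(fr[[2]], 1, 1), list(start = 1L, end = 4L))
  # every frame: re-translating the mapped span reproduces the residues
  set.seed(42)
  dna <- random_dna(60)
  for (f in six_frame_translate(dna)) {
    n <- nchar(f$peptide)
    if (n < 3) next
    sp <- frame_to_genomic(f, 2, n - 1)
    sub <- substr(dna, sp$start + 1, sp$end)
    if (f$strand == "-") sub <- matsys:::rc_string(sub)
    expect_equal(
      as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                         no.init.codon = TRUE)),
      substr(f$peptide, 2, n - 1))
  }
})

test_that("local alignment scores match hand-computed BLOSUM62 sums", {
  # MKWV vs itself: diagonal BLOSUM62 entries M(5)+K(5)+W(11)+V(4) = 25,
  # cross-checked by summing the matrix entries directly
  al <- local_align("MKWV", "MKWV")
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  expected <- sum(diag(e$BLOSUM62[c("M", "K", "W", "V"),
                                  c("M", "K", "W", "V")]))
  expect_equal(al$raw_score, expected)
  expect_equal(al$n_identities, 4L)

  expect_equal(local_align("MKWV", "")$raw_score, 0)
  expect_equal(local_align("", "MKWV")$raw_score, 0)
  # symmetry for symmetric matrices
  expect_equal(local_align("MKWVDD", "AKWVEE")$raw_score,
               local_align("AKWVEE", "MKWVDD")$raw_score)
})

test_that("Karlin-Altschul E-values behave as specified", {
  # direct evaluation of E = K m n exp(-lambda S)
  e <- estimate_evalue(50, 100, 1e6, K = 0.041, lambda = 0.267)
  expect_equal(e, 0.041 * 100 * 1e6 * exp(-0.267 * 50))
  expect_equal(round(e, 1), 6.5)
  # linear in n
  expect_equal(estimate_evalue(50, 100, 2e6), 2 * estimate_evalue(50, 100, 1e6))
  # strictly decreasing in score, vanishing for large scores
  s <- seq(10, 200, by = 5)
  ev <- estimate_evalue(s, 100, 1e6)
  expect_true(all(diff(ev) < 0))
  expect_lt(estimate_evalue(1000, 100, 1e6), 1e-100)
  expect_error(estimate_evalue(50, 0, 10), "positive")
})

test_that("planted MAT cassettes are found as multi-query candidate regions", {
  g <- generate_genome("HET", seed = 11)
  res <- search_mat_genes(g$assembly, toy_queries())
  expect_true(all(res$hits$e_value < default_config()$e_max))
  expect_gte(nrow(res$candidates), 1L)
  qs <- strsplit(res$candidates$queries[1], ",")[[1]]
  expect_true(all(c("MATa1", "MATa2") %in% qs))
  # planted genes recovered essentially full length
  ch <- res$chains
  for (gene in c("MATa1", "MATa2", "SLA2", "DIC1")) {
    expect_gte(max(ch$query_cover[ch$query == gene]), 0.9)
  }
})

test_that("search is invariant under contig reordering", {
  g <- generate_genome("PHN", seed = 12)
  asm <- g$assembly
  asm_rev <- new_assembly(asm$species, rev(as.character(asm$contigs)),
                          rev(asm$coverage))
  h1 <- search_mat_genes(asm, toy_queries())$hits
  h2 <- search_mat_genes(asm_rev, toy_queries())$hits
  expect_equal(h1, h2)
})

test_that("retained hit spans re-translate to the aligned peptide", {
  g <- generate_genome("HET", seed = 13)
  res <- search_mat_genes(g$assembly, toy_queries())
  hits <- res$hits[res$hits$query_cover > 0.5, ]
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    sub <- substr(as.character(g$assembly$contigs[[h$contig]]),
                  h$start + 1, h$end)
    if (h$strand == "-") sub <- matsys:::rc_string(sub)
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                              no.init.codon = TRUE))
    q <- toy_queries()
    qsub <- substr(q$seq[q$name == h$query][1], h$q_start, h$q_end)
    # gapless planted genes: translated span equals the query segment
    expect_equal(pep, qsub)
  }
})

test_that("no-similarity assemblies yield empty results", {
  set.seed(99)
  asm <- new_assembly("bg", c(c1 = random_dna(3000)))
  res <- search_mat_genes(asm, toy_queries())
  strong <- res$hits[res$hits$query_cover >= 0.2, ]
  expect_equal(nrow(strong), 0L)
  expect_equal(nrow(res$candidates), 0L)
})
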