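test_that("contig header parsing is total and extracts SPAdes coverage", {
  p <- parse_contig_header("NODE_122_length_9071_cov_88.4")
  expect_equal(p$id, "NODE_122_length_9071_cov_88.4")
  expect_equal(p$coverage, 88.4)

  expect_equal(parse_contig_header("scaffold_7 assembled")$id, "scaffold_7")
  expect_true(is.na(parse_contig_header("scaffold_7 assembled")$coverage))
  expect_equal(parse_contig_header("NODE_3_length_100_cov_0")$coverage, 0)
  # every header yields an id
  for (h in c("x", "a b c", ">", "NODE_1", "NODE_1_length_2_cov_x"))
    expect_true(nzchar(parse_contig_header(h)$id) || h == ">")
})

test_that("read_assembly uppercases, preserves order and reads coverage", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">NODE_1_length_10_cov_4.5", "ACGTACGTAC",
               ">chr1", "acgt"), f)
  asm <- read_assembly(f)
  expect_equal(length(asm$contigs), 2L)
  expect_equal(unname(Biostrings::width(asm$contigs)[1]), 10L)
  expect_equal(unname(asm$coverage[[1]]), 4.5)
  expect_equal(as.character(asm$contigs[[2]]), "ACGT")
  expect_true(is.na(asm$coverage[[2]]))

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_assembly(empty))

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTZZ"), bad)
  expect_error(read_assembly(bad), "non-nucleotide")
  expect_message(asm2 <- read_assembly(bad, on_bad_char = "mask"), "masking")
  expect_equal(as.character(asm2$contigs[[1]]), "ACGTNN")
})

test_that("sidecar coverage TSV overrides header coverage", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTACGTAC", ">c2", "ACGT"), f)
  side <- tempfile(fileext = ".tsv")
  writeLines(c("c1\t12.5", "c2\t3"), side)
  asm <- read_assembly(f, coverage_tsv = side)
  expect_equal(unname(asm$coverage), c(12.5, 3))
})

test_that("median coverage is length-weighted", {
  asm <- new_assembly("x",
                      c(c1 = strrep("A", 1000), c2 = strrep("A", 10),
                        c3 = strrep("A", 10)),
                      coverage = c(c1 = 10, c2 = 100, c3 = 90))
  expect_equal(median_coverage(asm), 10)
  asm2 <- new_assembly("y", c(c1 = "ACGT"), coverage = c(c1 = NA))
  expect_true(is.na(median_coverage(asm2)))
})

test_that("sequence content round-trips through FASTA", {
  g <- generate_genome("PHC", seed = 3)
  f <- tempfile(fileext = ".fa")
  write_assembly_fasta(g$assembly, f, dialect = "spades")
  back <- read_assembly(f)
  expect_equal(unname(as.character(back$contigs)),
               unname(as.character(g$assembly$contigs)))
  expect_equal(unname(back$coverage),
               unname(g$assembly$coverage))
})

test_that("GFF3 export is 1-based inclusive and round-trips spans", {
  g <- generate_genome("FF1", seed = 2)
  ann <- annotate_assembly(g$assembly)
  f <- tempfile(fileext = ".gff3")
  export_annotation_gff3(ann, f)
  gr <- rtracklayer::import.gff3(f)
  loci <- gr[gr$type == "mat_locus"]
  expect_equal(length(loci), length(ann$loci))
  # internal 0-based half-open [s, e) must appear as 1-based inclusive
  expect_equal(sort(GenomicRanges::start(loci)),
               sort(vapply(ann$loci, `[[`, 0L, "start") + 1L))
  expect_equal(sort(GenomicRanges::end(loci)),
               sort(vapply(ann$loci, `[[`, 0L, "end")))
  rep_feats <- gr[gr$type == "repeat_pair"]
  expect_equal(length(rep_feats), 2L * nrow(ann$repeats))
})

test_that("export_results writes calls TSV, GFF3, JSON and Newick", {
  g <- generate_genome("PHC", seed = 4)
  ann <- annotate_assembly(g$assembly)
  cl <- classify_species(ann)
  tree <- parse_newick("(a,b);")
  rec <- reconstruct_states(tree, c(a = "PHC", b = "PHC"))
  outdir <- tempfile()
  calls <- stats::setNames(list(cl), g$assembly$species)
  anns <- stats::setNames(list(ann), g$assembly$species)
  files <- export_results(calls, anns, count_transitions(rec),
                          state_labelled_tree(rec), outdir)
  expect_length(files, 4L)
  tsv <- read.table(file.path(outdir, "calls.tsv"), sep = "\t",
                    header = TRUE)
  expect_equal(nrow(tsv), 1L)
  expect_equal(tsv$category, "PHC")
  js <- jsonlite::read_json(file.path(outdir, "transition_summary.json"))
  expect_equal(js$switching_origins, 0L)
  expect_equal(length(js$counts), 0L)
})
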