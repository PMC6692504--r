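test_that("gene-call status is a total function of cover and stops", {
  chains <- data.frame(
    query = c("MATa1", "MATa1", "SLA2", "MATalpha1"),
    source = "toy", family = c("mat_core", "mat_core", "neighbor", "mat_core"),
    contig = "c1", start = c(0L, 5000L, 10000L, 15000L),
    end = c(360L, 5120L, 10480L, 15360L), strand = "+",
    raw_score = 500, bit_score = 200, e_value = 1e-40,
    query_cover = c(0.95, 0.35, 1.0, 0.85),
    n_internal_stops = c(0L, 0L, 2L, 0L), n_members = 1L)
  calls <- call_genes(chains)
  expect_equal(calls$status[calls$query_cover == 0.95], "intact")
  expect_equal(calls$status[calls$query_cover == 0.35], "fragment")
  expect_equal(calls$status[calls$n_internal_stops == 2], "pseudogene")
  expect_equal(calls$status[calls$query_cover == 0.85], "intact")
})

test_that("overlapping chains of one gene resolve by bit score", {
  chains <- data.frame(
    query = "MATa1", source = c("toy", "alt"), family = "mat_core",
    contig = "c1", start = c(100L, 150L), end = c(460L, 500L),
    strand = "+", raw_score = c(500, 300), bit_score = c(200, 120),
    e_value = 1e-40, query_cover = c(0.95, 0.5),
    n_internal_stops = 0L, n_members = 1L)
  calls <- call_genes(chains)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$bit_score, 200)
})

test_that("a contiguous SLA2-a-alpha-DIC1 arrangement forms one locus", {
  g <- generate_genome("PHC", seed = 21)
  ann <- annotate_assembly(g$assembly)
  expect_length(ann$loci, 1L)
  lc <- ann$loci[[1]]
  expect_equal(lc$idiomorph, "both")
  expect_true(all(c("SLA2", "DIC1") %in% names(lc$neighbors)))
  expect_lt(lc$neighbors[["SLA2"]], 0)   # upstream
  expect_gt(lc$neighbors[["DIC1"]], 0)   # downstream
})

test_that("no intact MAT genes yields no loci", {
  g <- generate_genome("NOMAT", seed = 22)
  ann <- annotate_assembly(g$assembly)
  expect_length(ann$loci, 0L)
})

test_that("planted IRs are found with correct orientation, role, identity", {
  g <- generate_genome(planted_genome_spec("FF1", seed = 23,
                                           ir_identity = 97))
  ann <- annotate_assembly(g$assembly)
  rp <- ann$repeats
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$orientation, "inverted")
  expect_equal(rp$role, "IR")
  expect_gte(rp$identity, 90)
  expect_lte(abs(rp$identity - 97), 2)
  expect_gte(rp$length, 1800)
  cfg <- default_config()
  expect_true(all(ann$repeats$identity >= cfg$min_repeat_identity))
  expect_true(all(ann$repeats$length >= cfg$min_repeat_len))
})

test_that("repeat detection is strand-symmetric", {
  g <- generate_genome("FF2", seed = 24)
  ann1 <- annotate_assembly(g$assembly)
  L <- Biostrings::width(g$assembly$contigs)[[1]]
  flipped <- new_assembly(g$assembly$species,
                          c(c1 = matsys:::rc_string(
                            as.character(g$assembly$contigs[[1]]))),
                          g$assembly$coverage)
  ann2 <- annotate_assembly(flipped)
  expect_equal(nrow(ann1$repeats), nrow(ann2$repeats))
  expect_equal(sort(ann1$repeats$orientation), sort(ann2$repeats$orientation))
  # mirrored coordinates: copy spans map to L - end, L - start
  mirrored <- sort(c(L - ann1$repeats$endA, L - ann1$repeats$endB))
  expect_equal(sort(c(ann2$repeats$startA, ann2$repeats$startB)), mirrored)
})

test_that("telomere arrays are detected at ends only, any unit phase", {
  cfg <- default_config()
  set.seed(31)
  unit <- "TTTTAGTAGGG"
  near_end <- paste0(random_dna(80), strrep(unit, 5), random_dna(4000))
  tel <- detect_telomere(near_end, cfg)
  expect_equal(nrow(tel), 1L)
  expect_equal(tel$contig_end, "left")
  expect_equal(tel$unit, matsys:::canonical_rotation(unit))
  expect_gte(tel$copies, 5L)

  # same array mid-contig: no telomere
  center <- paste0(random_dna(3000), strrep(unit, 5), random_dna(3000))
  expect_equal(nrow(detect_telomere(center, cfg)), 0L)

  # rotated phase gives the same canonical unit
  rot <- paste0(substr(unit, 4, 11), strrep(unit, 5), random_dna(4000))
  tel2 <- detect_telomere(rot, cfg)
  expect_equal(tel2$unit[1], tel$unit[1])

  # 8-bp unit 47 bp from the array to the contig end
  s <- paste0(random_dna(5000), strrep("TTTGAGGG", 6), random_dna(47))
  tel3 <- detect_telomere(s, cfg)
  expect_equal(tel3$contig_end, "right")
  expect_equal(nchar(tel3$unit), 8L)
})

test_that("assembler-artifact flag applies all three gates", {
  # 118-kb IR, 1 mismatch, both copies to contig ends: artifact
  p1 <- make_repeat_pair("c1", 0, 118000, "c1", 200000, 318000,
                         identity = 100 * (1 - 1 / 118000),
                         reachesA = TRUE, reachesB = TRUE)
  expect_true(flag_assembly_artifact(p1))
  # ordinary internal 2-kb IR at 97%
  p2 <- make_repeat_pair("c1", 5000, 7000, "c1", 20000, 22000,
                         identity = 97)
  expect_false(flag_assembly_artifact(p2))
  # long and perfect but internal
  p3 <- make_repeat_pair("c1", 5000, 65000, "c1", 100000, 160000,
                         identity = 100)
  expect_false(flag_assembly_artifact(p3))
  # long, reaches ends, but too divergent
  p4 <- make_repeat_pair("c1", 0, 60000, "c1", 100000, 160000,
                         identity = 99, reachesA = TRUE, reachesB = TRUE)
  expect_false(flag_assembly_artifact(p4))
})

test_that("allelism verdicts follow the shared-flank rule", {
  set.seed(41)
  shared_l <- random_dna(1000); shared_r <- random_dna(1000)
  core_a <- paste0(random_dna(200),
                   matsys:::reverse_translate(matsys:::TOY_MATA1),
                   random_dna(200))
  core_al <- paste0(random_dna(200),
                    matsys:::reverse_translate(matsys:::TOY_MATALPHA1),
                    random_dna(200))
  asm <- new_assembly("dip", c(
    c1 = paste0(shared_l, core_a, shared_r),
    c2 = paste0(shared_l, core_al, shared_r),
    c3 = paste0(random_dna(1000), core_al, random_dna(1000)),
    c4 = paste0(shared_l, core_al, random_dna(1000))))
  lA <- make_locus("c1", 1000, 1000 + nchar(core_a), "a")
  lB <- make_locus("c2", 1000, 1000 + nchar(core_al), "alpha")
  lC <- make_locus("c3", 1000, 1000 + nchar(core_al), "alpha")
  lD <- make_locus("c4", 1000, 1000 + nchar(core_al), "alpha")
  expect_equal(detect_allelism(asm, lA, lB)$verdict, "allelic")
  expect_equal(detect_allelism(asm, lA, lC)$verdict, "non_allelic")
  expect_equal(detect_allelism(asm, lA, lD)$verdict, "ambiguous")
  # overlapping loci on one contig are malformed input
  expect_error(detect_allelism(asm, lA, make_locus("c1", 1100, 1500, "alpha")),
               "malformed")
})

test_that("collapsed-repeat links require the coverage gate", {
  g <- generate_genome("FF1", seed = 26)
  gc <- emulate_assembler_collapse(g, k = 55)
  links <- infer_collapsed_repeats(gc$assembly)
  expect_equal(links$repeat_contig, "cM")
  expect_equal(links$overlap_len, 55L)
  expect_setequal(strsplit(links$neighbors, ",")[[1]],
                  gc$truth$expected_link$neighbors)
  # set the repeat contig to 1x: gate closes
  asm2 <- gc$assembly
  asm2$coverage[["cM"]] <- asm2$coverage[["cL"]]
  expect_equal(nrow(infer_collapsed_repeats(asm2)), 0L)
  # no coverage at all: empty with warning
  asm3 <- gc$assembly
  asm3$coverage[] <- NA_real_
  expect_warning(out <- infer_collapsed_repeats(asm3), "coverage")
  expect_equal(nrow(out), 0L)
})

test_that("PHN context flags fire for telomeric and rDNA second loci", {
  g <- generate_genome("PHN", seed = 27)
  ann <- annotate_assembly(g$assembly)
  second <- Filter(function(lc) lc$contig == "c2", ann$loci)
  expect_length(second, 1L)
  expect_true(second[[1]]$telomere_proximal)

  g2 <- generate_genome(planted_genome_spec("PHN", seed = 28,
                                            plant_rdna = TRUE))
  ann2 <- annotate_assembly(g2$assembly)
  second2 <- Filter(function(lc) lc$contig == "c2", ann2$loci)
  expect_true(second2[[1]]$rdna_proximal)
})
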