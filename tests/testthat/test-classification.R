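test_that("each planted category classifies to itself end to end", {
  for (cat_ in MAT_SYSTEMS) {
    g <- generate_genome(cat_, seed = 101)
    cl <- classify_assembly(g$assembly)
    expect_equal(cl$category, cat_, label = paste("category", cat_))
  }
})

test_that("classification is deterministic and order-independent", {
  loci <- list(make_locus("c1", 1000, 2000, "a"),
               make_locus("c2", 1000, 2000, "alpha"))
  rp <- make_repeat_pair("c1", 100, 400, "c2", 100, 400)
  a1 <- make_annotation(loci, repeats = rp)
  a2 <- make_annotation(rev(loci), repeats = rp)
  c1 <- classify_species(a1); c2 <- classify_species(a2)
  expect_equal(c1$category, c2$category)
  expect_equal(c1$provisional, c2$provisional)
  expect_equal(classify_species(a1), classify_species(a1))
})

test_that("rule order: no intact genes is NOMAT only after a search ran", {
  expect_equal(classify_species(make_annotation(list()))$category, "NOMAT")
  expect_error(classify_species(make_annotation(list(), searched = FALSE)),
               "not searched")
})

test_that("single idiomorph is haploid HET; allelic pairs are diploid HET", {
  only_a <- make_annotation(list(make_locus("c1", 1000, 2000, "a")))
  cl <- classify_species(only_a)
  expect_equal(cl$category, "HET")
  expect_equal(cl$ploidy_note, "haploid")

  loci <- list(make_locus("c1", 1000, 2000, "a"),
               make_locus("c2", 1000, 2000, "alpha"))
  allel <- data.frame(locusA = 1L, locusB = 2L, left_len = 500L,
                      left_ident = 100, right_len = 500L, right_ident = 100,
                      orientation = "direct", verdict = "allelic")
  cl2 <- classify_species(make_annotation(loci, allelism = allel))
  expect_equal(cl2$category, "HET")
  expect_equal(cl2$ploidy_note, "diploid")
  # non-allelic version of the same loci, no repeats: PHN
  cl3 <- classify_species(make_annotation(loci))
  expect_equal(cl3$category, "PHN")
  expect_equal(cl3$ploidy_note, "unknown")
})

test_that("three non-allelic cassettes are 3LOC even with fragments", {
  loci <- list(make_locus("c1", 1000, 2000, "alpha"),
               make_locus("c1", 15000, 16000, "a"))
  frag <- data.frame(contig = "c1", start = 30000L, end = 30400L,
                     genes = "MATa1")
  rp <- make_repeat_pair("c1", 900, 1200, "c1", 29800, 30100,
                         orientation = "direct", role = "XZ_like")
  cl <- classify_species(make_annotation(loci, repeats = rp,
                                         fragments = frag))
  expect_equal(cl$category, "3LOC")
})

test_that("IR family count separates FF1 from FF2; repeats trump distance", {
  # two loci 12 kb apart (below the PHC bound) with one IR family: FF1
  loci <- list(make_locus("c1", 3000, 4000, "a"),
               make_locus("c1", 16000, 17000, "alpha"))
  one_ir <- make_repeat_pair("c1", 500, 2700, "c1", 17300, 19500)
  cl <- classify_species(make_annotation(loci, repeats = one_ir))
  expect_equal(cl$category, "FF1")
  expect_false(cl$provisional)
  # same loci without repeats would be PHC: repeats trump distance
  expect_equal(classify_species(make_annotation(loci))$category, "PHC")
  # two inverted families: FF2
  two_ir <- rbind(one_ir,
                  make_repeat_pair("c1", 4200, 4500, "c1", 15500, 15800))
  cl2 <- classify_species(make_annotation(loci, repeats = two_ir))
  expect_equal(cl2$category, "FF2")
})

test_that("cross-contig repeat families give a provisional FF2", {
  # two loci on different contigs joined by two repeat families of
  # unknowable relative orientation
  loci <- list(make_locus("c1", 300000, 301000, "a"),
               make_locus("c2", 2000, 3000, "alpha"))
  fams <- rbind(
    make_repeat_pair("c1", 297000, 299000, "c2", 100, 1800,
                     orientation = "direct", role = "unknown"),
    make_repeat_pair("c1", 301200, 301420, "c2", 3100, 3313,
                     identity = 100, orientation = "inverted",
                     role = "unknown"))
  cl <- classify_species(make_annotation(loci, repeats = fams))
  expect_equal(cl$category, "FF2")
  expect_true(cl$provisional)
})

test_that("artifact-flagged IRs still count as FF1 evidence, provisionally", {
  loci <- list(make_locus("c1", 120000, 121000, "a"),
               make_locus("c1", 170000, 171000, "alpha"))
  huge <- make_repeat_pair("c1", 0, 118000, "c1", 172000, 290000,
                           identity = 100 * (1 - 1 / 118000),
                           reachesA = TRUE, reachesB = TRUE)
  expect_true(huge$artifact)
  cl <- classify_species(make_annotation(loci, repeats = huge))
  expect_equal(cl$category, "FF1")
  expect_true(cl$provisional)
})

test_that("collapsed-repeat links joining both idiomorphs count as an IR", {
  loci <- list(make_locus("cI1", 1000, 2000, "a"),
               make_locus("cI2", 1000, 2000, "alpha"))
  links <- data.frame(repeat_contig = "cM", neighbors = "cI1,cI2,cL,cR",
                      n_neighbors = 4L, overlap_len = 55L,
                      coverage_ratio = 2.0)
  cl <- classify_species(make_annotation(loci, links = links))
  expect_equal(cl$category, "FF1")
  expect_false(cl$provisional)
})

test_that("the PHC/PHN boundary flips exactly at phc_max_gap", {
  cfg <- default_config()
  mk <- function(gap) {
    a_end <- 5000L
    list(make_locus("c1", 4000, a_end, "a"),
         make_locus("c1", a_end + gap, a_end + gap + 1000, "alpha"))
  }
  for (gap in c(1000L, 19999L)) {
    expect_equal(classify_species(make_annotation(mk(gap)), cfg)$category,
                 "PHC", label = paste("gap", gap))
  }
  for (gap in c(20000L, 20001L, 90000L)) {
    expect_equal(classify_species(make_annotation(mk(gap)), cfg)$category,
                 "PHN", label = paste("gap", gap))
  }
  # nothing else changes across the boundary
  c1 <- classify_species(make_annotation(mk(19999L)), cfg)
  c2 <- classify_species(make_annotation(mk(20000L)), cfg)
  expect_equal(c1$ploidy_note, c2$ploidy_note)
  expect_equal(c1$provisional, c2$provisional)
})
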