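#!/usr/bin/env Rscript
# Generate one synthetic assembly per mating-compatibility category, plus
# assembler-collapsed variants of the flip/flop genomes, as inputs for the
# classification stage. Writes FASTA (SPAdes-style headers carrying
# coverage) and the ground-truth category table under results/simulated/.

suppressPackageStartupMessages(library(matsys))

seed <- 20190805L %% 1000003L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- list()
for (cat_ in MAT_SYSTEMS) {
  g <- generate_genome(cat_, seed = seed)
  f <- file.path(out, paste0(g$assembly$species, ".fa"))
  write_assembly_fasta(g$assembly, f, dialect = "plain")
  truth[[g$assembly$species]] <- cat_
  message("planted ", cat_, " genome: ", f, " (",
          sum(Biostrings::width(g$assembly$contigs)), " bp)")
}
for (cat_ in c("FF1", "FF2")) {
  g <- emulate_assembler_collapse(generate_genome(cat_, seed = seed + 1L))
  g$assembly$species <- paste0(g$assembly$species, "_collapsed")
  f <- file.path(out, paste0(g$assembly$species, ".fa"))
  write_assembly_fasta(g$assembly, f, dialect = "spades")
  truth[[g$assembly$species]] <- cat_
  message("planted collapsed ", cat_, " genome: ", f)
}

write.table(data.frame(species = names(truth),
                       true_category = unlist(truth)),
            file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("ground truth for ", length(truth), " genomes -> ",
        file.path(out, "truth.tsv"))
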