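#!/usr/bin/env Rscript

# Cross-assembly comparison: the aligned HOR schemes of the Neanderthal-like,
# hg38-like and T2T-like annotations are laid out side by side with the four
# shared prominent arrays (the NBPF20/14/10/19 stand-ins) horizontally
# anchored, and the consensus monomer panels of the two hominin-like
# assemblies are compared family by family.  Writes the combined panel to
# results/comparison/.

suppressMessages(library(horseq))

indir <- "results/genomes"
outdir <- "results/comparison"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
stopifnot(file.exists(file.path(indir, "t2t_like.fa")))

annotate <- function(nm) {
  run_pipeline(pipeline_config(
    fasta = file.path(indir, paste0(nm, ".fa")),
    consensus_fasta = file.path(indir, "human_consensus_panel.fa"),
    seed = 42))
}
panels <- lapply(c(neanderthal_like = "neanderthal_like",
                   hg38_like = "hg38_like",
                   t2t_like = "t2t_like"), annotate)

# anchor the four prominent arrays shared by all three assemblies
anchors <- lapply(panels, function(p) {
  per <- p$assembly$report$per_array
  head(per$array[per$prominent], 4)
})
aligned <- align_panels(lapply(panels, `[[`, "assembly"), anchors = anchors,
                        names = names(panels))
writeLines(aligned, file.path(outdir, "aligned_panels.txt"))
cat("wrote", file.path(outdir, "aligned_panels.txt"), "\n")

# consensus monomer panels re-estimated independently from each assembly's
# own hits: Neanderthal-like vs T2T-like
reestimate <- function(nm) {
  seq <- read_fasta(file.path(indir, paste0(nm, ".fa")))[[1]]
  consensus_from_hits(seq, panels[[nm]]$hits)
}
cn <- reestimate("neanderthal_like")
ct <- reestimate("t2t_like")
dv <- vapply(c("m1", "m2", "m3"), function(f)
  pairwise_divergence(cn[[f]], ct[[f]]), 0)
cat("consensus divergence Neanderthal-like vs T2T-like, per family:\n")
print(round(dv, 4))
cat(sprintf("mean: %.3f%% (cross-assembly consensus agreement)\n",
            100 * mean(dv)))
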