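#!/usr/bin/env Rscript

# Simulate the four study genomes: desk-scale stand-ins for chromosome-1 of
# T2T-CHM13, hg38.p14, Neanderthal (AltaiNea.hg19) and chimpanzee, each
# planting the corresponding published HOR-copy layout (arrays of canonical
# m1m2m3 copies plus variant rows, mixed strands, one >2 kb N-gap) into ~2 Mb
# of random background.  All genomes share one homologous base-monomer
# panel: the archaic-like panel drifts from the human one by 0.5%
# substitutions, the chimp-like panel by 1%.  Writes FASTA plus exact truth
# (BED6 + JSON) under results/genomes/.

suppressMessages(library(horseq))

seed <- 42L
outdir <- "results/genomes"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

human <- make_family_set(family_spec(monomer_length = 1600, seed = seed))
drift <- function(panel, rate, s) {
  stats::setNames(vapply(panel, function(x)
    mutate_seq(x, sub_rate = rate, seed = s), ""), names(panel))
}
nea_mono <- drift(human, 0.005, seed + 101L)
chimp_mono <- drift(human, 0.010, seed + 102L)
write_fasta(human, file.path(outdir, "human_consensus_panel.fa"))

scenarios <- list(
  t2t_like = t2t_like_scenario(seed = seed, monomers = human),
  hg38_like = hg38_like_scenario(seed = seed + 1L, monomers = human),
  neanderthal_like = neanderthal_like_scenario(seed = seed + 2L,
                                               monomers = nea_mono),
  chimp_like = chimp_like_scenario(seed = seed + 3L, monomers = chimp_mono)
)

for (nm in names(scenarios)) {
  sc <- scenarios[[nm]]
  g <- generate_genome(sc$spec, sc$monomers, chrom = nm)
  write_fasta(stats::setNames(g$seq, nm), file.path(outdir, paste0(nm, ".fa")))
  write_fasta(sc$monomers, file.path(outdir, paste0(nm, ".monomers.fa")))
  write_truth(g$truth, file.path(outdir, paste0(nm, ".truth.bed")),
              file.path(outdir, paste0(nm, ".truth.json")))
  cat(sprintf("%-18s %8d bp, %3d monomers, %2d copies (%2d canonical), %d arrays\n",
              nm, nchar(g$seq), nrow(g$truth$monomers), nrow(g$truth$copies),
              sum(g$truth$copies$canonical), nrow(g$truth$arrays)))
}
cat("wrote genomes and truth to", outdir, "\n")
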