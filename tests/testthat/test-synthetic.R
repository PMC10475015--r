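test_that("family sets honour the requested size, length and divergence", {
  # degenerate cases
  one <- make_family_set(family_spec(n_families = 1, monomer_length = 100,
                                     seed = 3))
  expect_length(one, 1L)
  expect_equal(nchar(one[[1]]), 100L)

  same <- make_family_set(family_spec(n_families = 3, monomer_length = 60,
                                      inter_family_divergence = 0, seed = 3))
  expect_equal(unname(same[1]), unname(same[2]))
  expect_equal(unname(same[2]), unname(same[3]))

  # the planted 25% regime, measured with the pipeline's own metric
  fams <- make_family_set(family_spec(n_families = 3, monomer_length = 1600,
                                      inter_family_divergence = 0.25, seed = 7))
  m <- divergence_matrix(fams)
  off <- m[upper.tri(m)]
  expect_true(all(off >= 0.20 & off <= 0.30))

  # determinism
  expect_identical(fams, make_family_set(family_spec(seed = 7)))

  expect_error(family_spec(n_families = 0), "n_families")
  expect_error(family_spec(monomer_length = 10), "monomer_length")
  expect_error(family_spec(inter_family_divergence = 0.9), "divergence")
})

test_that("mutation applies substitutions and indels at the stated rates", {
  s <- strrep("A", 1000)
  expect_identical(mutate_seq(s, 0, 0, seed = 1), s)
  expect_identical(mutate_seq("", 0.5, 0.5, seed = 1), "")
  # deletion-only at rate 1 empties the sequence
  expect_identical(mutate_seq("ACGTA", del_rate = 1, seed = 1), "")

  # substitution count within the 99.9% binomial envelope of Bin(1000, 0.01)
  m <- mutate_seq(s, sub_rate = 0.01, seed = 11)
  expect_equal(nchar(m), 1000L)
  ham <- sum(strsplit(m, "")[[1]] != "A")
  env <- qbinom(c(5e-4, 1 - 5e-4), 1000, 0.01)
  expect_gte(ham, env[1])
  expect_lte(ham, env[2])

  # determinism given seed
  expect_identical(mutate_seq(s, 0.02, 0.01, seed = 5),
                   mutate_seq(s, 0.02, 0.01, seed = 5))
  expect_error(mutate_seq("ACGT", sub_rate = 2), "rates")
})

test_that("generated genomes match their ground truth exactly", {
  mono <- make_family_set(family_spec(monomer_length = 200, seed = 5))
  # no plants: pure background, empty truth
  g0 <- generate_genome(genome_spec(5000, seed = 2), mono)
  expect_equal(nchar(g0$seq), 5000L)
  expect_equal(nrow(g0$truth$monomers), 0L)

  # one array of 5 canonical rows, zero noise
  ap <- array_plan(position = 1000, rows = rep(list(c("m1", "m2", "m3")), 5),
                   intra_divergence = 0, indel_rate = 0)
  g <- generate_genome(genome_spec(10000, arrays = list(ap), seed = 2), mono)
  tm <- g$truth$monomers
  expect_equal(nrow(tm), 15L)
  expect_equal(nrow(g$truth$copies), 5L)
  expect_equal(nrow(g$truth$arrays), 1L)
  expect_equal(nchar(g$seq), 10000L + 15L * 200L)
  # each truth interval carries exactly its base monomer
  for (i in seq_len(nrow(tm))) {
    expect_identical(substr(g$seq, tm$start[i], tm$end[i]),
                     unname(mono[[tm$family[i]]]))
  }
  # conservation: truth monomers = sum of row lengths
  expect_equal(nrow(tm), sum(vapply(ap$rows, length, 0L)))

  # determinism: same spec + seed => identical genome and truth
  g2 <- generate_genome(genome_spec(10000, arrays = list(ap), seed = 2), mono)
  expect_identical(g$seq, g2$seq)
  expect_identical(g$truth, g2$truth)

  # overlapping insertion points refuse to build
  expect_error(genome_spec(10000, arrays = list(ap, ap)), "overlap")
})

test_that("minus-strand arrays are reverse-complement planted with forward truth", {
  mono <- make_family_set(family_spec(monomer_length = 150, seed = 6))
  ap <- array_plan(position = 500, rows = rep(list(c("m1", "m2", "m3")), 3),
                   strand = "-", intra_divergence = 0, indel_rate = 0)
  g <- generate_genome(genome_spec(3000, arrays = list(ap), seed = 4), mono)
  tm <- g$truth$monomers
  expect_true(all(tm$strand == "-"))
  # genomic order of families is reversed (m3 first)
  expect_equal(tm$family[1:3], c("m3", "m2", "m1"))
  # each slice is the reverse complement of its base monomer
  for (i in seq_len(nrow(tm))) {
    expect_identical(substr(g$seq, tm$start[i], tm$end[i]),
                     revcomp(mono[[tm$family[i]]]))
  }
})

test_that("truth round-trips through BED and JSON", {
  mono <- make_family_set(family_spec(monomer_length = 150, seed = 6))
  ap <- array_plan(position = 500, rows = rep(list(c("m1", "m2", "m3")), 5),
                   intra_divergence = 0, indel_rate = 0)
  g <- generate_genome(genome_spec(3000, arrays = list(ap), seed = 4), mono)
  bed <- tempfile(fileext = ".bed")
  js <- tempfile(fileext = ".json")
  write_truth(g$truth, bed, js)
  lines <- readLines(bed)
  expect_length(lines, 15L)
  expect_true(all(grepl("\t[+-]$", lines)))
  # BED is 0-based half-open
  f1 <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(f1[2]) + 1L, g$truth$monomers$start[1])
  expect_equal(as.integer(f1[3]), g$truth$monomers$end[1])
  back <- read_truth(js)
  expect_equal(back$monomers$start, g$truth$monomers$start)
  expect_equal(back$monomers$family, g$truth$monomers$family)
  expect_equal(back$arrays$n_canonical, g$truth$arrays$n_canonical)

  # empty truth writes an empty BED
  g0 <- generate_genome(genome_spec(1000, seed = 1), mono)
  write_truth(g0$truth, bed, js)
  expect_length(readLines(bed), 0L)
})
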