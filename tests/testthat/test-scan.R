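test_that("planted consensus copies are found exactly, on both strands", {
  set.seed(7)
  bg <- random_dna(30000)
  cons <- random_dna(100)

  s <- plant_at(bg, cons, 10000)
  h <- scan_monomers(s, c(m1 = cons))
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 10001L)   # 1-based
  expect_equal(h$end, 10100L)
  expect_equal(h$strand, "+")
  expect_equal(h$divergence, 0)

  # reverse-complement plant: same forward coordinates, minus strand
  s2 <- plant_at(bg, revcomp(cons), 10000)
  h2 <- scan_monomers(s2, c(m1 = cons))
  expect_equal(h2$start, 10001L)
  expect_equal(h2$end, 10100L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$edits, 0L)

  # known substitution count is reported as edits/divergence
  mut <- cons
  for (p in c(20, 50, 80)) {
    substr(mut, p, p) <- chartr("ACGT", "CAGT", substr(mut, p, p))
  }
  h3 <- scan_monomers(plant_at(bg, mut, 10000), c(m1 = cons))
  expect_equal(h3$edits, 3L)
  expect_equal(h3$divergence, 3 / 100)

  # consensus longer than the sequence: empty result with a warning
  expect_warning(h4 <- scan_monomers("ACGT", c(m1 = cons)), "longer")
  expect_equal(nrow(h4), 0L)
})

test_that("accepted hit divergences equal the brute-force DP minimum", {
  set.seed(19)
  cons <- random_dna(80)
  copies <- vapply(1:6, function(i)
    mutate_seq(cons, sub_rate = 0.05, indel_rate = 0.01), "")
  s <- random_dna(18000)
  at <- c(2000, 5000, 8000, 11000, 14000, 16000)
  for (i in seq_along(copies)) s <- plant_at(s, copies[i], at[i] + (i - 1) * 80)
  h <- scan_monomers(s, c(m1 = cons), scan_config(max_divergence = 0.15))
  expect_equal(nrow(h), 6L)
  ref <- brute_end_dists(s, cons)
  for (i in seq_len(nrow(h))) {
    expect_equal(h$edits[i], ref[h$end[i]])
    # and it is the locus minimum in a window around the hit
    win <- max(1, h$end[i] - 40):min(nchar(s), h$end[i] + 40)
    expect_equal(h$edits[i], min(ref[win]))
  }
})

test_that("strand involution: scanning the reverse complement reflects hits", {
  set.seed(23)
  cons <- list(m1 = random_dna(120), m2 = random_dna(120))
  s <- random_dna(20000)
  s <- plant_at(s, cons$m1, 3000)
  s <- plant_at(s, revcomp(cons$m2), 9000)
  s <- plant_at(s, cons$m2, 15000)
  cset <- unlist(cons)
  h <- scan_monomers(s, cset)
  hr <- scan_monomers(revcomp(s), cset)
  n <- nchar(s)
  reflected <- data.frame(start = n - hr$end + 1L, end = n - hr$start + 1L,
                          family = hr$family,
                          strand = ifelse(hr$strand == "+", "-", "+"))
  reflected <- reflected[order(reflected$start), ]
  expect_equal(reflected$start, h$start)
  expect_equal(reflected$end, h$end)
  expect_equal(reflected$family, h$family)
  expect_equal(reflected$strand, h$strand)
})

test_that("overlap resolution keeps the best family per locus", {
  set.seed(31)
  # two families 25% apart; the planted copy is drawn from m1
  # (the family seed is decoupled from the background stream)
  fams <- make_family_set(family_spec(n_families = 2, monomer_length = 200,
                                      inter_family_divergence = 0.25,
                                      seed = 4031))
  s <- plant_at(random_dna(20000), mutate_seq(fams[["m1"]], 0.02), 8000)
  h <- scan_monomers(s, fams, scan_config(max_divergence = 0.2))
  # only the closer family survives at the locus
  expect_equal(nrow(h), 1L)
  expect_equal(h$family, "m1")
  # no two accepted hits ever share a base
  expect_true(all(h$start[-1] > h$end[-nrow(h)]))
})

test_that("hits overlapping long N-runs are rejected", {
  set.seed(37)
  cons <- random_dna(100)
  half <- paste0(substr(cons, 1, 50), strrep("N", 50))
  s <- plant_at(random_dna(10000), half, 5000)
  h <- scan_monomers(s, c(m1 = cons),
                     scan_config(max_divergence = 0.49, max_n_fraction = 0.1))
  nfrac <- vapply(seq_len(nrow(h)), function(i) {
    sub <- substr(s, h$start[i], h$end[i])
    nchar(gsub("[^N]", "", sub)) / nchar(sub)
  }, 0)
  expect_true(!nrow(h) || all(nfrac <= 0.1))
})

test_that("assembly gaps are maximal N-runs strictly above the cutoff", {
  expect_equal(nrow(find_assembly_gaps(random_dna(5000))), 0L)
  s <- paste0(strrep("A", 10), strrep("N", 2500), strrep("A", 10))
  g <- find_assembly_gaps(s, min_len = 2000)
  expect_equal(g$start, 11L)
  expect_equal(g$end, 2510L)
  expect_equal(g$length, 2500L)
  # a run of exactly min_len does not qualify (strict inequality)
  s2 <- paste0(strrep("A", 10), strrep("N", 2000), strrep("A", 10))
  expect_equal(nrow(find_assembly_gaps(s2, min_len = 2000)), 0L)
  # two runs are reported in order
  s3 <- paste0(strrep("N", 2100), strrep("A", 100), strrep("N", 3000))
  g3 <- find_assembly_gaps(s3, min_len = 2000)
  expect_equal(g3$start, c(1L, 2201L))
  expect_equal(g3$length, c(2100L, 3000L))
})

test_that("every planted monomer at 2% noise is recovered with family and strand", {
  fams <- make_family_set(family_spec(monomer_length = 300, seed = 41))
  ok <- TRUE
  for (trial in 1:20) {
    g <- with_seed(trial + 500, {
      strands <- sample(c("+", "-"), 3, replace = TRUE)
      plans <- lapply(1:3, function(i)
        array_plan(position = i * 10000,
                   rows = rep(list(c("m1", "m2", "m3")), 2),
                   strand = strands[i], intra_divergence = 0.02,
                   indel_rate = 0))
      generate_genome(genome_spec(40000, arrays = plans,
                                  seed = trial), fams)
    })
    h <- scan_monomers(g$seq, fams)
    tm <- g$truth$monomers
    if (nrow(h) != nrow(tm)) { ok <- FALSE; break }
    matched <- vapply(seq_len(nrow(tm)), function(i) {
      j <- which(abs(h$start - tm$start[i]) < 50)
      length(j) == 1L && h$family[j] == tm$family[i] &&
        h$strand[j] == tm$strand[i]
    }, TRUE)
    if (!all(matched)) { ok <- FALSE; break }
  }
  expect_true(ok)
})
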