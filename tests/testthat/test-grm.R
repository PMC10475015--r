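test_that("K-string histogram matches direct enumeration", {
  # hand-checkable worked case
  d <- grm_histogram("ACGTACGTACGT", grm_config(K = 4))
  expect_equal(d$histogram, data.frame(length = 4, count = 5))

  # all K-mers unique: empty histogram
  expect_equal(nrow(grm_histogram("ACGTTGCA", grm_config(K = 4))$histogram), 0L)

  # sequence shorter than K: empty diagram
  expect_equal(nrow(grm_histogram("ACG", grm_config(K = 12))$histogram), 0L)

  # tandem of a unit with distinct cyclic 10-mers: one bin, 441 intervals
  set.seed(31)
  u <- distinct_cyclic_unit(50, 10)
  d10 <- grm_histogram(strrep(u, 10), grm_config(K = 10))
  expect_equal(d10$histogram, data.frame(length = 50, count = 441))

  # full agreement with the enumeration oracle on mixed random sequences
  set.seed(17)
  for (i in 1:5) {
    s <- paste0(random_dna(1500), strrep(random_dna(40), 8), random_dna(500))
    if (i %% 2 == 0) s <- plant_at(s, strrep("N", 30), 700)
    got <- grm_histogram(s, grm_config(K = 8, max_length = 1000))$histogram
    ref <- grm_brute(s, 8, 1000)
    expect_equal(got$length, ref$length)
    expect_equal(got$count, ref$count)
  }
})

test_that("histogram mass and reverse-complement invariance hold", {
  set.seed(23)
  s <- paste0(random_dna(2000), strrep(random_dna(100), 10), random_dna(1000))
  cfg <- grm_config(K = 12, max_length = 20000)
  h <- grm_histogram(s, cfg)$histogram
  # mass conservation: sum over K-strings of (occurrences - 1)
  wins <- substring(s, 1:(nchar(s) - 11), 12:nchar(s))
  expect_equal(sum(h$count), sum(table(wins) - 1))
  # reflection leaves inter-occurrence distances unchanged
  hrc <- grm_histogram(revcomp(s), cfg)$histogram
  expect_equal(h, hrc)
})

test_that("peak detection merges bins and ranks by count", {
  mkdiag <- function(df) {
    structure(list(histogram = df, K = 12, max_length = 20000,
                   interval = c(1, 1)), class = "grm_diagram")
  }
  # empty in, empty out
  expect_equal(nrow(grm_detect_peaks(mkdiag(
    data.frame(length = numeric(0), count = numeric(0))))), 0L)
  # single bin
  p1 <- grm_detect_peaks(mkdiag(data.frame(length = 4, count = 5)))
  expect_equal(p1$length, 4)
  expect_equal(p1$count, 5)
  # merge rule: 1590 merges into 1600 (within 3%), microsatellite bin stays
  p <- grm_detect_peaks(mkdiag(data.frame(
    length = c(7, 1590, 1600, 3200, 4800),
    count = c(100000, 40, 900, 300, 500))))
  expect_equal(p$length, c(7, 1600, 4800, 3200))
  expect_equal(p$count[p$length == 1600], 940)
  # min_count filter
  pf <- grm_detect_peaks(mkdiag(data.frame(length = c(10, 20),
                                           count = c(3, 50))),
                         grm_config(min_count = 5))
  expect_equal(pf$length, 20)
})

test_that("planted exact tandems produce a peak at exactly the unit length", {
  set.seed(41)
  for (unit in c(20L, 171L, 1600L, 5000L)) {
    u <- random_dna(unit)
    s <- plant_at(random_dna(20000), strrep(u, 6), 9000)
    pk <- grm_detect_peaks(grm_histogram(s, grm_config()))
    expect_true(unit %in% pk$length)
    # monotonicity: one more copy never lowers the unit peak
    s2 <- plant_at(random_dna(20000), strrep(u, 7), 9000)
    pk2 <- grm_detect_peaks(grm_histogram(s2, grm_config()))
    expect_gte(pk2$count[pk2$length == unit], pk$count[pk$length == unit])
  }
})

test_that("HOR signature requires every multiple of the unit length", {
  mkpeaks <- function(lens) {
    structure(data.frame(length = lens, count = 10, prominence = 1),
              class = c("grm_peaks", "data.frame"))
  }
  expect_true(validate_hor_signature(mkpeaks(c(1600, 3210, 4795)), 1600, 3))
  expect_false(validate_hor_signature(mkpeaks(1600), 1600, 3))
  expect_false(validate_hor_signature(mkpeaks(c(1600, 3200)), 1600, 3))

  # planted canonical 3mer HOR array, zero noise
  mono <- make_family_set(family_spec(monomer_length = 400, seed = 9))
  ap <- array_plan(position = 5000, rows = rep(list(c("m1", "m2", "m3")), 10),
                   intra_divergence = 0, indel_rate = 0)
  g <- generate_genome(genome_spec(50000, arrays = list(ap), seed = 10), mono)
  expect_true(validate_hor_signature(grm_histogram(g$seq), 400, 3))
})

test_that("tandem regions are located and their copies extracted", {
  set.seed(53)
  u <- random_dna(50)
  bg <- random_dna(100000)
  s <- plant_at(bg, strrep(u, 100), 40000)
  reg <- locate_tandem_regions(s, grm_config(), min_copies = 3,
                               unit_range = c(20, 200))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$unit_length, 50)
  expect_gte(reg$n_units, 95)

  # pure random background: nothing
  expect_equal(nrow(locate_tandem_regions(random_dna(100000), grm_config(),
                                          min_copies = 3,
                                          unit_range = c(20, 200))), 0L)

  # two arrays 50 kb apart, in order
  s2 <- plant_at(plant_at(bg, strrep(u, 20), 90000), strrep(random_dna(60), 20), 30000)
  reg2 <- locate_tandem_regions(s2, grm_config(), min_copies = 3,
                                unit_range = c(20, 200))
  expect_equal(nrow(reg2), 2L)
  expect_true(reg2$start[1] < reg2$start[2])
  expect_equal(reg2$unit_length, c(60, 50))

  # copy extraction: exact copies are returned verbatim
  cp <- extract_repeat_copies(s, reg[1, ])
  expect_gte(nrow(cp), 95)
  expect_true(all(vapply(cp$seq, nchar, 0L) == 50L))
  # phase is arbitrary but every copy equals a rotation of the unit
  expect_true(all(vapply(cp$seq, function(x)
    grepl(x, paste0(u, u), fixed = TRUE), TRUE)))

  # worked toy example: terminal fragment dropped
  toy <- list(start = 1, end = 12, unit_length = 4, key = "ACGT")
  expect_equal(extract_repeat_copies("ACGTACGTACGT", toy)$seq,
               c("ACGT", "ACGT"))
  expect_error(extract_repeat_copies("AAAA", toy), "key")
})

test_that("copies extracted from a mutated tandem stay near the base unit", {
  set.seed(67)
  u <- random_dna(500)
  copies <- vapply(1:12, function(i) mutate_seq(u, sub_rate = 0.01), "")
  s <- plant_at(random_dna(30000), paste(copies, collapse = ""), 12000)
  reg <- locate_tandem_regions(s, grm_config(), min_copies = 3,
                               unit_range = c(300, 700))
  expect_equal(nrow(reg), 1L)
  cp <- extract_repeat_copies(s, reg[1, ])
  expect_gte(nrow(cp), 8)
  dv <- vapply(cp$seq, function(x)
    rotational_divergence(x, u, orientation = "forward"), 0)
  expect_lt(mean(dv), 0.02)
  expect_true(all(dv < 0.04))
})
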