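test_that("pairwise divergence is the length-normalised edit distance", {
  expect_equal(pairwise_divergence("ACGT", "ACGT"), 0)
  expect_equal(pairwise_divergence("ACGT", "ACGA"), 0.25)
  expect_equal(pairwise_divergence("ACGTACGT", "ACGT"), 0.5)
  expect_error(pairwise_divergence("", "ACGT"), "empty")

  # oracle equivalence against base R's quadratic DP on random pairs
  set.seed(3)
  for (i in 1:25) {
    a <- random_dna(sample(1:200, 1))
    b <- random_dna(sample(1:200, 1))
    expect_equal(pairwise_divergence(a, b),
                 as.numeric(adist(a, b)) / max(nchar(a), nchar(b)))
  }
})

test_that("divergence matrices are symmetric, zero-diagonal and ordered", {
  expect_equal(unclass(divergence_matrix("ACGT"))[1, 1], 0)
  m2 <- divergence_matrix(c(x = "ACGT", y = "ACGT"))
  expect_equal(m2[1, 2], 0)
  expect_equal(rownames(m2), c("x", "y"))

  fams <- make_family_set(family_spec(monomer_length = 400,
                                      inter_family_divergence = 0.25,
                                      seed = 13))
  m <- divergence_matrix(fams)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(diag(unclass(m)), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(m[upper.tri(m)] >= 0.20 & m[upper.tri(m)] <= 0.30))
})

test_that("single-linkage clustering follows the strict threshold rule", {
  # identical copies collapse to one family
  m0 <- divergence_matrix(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_length(cluster_families(m0), 1L)

  # chain a-b-c links through b; the chain diameter is reported
  mchain <- matrix(c(0, .04, .08, .04, 0, .04, .08, .04, 0), 3,
                   dimnames = list(letters[1:3], letters[1:3]))
  class(mchain) <- c("divergence_matrix", class(mchain))
  f <- cluster_families(mchain, cluster_config(0.05))
  expect_length(f, 1L)
  expect_equal(f[[1]]$max_intra_divergence, 0.08)

  # divergence exactly at the threshold does NOT link ("less than 5%")
  mb <- matrix(c(0, .05, .05, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  class(mb) <- c("divergence_matrix", class(mb))
  expect_length(cluster_families(mb, cluster_config(0.05)), 2L)
})

test_that("planted families are recovered with perfect membership", {
  set.seed(29)
  fams <- make_family_set(family_spec(monomer_length = 1600, seed = 29))
  copies <- unlist(lapply(c("m1", "m2", "m3"), function(f)
    vapply(1:5, function(i) mutate_seq(fams[[f]], sub_rate = 0.01), "")))
  truth_lab <- rep(c("m1", "m2", "m3"), each = 5)
  m <- divergence_matrix(copies)
  cl <- cluster_families(m, cluster_config(0.05), seqs = copies)
  expect_length(cl, 3L)
  for (f in cl) {
    expect_length(unique(truth_lab[f$members]), 1L)
    expect_lt(f$max_intra_divergence, 0.05)
  }

  # permutation equivariance: shuffling copies permutes membership only
  perm <- sample(length(copies))
  clp <- cluster_families(divergence_matrix(copies[perm]),
                          cluster_config(0.05))
  part <- function(cl, ids) {
    sets <- lapply(cl, function(f) sort(ids[f$members]))
    sets[order(vapply(sets, function(s) s[1], 0L))]
  }
  expect_equal(part(cl, seq_along(copies)), part(clp, perm))
})

test_that("consensus construction is majority vote over a star alignment", {
  expect_equal(build_consensus("ACGTACGT"), "ACGTACGT")

  # one substitution among three copies is outvoted
  set.seed(37)
  base <- random_dna(1600)
  mut <- paste0(substr(base, 1, 799),
                chartr("ACGT", "CAGT", substr(base, 800, 800)),
                substr(base, 801, 1600))
  expect_equal(build_consensus(c(base, base, mut)), base)

  # 5 copies at 2% divergence: consensus lands within 1% of the base
  copies <- vapply(1:5, function(i) mutate_seq(base, sub_rate = 0.02), "")
  cons <- build_consensus(copies)
  expect_lt(pairwise_divergence(cons, base), 0.01)
  # contract: members sit no farther from the consensus than from each other
  mean_to_cons <- mean(vapply(copies, pairwise_divergence, 0, b = cons))
  mm <- divergence_matrix(copies)
  expect_lte(mean_to_cons, mean(mm[upper.tri(mm)]))
})

test_that("consensus recovery succeeds in at least 19 of 20 seeded runs", {
  ok <- 0L
  for (seed in 1:20) {
    base <- with_seed(seed, random_dna(1600))
    copies <- vapply(1:5, function(i)
      mutate_seq(base, sub_rate = 0.02, seed = seed * 100L + i), "")
    if (pairwise_divergence(build_consensus(copies), base) < 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("phase relabelling rotates labels to the dominant HOR order", {
  # families in scrambled positional order; hits reveal the true phase
  fams <- structure(lapply(1:3, function(i)
    list(label = paste0("m", i), members = i, seqs = "A")),
    class = "monomer_families")
  mkhits <- function(order3, n = 6) {
    starts <- seq(1, by = 100, length.out = 3 * n)
    data.frame(chrom = "c", start = starts, end = starts + 99,
               family = rep(order3, n), strand = "+",
               edits = 0L, divergence = 0)
  }
  # copies read m2 m3 m1 in the draft labels -> m2 becomes the new m1
  rel <- relabel_by_hor_phase(fams, mkhits(c("m2", "m3", "m1"),
                                           n = 4), gap_tol = 1000)
  map <- attr(rel, "relabel")
  expect_equal(unname(map[c("m2", "m3", "m1")]), c("m1", "m2", "m3"))

  # single family: unchanged
  f1 <- structure(fams[1], class = "monomer_families")
  expect_identical(relabel_by_hor_phase(f1, mkhits(c("m1", "m1", "m1"))), f1)

  # two equally frequent orders: warning, labels kept
  h <- rbind(mkhits(c("m1", "m2", "m3"), n = 1),
             within(mkhits(c("m1", "m3", "m2"), n = 1),
                    start <- start + 100000))
  h$end <- h$start + 99
  expect_warning(relabel_by_hor_phase(fams, h, gap_tol = 1000), "phase")
})

test_that("rotational divergence identifies rotated and reflected units", {
  set.seed(43)
  u <- random_dna(300)
  rot <- paste0(substr(u, 101, 300), substr(u, 1, 100))
  expect_equal(rotational_divergence(rot, u), 0)
  expect_equal(rotational_divergence(revcomp(rot), u), 0)
  expect_gt(rotational_divergence(revcomp(rot), u, orientation = "forward"),
            0.3)
  expect_gt(rotational_divergence(random_dna(300), u), 0.3)
})
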