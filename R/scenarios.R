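#' Build a planted HOR scenario
#'
#' Constructs a [genome_spec()] planting one tandem array per entry of
#' `array_totals` into a random background, each array holding the given
#' total number of HOR-copy rows of which `variants_per_array` are variant
#' rows (patterns cycling through m1m3, m1m2, m1 -- all opening with m1 so
#' that planted row boundaries coincide with the label-increase grouping
#' rule), evenly interspersed among canonical m1m2m3 rows.
#'
#' @param array_totals integer vector: copies (canonical + variant) per array.
#' @param variants_per_array integer vector, same length: variant rows per
#'   array.
#' @param strands strand per array (`"+"`/`"-"`).
#' @param background_length random background length in bases.
#' @param sub_rate,indel_rate per-monomer mutation rates applied to every
#'   planted copy.
#' @param gap_runs list of `c(position, length)` N-run insertions.
#' @param seed integer seed (also seeds the family set).
#' @param family a [family_spec()] for the monomer families.
#' @param monomers optional named base-monomer vector overriding the family
#'   set (e.g. a panel shared, or drifted, across several assemblies).
#' @return list with `spec` (the [genome_spec()]), `family` and `monomers`
#'   (named base-monomer vector).
#' @export
hor_scenario <- function(array_totals, variants_per_array, strands,
                         background_length = 2e6, sub_rate = 0.02,
                         indel_rate = 0.005, gap_runs = list(), seed = 42L,
                         family = family_spec(seed = seed), monomers = NULL) {
  stopifnot(length(array_totals) == length(variants_per_array),
            length(array_totals) == length(strands),
            all(variants_per_array <= array_totals))
  if (is.null(monomers)) monomers <- make_family_set(family)
  variant_patterns <- list(c("m1", "m3"), c("m1", "m2"), "m1")
  n <- length(array_totals)
  positions <- round(seq(0.08, 0.88, length.out = max(n, 2L)) *
                       background_length)[seq_len(n)]
  arrays <- lapply(seq_len(n), function(i) {
    t <- array_totals[i]; v <- variants_per_array[i]
    rows <- rep(list(c("m1", "m2", "m3")), t)
    if (v > 0) {
      at <- unique(round(seq(2, max(t - 1, 2), length.out = v)))
      # ensure exactly v distinct slots
      extra <- setdiff(seq(2, t), at)
      while (length(at) < v) { at <- c(at, extra[1]); extra <- extra[-1] }
      at <- sort(at[seq_len(v)])
      for (j in seq_along(at)) {
        rows[[at[j]]] <- variant_patterns[[(j - 1L) %% 3L + 1L]]
      }
    }
    array_plan(position = positions[i], rows = rows, strand = strands[i],
               intra_divergence = sub_rate, indel_rate = indel_rate)
  })
  # background stream decoupled from the family-set stream
  spec <- genome_spec(background_length = background_length,
                      arrays = arrays, gap_runs = gap_runs,
                      seed = seed + 7919L)
  list(spec = spec, family = family, monomers = monomers)
}

#' Desk-scale scenario emulating the T2T-CHM13 chromosome-1 HOR layout
#'
#' Six tandem arrays with 19, 15, 14, 13, 5 and 9 HOR copies (the per-gene
#' copy counts reported for the complete human assembly: four prominent NBPF
#' arrays plus the two novel distal arrays), 11 of the 75 rows being variant
#' copies so that 64 are canonical, two arrays on the minus strand, and one
#' 2.5 kb N-gap between arrays.
#'
#' @param seed integer seed.
#' @param sub_rate,indel_rate per-monomer mutation rates.
#' @param background_length background length in bases.
#' @param monomers optional base-monomer panel shared across assemblies.
#' @return scenario list (see [hor_scenario()]).
#' @export
t2t_like_scenario <- function(seed = 42L, sub_rate = 0.02, indel_rate = 0.005,
                              background_length = 2e6, monomers = NULL) {
  hor_scenario(array_totals = c(19L, 15L, 14L, 13L, 5L, 9L),
               variants_per_array = c(3L, 2L, 2L, 2L, 0L, 2L),
               strands = c("+", "-", "+", "+", "-", "+"),
               background_length = background_length,
               sub_rate = sub_rate, indel_rate = indel_rate,
               gap_runs = list(c(round(0.62 * background_length), 2500)),
               seed = seed, monomers = monomers)
}

#' Desk-scale scenario emulating the hg38.p14 chromosome-1 HOR layout
#'
#' Four prominent arrays with 22, 13, 10 and 14 HOR copies, 7 of the 59 rows
#' variant (52 canonical).
#'
#' @inheritParams t2t_like_scenario
#' @return scenario list (see [hor_scenario()]).
#' @export
hg38_like_scenario <- function(seed = 42L, sub_rate = 0.02, indel_rate = 0.005,
                               background_length = 2e6, monomers = NULL) {
  hor_scenario(array_totals = c(22L, 13L, 10L, 14L),
               variants_per_array = c(3L, 2L, 1L, 1L),
               strands = c("+", "-", "+", "+"),
               background_length = background_length,
               sub_rate = sub_rate, indel_rate = indel_rate,
               gap_runs = list(c(round(0.7 * background_length), 2500)),
               seed = seed, monomers = monomers)
}

#' Desk-scale scenario emulating the Neanderthal (AltaiNea.hg19) HOR layout
#'
#' Four arrays with 16, 13, 12 and 17 HOR copies, 19 of the 58 rows variant
#' (39 canonical) -- the higher variant load mirrors the fragmentary state
#' of the archaic assembly.
#'
#' @inheritParams t2t_like_scenario
#' @return scenario list (see [hor_scenario()]).
#' @export
neanderthal_like_scenario <- function(seed = 42L, sub_rate = 0.02,
                                      indel_rate = 0.005,
                                      background_length = 2e6,
                                      monomers = NULL) {
  hor_scenario(array_totals = c(16L, 13L, 12L, 17L),
               variants_per_array = c(5L, 5L, 4L, 5L),
               strands = c("+", "+", "-", "+"),
               background_length = background_length,
               sub_rate = sub_rate, indel_rate = indel_rate,
               gap_runs = list(c(round(0.5 * background_length), 2500)),
               seed = seed, monomers = monomers)
}

#' Desk-scale scenario emulating the chimpanzee chromosome-1 layout
#'
#' No tandemly organised canonical HOR copies at all: a handful of isolated
#' monomers and a single two-monomer variant copy scattered over the
#' background, mirroring the absence of canonical HORs outside the human
#' lineage.
#'
#' @inheritParams t2t_like_scenario
#' @return scenario list (see [hor_scenario()]).
#' @export
chimp_like_scenario <- function(seed = 42L, sub_rate = 0.02,
                                indel_rate = 0.005,
                                background_length = 1e6, monomers = NULL) {
  family <- family_spec(seed = seed)
  if (is.null(monomers)) monomers <- make_family_set(family)
  positions <- round(c(0.15, 0.3, 0.45, 0.6, 0.75, 0.9) * background_length)
  rows <- list(list("m1"), list("m1"), list(c("m1", "m3")), list("m2"),
               list("m1"), list("m2"))
  arrays <- lapply(seq_along(positions), function(i) {
    array_plan(position = positions[i], rows = rows[[i]], strand = "+",
               intra_divergence = sub_rate, indel_rate = indel_rate)
  })
  spec <- genome_spec(background_length = background_length, arrays = arrays,
                      seed = seed + 7919L)
  list(spec = spec, family = family, monomers = monomers)
}
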