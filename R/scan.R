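#' Configuration for the consensus monomer scan
#'
#' @param max_divergence maximal accepted divergence (edit distance divided
#'   by consensus length), in `(0, 0.5)`.  The default 0.15 comfortably
#'   contains intra-family drift (< 5%) while rejecting cross-family matches
#'   (~25% for the NBPF families).
#' @param min_separation minimal number of bases required between accepted
#'   hits (0 = strict non-overlap).
#' @param max_n_fraction maximal fraction of N bases tolerated inside a hit.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(max_divergence = 0.15, min_separation = 0L,
                        max_n_fraction = 0.1) {
  if (max_divergence <= 0 || max_divergence >= 0.5)
    stop("max_divergence must be in (0, 0.5)")
  if (min_separation < 0) stop("min_separation must be >= 0")
  structure(list(max_divergence = max_divergence,
                 min_separation = as.integer(min_separation),
                 max_n_fraction = max_n_fraction),
            class = "scan_config")
}

#' Scan a sequence with consensus monomers on both strands
#'
#' Semi-global (infix) edit-distance search of every consensus sequence and
#' its reverse complement against the sequence, base by base.  N never
#' matches any base.  Local-minimum candidate loci with divergence at most
#' `max_divergence` are collected across all consensus/strand combinations
#' and resolved greedily by ascending divergence, then ascending start, then
#' family order; accepted hits are mutually non-overlapping (a candidate
#' overlapping an accepted hit by at most 10% of its consensus length is
#' trimmed to abut it, larger overlaps are rejected).  Coordinates are always
#' reported on the forward strand, 1-based closed, sorted by start.
#'
#' @param seq character string over A/C/G/T/N.
#' @param consensus_set named character vector of consensus monomers
#'   (`m1`, `m2`, ...).
#' @param config a [scan_config()].
#' @param chrom sequence name for the output table.
#' @return data frame with columns `chrom`, `start`, `end`, `family`,
#'   `strand`, `edits`, `divergence`.
#' @export
scan_monomers <- function(seq, consensus_set, config = scan_config(),
                          chrom = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(consensus_set), length(consensus_set) >= 1L,
            !is.null(names(consensus_set)))
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      strand = character(0), edits = integer(0),
                      divergence = numeric(0), stringsAsFactors = FALSE)
  fams <- names(consensus_set)
  cand <- list()
  for (fi in seq_along(consensus_set)) {
    cons <- toupper(consensus_set[[fi]])
    m <- nchar(cons)
    if (m > n) {
      warning("consensus ", fams[fi], " longer than sequence; skipped")
      next
    }
    kmax <- floor(config$max_divergence * m)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") cons else revcomp(cons)
      d <- semiglobal_end_dists_cpp(seq, pat, kmax)
      ends <- candidate_ends(d, kmax, window = floor(m / 2))
      if (!length(ends)) next
      loc <- locate_hit_starts_cpp(seq, pat, ends, kmax)
      keep <- loc$edits <= kmax
      if (!any(keep)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = loc$start[keep], end = loc$end[keep],
        family = fams[fi], fi = fi, strand = strand,
        edits = loc$edits[keep],
        divergence = loc$edits[keep] / m, clen = m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$divergence, cand$start, cand$fi), , drop = FALSE]
  taken <- logical(n)
  sep <- config$min_separation
  acc <- vector("list", nrow(cand))
  nacc <- 0L
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    seg <- taken[s:e]
    tol <- 0.1 * cand$clen[i]
    if (any(seg)) {
      # trim a small boundary overlap with already-accepted hits
      free <- which(!seg)
      if (!length(free)) next
      if ((min(free) - 1L) + (length(seg) - max(free)) > tol) next
      e <- s + max(free) - 1L
      s <- s + min(free) - 1L
      if (any(taken[s:e])) next
    }
    nacc <- nacc + 1L
    row <- cand[i, ]
    row$start <- s
    row$end <- e
    acc[[nacc]] <- row
    lo <- max(1L, s - sep)
    hi <- min(n, e + sep)
    taken[lo:hi] <- TRUE
  }
  if (!nacc) return(empty)
  out <- do.call(rbind, acc[seq_len(nacc)])
  # N content filter
  nfrac <- vapply(seq_len(nrow(out)), function(i) {
    sub <- substr(seq, out$start[i], out$end[i])
    lengths(regmatches(sub, gregexpr("N", sub, fixed = TRUE))) / nchar(sub)
  }, 0)
  out <- out[nfrac <= config$max_n_fraction, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  data.frame(chrom = chrom, start = out$start, end = out$end,
             family = out$family, strand = out$strand, edits = out$edits,
             divergence = out$divergence, stringsAsFactors = FALSE,
             row.names = NULL)
}

# local-minimum candidate end positions among dists <= kmax, suppressing
# competitors within +/- window (ascending distance, ties to the left)
candidate_ends <- function(d, kmax, window) {
  ok <- which(d <= kmax)
  if (!length(ok)) return(integer(0))
  ok <- ok[order(d[ok], ok)]
  chosen <- integer(0)
  blocked <- integer(0)
  for (j in ok) {
    if (length(chosen) && any(abs(chosen - j) <= window)) next
    chosen <- c(chosen, j)
  }
  sort(chosen)
}

#' Find assembly gaps (N-runs)
#'
#' Maximal runs of N strictly longer than `min_len`, the classic map of
#' assembly gaps ("N-runs larger than 2000 bp").
#'
#' @param seq character string.
#' @param min_len strict lower bound on run length (bases).
#' @param chrom sequence name for the output.
#' @return data frame with `chrom`, `start`, `end` (1-based closed),
#'   `length`, sorted by start.
#' @export
find_assembly_gaps <- function(seq, min_len = 2000L, chrom = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 1)
  seq <- toupper(seq)
  m <- gregexpr("N+", seq)[[1]]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  keep <- len > min_len
  if (!any(keep)) return(empty)
  data.frame(chrom = chrom, start = as.integer(m[keep]),
             end = as.integer(m[keep]) + len[keep] - 1L,
             length = len[keep], stringsAsFactors = FALSE)
}
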