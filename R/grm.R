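#' Configuration for the K-string repeat spectrum
#'
#' @param K K-string length in bases (4-64; lengths above 32 use a slower
#'   string-keyed path and are unavailable for tandem-region detection).
#' @param min_count minimum summed count for a reported peak.
#' @param peak_merge_radius relative radius for merging neighbouring
#'   histogram bins into one peak (fraction of the peak length).
#' @param max_length largest inter-occurrence distance recorded, in bases.
#' @param min_prominence minimum ratio of a peak's merged count to the mass
#'   expected over its merge window from the local background density; flat
#'   background merged over a wide window must not masquerade as a peak.
#' @return object of class `grm_config`.
#' @export
grm_config <- function(K = 12L, min_count = 5L, peak_merge_radius = 0.03,
                       max_length = 20000L, min_prominence = 3) {
  K <- as.integer(K)
  if (is.na(K) || K < 4L || K > 64L) stop("K must be in [4, 64]")
  if (peak_merge_radius <= 0 || peak_merge_radius >= 0.2)
    stop("peak_merge_radius must be in (0, 0.2)")
  if (max_length < 1) stop("max_length must be positive")
  if (min_prominence < 0) stop("min_prominence must be >= 0")
  structure(list(K = K, min_count = as.integer(min_count),
                 peak_merge_radius = peak_merge_radius,
                 max_length = as.numeric(max_length),
                 min_prominence = min_prominence),
            class = "grm_config")
}

#' Repeat-length spectrum of a sequence (complete K-string ensemble)
#'
#' For every K-length window over A/C/G/T (windows containing N or other
#' letters are skipped), the start-to-start distances between consecutive
#' occurrences of that window are accumulated into a histogram.  Peaks of the
#' histogram mark repeat-unit and HOR lengths: a tandem of ~1.6 kb monomers
#' organised in ~4.8 kb 3mer HOR copies shows peaks at ~1.6, ~3.2 and
#' ~4.8 kb.
#'
#' @param seq character string over A/C/G/T/N.
#' @param config a [grm_config()].
#' @param interval optional 1-based closed `c(start, end)` restricting the
#'   analysed region.
#' @return object of class `grm_diagram`: list with `histogram` (data frame
#'   `length`, `count`), `K`, `max_length` and `interval`.
#' @export
grm_histogram <- function(seq, config = grm_config(), interval = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2L, interval[1] >= 1,
              interval[2] <= nchar(seq), interval[1] <= interval[2])
    seq <- substr(seq, interval[1], interval[2])
  } else {
    interval <- c(1L, nchar(seq))
  }
  hist <- if (nchar(seq) < config$K) {
    data.frame(length = numeric(0), count = numeric(0))
  } else {
    kstring_histogram_cpp(seq, config$K, config$max_length)
  }
  structure(list(histogram = hist, K = config$K,
                 max_length = config$max_length, interval = interval),
            class = "grm_diagram")
}

#' @export
print.grm_diagram <- function(x, ...) {
  cat("K-string repeat spectrum (K =", x$K, ")\n")
  cat("  region:", x$interval[1], "-", x$interval[2], "\n")
  cat("  ", nrow(x$histogram), "distinct distances, total mass",
      sum(x$histogram$count), "\n")
  invisible(x)
}

#' Detect peaks in a repeat-length spectrum
#'
#' Bins within `peak_merge_radius * length` of a local maximum are merged
#' into one peak reported at the modal (highest-count) length; peaks with
#' summed count below `min_count` are dropped.  Peaks are sorted by count
#' (descending), ties by shorter length.
#'
#' @param diagram a [grm_histogram()] result.
#' @param config a [grm_config()].
#' @return data frame (class `grm_peaks`) with columns `length`, `count`,
#'   `prominence` (peak count relative to the local background level).
#' @export
grm_detect_peaks <- function(diagram, config = grm_config()) {
  stopifnot(inherits(diagram, "grm_diagram"))
  h <- diagram$histogram
  if (!nrow(h)) {
    return(structure(data.frame(length = numeric(0), count = numeric(0),
                                prominence = numeric(0)),
                     class = c("grm_peaks", "data.frame")))
  }
  remaining <- h[order(-h$count, h$length), ]
  used <- logical(nrow(remaining))
  peaks <- list()
  for (i in seq_len(nrow(remaining))) {
    if (used[i]) next
    len <- remaining$length[i]
    rad <- config$peak_merge_radius * len
    memb <- !used & abs(remaining$length - len) <= rad
    used[memb] <- TRUE
    count <- sum(remaining$count[memb])
    # prominence: merged mass over the mass expected in the merge window
    # from the local (+/-20%) background density, counting empty bins
    ctx <- !memb & abs(remaining$length - len) <= 0.2 * len
    win_bins <- floor(len + rad) - ceiling(len - rad) + 1
    ctx_bins <- max(floor(1.2 * len) - ceiling(0.8 * len) + 1 - win_bins, 1)
    expected <- sum(remaining$count[ctx]) / ctx_bins * win_bins
    peaks[[length(peaks) + 1L]] <- data.frame(
      length = len, count = count, prominence = count / (expected + 1))
  }
  out <- do.call(rbind, peaks)
  out <- out[out$count >= config$min_count &
               out$prominence >= config$min_prominence, , drop = FALSE]
  out <- out[order(-out$count, out$length), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("grm_peaks", "data.frame"))
}

#' Test a spectrum for an n-multiple HOR signature
#'
#' A sequence carries the signature of an HOR built on unit length `L` when
#' the detected peaks contain every multiple `m * L`, `m = 1..n`, within a
#' relative tolerance (for the ~1.6 kb NBPF monomer with `n = 3`: peaks at
#' ~1.6, ~3.2 and ~4.8 kb).
#'
#' @param diagram a [grm_histogram()] result (or a `grm_peaks` data frame).
#' @param L repeat-unit length in bases.
#' @param n number of multiples required (>= 2).
#' @param tol relative tolerance on each multiple.
#' @param config a [grm_config()] (used when `diagram` is a spectrum).
#' @return `TRUE` iff all `n` multiples are present.
#' @export
validate_hor_signature <- function(diagram, L, n = 3L, tol = 0.05,
                                   config = grm_config()) {
  stopifnot(L > 0, n >= 2)
  peaks <- if (inherits(diagram, "grm_peaks")) diagram
           else grm_detect_peaks(diagram, config)
  if (!nrow(peaks)) return(FALSE)
  all(vapply(seq_len(n), function(m) {
    any(abs(peaks$length - m * L) <= tol * m * L)
  }, TRUE))
}

#' Locate tandem-repeat regions
#'
#' Finds maximal regions in which some K-string recurs with near-constant
#' spacing (coefficient of variation of the spacings <= `cv_max`), with at
#' least `min_copies` occurrences and a modal spacing inside `unit_range`.
#' Overlapping candidate regions with compatible unit lengths (within the
#' peak-merge radius) are merged; the reported key is the K-string of the
#' deepest constituent run, usable with [extract_repeat_copies()].
#'
#' @param seq character string over A/C/G/T/N.
#' @param config a [grm_config()].
#' @param min_copies minimum number of unit copies.
#' @param unit_range `c(min, max)` admissible unit lengths in bases.
#' @param cv_max maximal coefficient of variation of the spacings in a run.
#' @return data frame with columns `start`, `end` (1-based closed),
#'   `unit_length`, `n_units`, `key`, sorted by `start`.
#' @export
locate_tandem_regions <- function(seq, config = grm_config(), min_copies = 3L,
                                  unit_range = c(10, config$max_length),
                                  cv_max = 0.1) {
  stopifnot(is.character(seq), length(seq) == 1L,
            length(unit_range) == 2L, unit_range[1] >= 1,
            unit_range[2] <= config$max_length)
  seq <- toupper(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = numeric(0), n_units = integer(0),
                      key = character(0), stringsAsFactors = FALSE)
  if (nchar(seq) < config$K) return(empty)
  runs <- kstring_tandem_runs_cpp(seq, config$K, as.integer(min_copies),
                                  cv_max, unit_range[1], unit_range[2])
  if (!nrow(runs)) return(empty)
  runs$start <- runs$start + 1 # to 1-based closed
  runs <- runs[order(runs$start, -runs$n_units), , drop = FALSE]
  # merge overlapping runs with compatible units
  out <- list()
  cur <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    r <- runs[i, ]
    compatible <- abs(r$unit - cur$unit) <= config$peak_merge_radius *
      max(r$unit, cur$unit)
    if (r$start <= cur$end && compatible) {
      if (r$n_units > cur$n_units) { cur$n_units <- r$n_units; cur$key <- r$key; cur$unit <- r$unit }
      cur$end <- max(cur$end, r$end)
      cur$start <- min(cur$start, r$start)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- r
    }
  }
  out[[length(out) + 1L]] <- cur
  out <- do.call(rbind, out)
  data.frame(start = as.integer(out$start), end = as.integer(out$end),
             unit_length = out$unit, n_units = as.integer(out$n_units),
             key = out$key, stringsAsFactors = FALSE)
}

#' Extract repeat-unit copies from a tandem region
#'
#' The region is segmented at successive occurrences of its key K-string;
#' fragments between successive key starts are the unit copies.  Fragments
#' whose length falls outside `[0.8, 1.25] * unit_length` (terminal partials,
#' or fused units where the key was destroyed by mutation) are discarded.
#'
#' @param seq the sequence the region was located in.
#' @param region one row of [locate_tandem_regions()] output (or a list with
#'   `start`, `end`, `unit_length`, `key`).
#' @return data frame with `start`, `end` (1-based closed) and `seq` of each
#'   retained copy.
#' @export
extract_repeat_copies <- function(seq, region) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  reg <- substr(seq, region$start, region$end)
  occ <- gregexpr(region$key, reg, fixed = TRUE)[[1]]
  if (occ[1] == -1L) stop("region key not found in region (corrupt region)")
  occ <- as.integer(occ)
  if (length(occ) < 2L) stop("region key occurs fewer than twice (corrupt region)")
  starts <- occ[-length(occ)]
  ends <- occ[-1] - 1L
  len <- ends - starts + 1L
  keep <- len >= 0.8 * region$unit_length & len <= 1.25 * region$unit_length
  data.frame(start = region$start + starts[keep] - 1L,
             end = region$start + ends[keep] - 1L,
             seq = substring(reg, starts[keep], ends[keep]),
             stringsAsFactors = FALSE)
}
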