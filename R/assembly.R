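#' Configuration for HOR copy and array assembly
#'
#' @param intra_copy_gap_tol maximal gap in bases between neighbouring
#'   monomers of one HOR copy (default a quarter monomer length).
#' @param array_gap_tol maximal gap in bases between consecutive HOR copies
#'   of one tandem array (default ~2 canonical HOR lengths; larger gaps are
#'   the "blank space" separating arrays in an aligned scheme).
#' @return object of class `assembly_config`.
#' @export
assembly_config <- function(intra_copy_gap_tol = 400L, array_gap_tol = 10000L) {
  if (intra_copy_gap_tol <= 0 || array_gap_tol <= 0)
    stop("gap tolerances must be positive")
  structure(list(intra_copy_gap_tol = as.integer(intra_copy_gap_tol),
                 array_gap_tol = as.integer(array_gap_tol)),
            class = "assembly_config")
}

#' Group monomer hits into HOR copies
#'
#' Hits are traversed in genomic order, with maximal minus-strand blocks
#' traversed in reverse so that rows read m1 -> m2 -> m3 in gene orientation
#' while coordinates stay on the forward strand.  A new copy starts whenever
#' (a) the family label does not strictly increase, (b) the strand changes,
#' or (c) the gap to the previous monomer exceeds `intra_copy_gap_tol`.  A
#' copy is canonical iff it is exactly (m1, m2, m3).
#'
#' @param hits sorted, non-overlapping hit table from [scan_monomers()].
#' @param config an [assembly_config()].
#' @return data frame of copies with columns `copy`, `chrom`, `start` (first
#'   monomer in gene orientation, the position printed in schemes), `gstart`,
#'   `gend` (genomic span), `strand`, `pattern`, `n_monomers`, `canonical`,
#'   and a list column `families`; the input hits (with a `copy` column) are
#'   attached as attribute `"hits"`.
#' @export
group_hits_into_copies <- function(hits, config = assembly_config()) {
  if (!nrow(hits)) {
    out <- data.frame(copy = integer(0), chrom = character(0),
                      start = integer(0), gstart = integer(0),
                      gend = integer(0), strand = character(0),
                      pattern = character(0), n_monomers = integer(0),
                      canonical = logical(0), stringsAsFactors = FALSE)
    attr(out, "hits") <- hits
    return(out)
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  if (any(hits$start[-1] <= hits$end[-nrow(hits)]))
    stop("input hits overlap")
  tr <- gene_orientation_order(hits$strand)
  h <- hits[tr, , drop = FALSE]
  nh <- nrow(h)
  fam_i <- family_index(h$family)
  if (nh > 1L) {
    prev <- seq_len(nh - 1L)
    gap <- interval_gap(h$start[prev], h$end[prev], h$start[-1], h$end[-1])
    brk <- fam_i[-1] <= fam_i[prev] |
      h$strand[-1] != h$strand[prev] |
      gap > config$intra_copy_gap_tol
    copy <- cumsum(c(1L, as.integer(brk)))
  } else {
    copy <- 1L
  }
  h$copy <- copy
  rows <- split(seq_len(nh), copy)
  copies <- do.call(rbind, lapply(rows, function(idx) {
    fams <- h$family[idx]
    data.frame(copy = h$copy[idx[1]], chrom = h$chrom[idx[1]],
               start = h$start[idx[1]],
               gstart = min(h$start[idx]), gend = max(h$end[idx]),
               strand = h$strand[idx[1]],
               pattern = paste(fams, collapse = ""),
               n_monomers = length(idx),
               canonical = identical(fams, c("m1", "m2", "m3")),
               stringsAsFactors = FALSE)
  }))
  copies$families <- lapply(rows, function(idx) h$family[idx])
  copies <- copies[order(copies$gstart), , drop = FALSE]
  copies$copy <- seq_len(nrow(copies))
  rownames(copies) <- NULL
  # map hit copy ids onto the re-sorted copy numbering
  remap <- stats::setNames(copies$copy, names(rows)[order(
    vapply(rows, function(idx) min(h$start[idx]), 0))])
  hits$copy <- NA_integer_
  hits[tr, "copy"] <- remap[as.character(h$copy)]
  attr(copies, "hits") <- hits
  copies
}

#' Group HOR copies into tandem arrays
#'
#' Maximal runs of copies whose genomic gaps are at most `array_gap_tol`
#' become arrays; isolated monomers therefore end up as single-copy arrays.
#' An array is "prominent" when it contains at least two neighbouring
#' canonical copies in tandem.
#'
#' @param copies copy table from [group_hits_into_copies()] (sorted by
#'   genomic start).
#' @param config an [assembly_config()].
#' @return data frame of arrays (`array`, `chrom`, `start`, `end`,
#'   `n_copies`, `n_canonical`, `prominent`); the copies (with an `array`
#'   column) are attached as attribute `"copies"`.
#' @export
group_copies_into_arrays <- function(copies, config = assembly_config()) {
  if (!nrow(copies)) {
    out <- data.frame(array = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_copies = integer(0), n_canonical = integer(0),
                      prominent = logical(0), stringsAsFactors = FALSE)
    attr(out, "copies") <- copies
    return(out)
  }
  stopifnot(!is.unsorted(copies$gstart))
  nc <- nrow(copies)
  if (nc > 1L) {
    prev <- seq_len(nc - 1L)
    gap <- interval_gap(copies$gstart[prev], copies$gend[prev],
                        copies$gstart[-1], copies$gend[-1])
    arr <- cumsum(c(1L, as.integer(gap > config$array_gap_tol)))
  } else {
    arr <- 1L
  }
  copies$array <- arr
  arrays <- do.call(rbind, lapply(split(seq_len(nc), arr), function(idx) {
    can <- copies$canonical[idx]
    data.frame(array = copies$array[idx[1]], chrom = copies$chrom[idx[1]],
               start = min(copies$gstart[idx]), end = max(copies$gend[idx]),
               n_copies = length(idx), n_canonical = sum(can),
               prominent = length(idx) > 1L && any(can[-length(can)] & can[-1]),
               stringsAsFactors = FALSE)
  }))
  rownames(arrays) <- NULL
  attr(arrays, "copies") <- copies
  arrays
}

#' Tabulate per-array and total HOR copy counts
#'
#' The classic per-assembly report: copies (canonical plus variant) and
#' canonical copies per tandem array, with totals, prominent arrays and
#' scattered groups listed separately.  Optional gene labels (e.g. NBPF20)
#' are user-supplied annotation applied positionally to the prominent arrays
#' in genomic order -- never inferred.
#'
#' @param arrays array table from [group_copies_into_arrays()].
#' @param labels optional character vector of labels for the prominent
#'   arrays; a length mismatch drops the labels with a warning.
#' @return object of class `hor_report`: list with `per_array` (data frame),
#'   `totals` and `prominent_totals` (named vectors).
#' @export
count_report <- function(arrays, labels = NULL) {
  per <- arrays[, c("array", "chrom", "start", "end", "n_copies",
                    "n_canonical", "prominent")]
  per$label <- rep(NA_character_, nrow(per))
  if (!is.null(labels)) {
    idx <- which(per$prominent)
    if (length(labels) != length(idx)) {
      warning("label count does not match the number of prominent arrays; ",
              "labels dropped")
    } else {
      per$label[idx] <- labels
    }
  }
  structure(list(
    per_array = per,
    totals = c(n_copies = sum(per$n_copies),
               n_canonical = sum(per$n_canonical),
               n_arrays = nrow(per)),
    prominent_totals = c(n_copies = sum(per$n_copies[per$prominent]),
                         n_canonical = sum(per$n_canonical[per$prominent]),
                         n_arrays = sum(per$prominent))),
    class = "hor_report")
}

#' @export
print.hor_report <- function(x, ...) {
  cat("HOR copy report:", x$totals[["n_arrays"]], "arrays,",
      x$totals[["n_copies"]], "copies (", x$totals[["n_canonical"]],
      "canonical )\n")
  cat("  prominent arrays:", x$prominent_totals[["n_arrays"]], "with",
      x$prominent_totals[["n_copies"]], "copies (",
      x$prominent_totals[["n_canonical"]], "canonical )\n")
  print(x$per_array, row.names = FALSE)
  invisible(x)
}

#' Assemble monomer hits into HOR copies, arrays and a report
#'
#' Convenience wrapper chaining [group_hits_into_copies()],
#' [group_copies_into_arrays()] and [count_report()].
#'
#' @param hits hit table from [scan_monomers()].
#' @param config an [assembly_config()].
#' @param labels optional prominent-array labels (see [count_report()]).
#' @return object of class `hor_assembly`: list with `hits`, `copies`,
#'   `arrays`, `report`, `config`.
#' @export
hor_assemble <- function(hits, config = assembly_config(), labels = NULL) {
  copies <- group_hits_into_copies(hits, config)
  arrays <- group_copies_into_arrays(copies, config)
  copies <- attr(arrays, "copies")
  report <- count_report(arrays, labels = labels)
  structure(list(hits = attr(copies, "hits") %||% hits,
                 copies = copies, arrays = arrays,
                 report = report, config = config),
            class = "hor_assembly")
}

#' @export
print.hor_assembly <- function(x, ...) {
  cat("HOR assembly of", nrow(x$hits), "monomer hits\n")
  print(x$report)
  invisible(x)
}
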