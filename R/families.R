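#' Divergence between two sequences
#'
#' Unit-cost (Levenshtein) global edit distance divided by the length of the
#' longer sequence.  Symmetric, zero iff the sequences are equal; indels
#' count as single edit operations.
#'
#' @param a,b non-empty character strings.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_divergence("ACGT", "ACGA") # 0.25
pairwise_divergence <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  levenshtein_cpp(toupper(a), toupper(b)) / max(nchar(a), nchar(b))
}

# full divergence matrix for a character vector of sequences
pairwise_divergence_matrix <- function(seqs) {
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  d <- levenshtein_matrix_cpp(toupper(seqs))
  norm <- outer(nchar(seqs), nchar(seqs), pmax)
  m <- d / norm
  dimnames(m) <- NULL
  m
}

#' Divergence matrix over repeat copies
#'
#' @param copies character vector of copy sequences (optionally named), or a
#'   data frame with a `seq` column (as from [extract_repeat_copies()]).
#' @return object of class `divergence_matrix`: symmetric numeric matrix with
#'   zero diagonal, labelled by copy identifier.
#' @export
divergence_matrix <- function(copies) {
  if (is.data.frame(copies)) {
    labels <- if (!is.null(copies$start)) paste0("copy_", copies$start)
              else paste0("copy_", seq_len(nrow(copies)))
    seqs <- copies$seq
  } else {
    seqs <- as.character(copies)
    labels <- names(copies) %||% paste0("copy_", seq_along(copies))
  }
  if (!length(seqs)) stop("at least one copy required")
  m <- pairwise_divergence_matrix(seqs)
  dimnames(m) <- list(labels, labels)
  class(m) <- c("divergence_matrix", class(m))
  m
}

#' Clustering configuration for monomer families
#'
#' @param threshold divergence threshold: copies differing by strictly less
#'   than this fraction are linked (the classic rule is "< 5%").
#' @param linkage only `"single"` is implemented: families are connected
#'   components of the strictly-below-threshold graph.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(threshold = 0.05, linkage = "single") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  linkage <- match.arg(linkage, "single")
  structure(list(threshold = threshold, linkage = linkage),
            class = "cluster_config")
}

#' Cluster repeat copies into monomer families
#'
#' Families are the connected components of the graph with an edge wherever
#' divergence is strictly below the threshold (single linkage).  Families are
#' ordered by their first member (input order, which for copies extracted
#' from a genome is genomic order) and labelled `m1`, `m2`, ... in that
#' order.  Because linkage is single, the maximal intra-family divergence may
#' exceed the threshold along chains; it is therefore reported per family.
#'
#' @param mat a [divergence_matrix()].
#' @param config a [cluster_config()].
#' @param seqs optional character vector of member sequences (stored with
#'   each family, enabling [build_consensus()]).
#' @return list of families, each a list with `label`, `members` (indices
#'   into the matrix order), `labels` (member identifiers) and
#'   `max_intra_divergence`.
#' @export
cluster_families <- function(mat, config = cluster_config(), seqs = NULL) {
  n <- nrow(mat)
  stopifnot(n >= 1L, ncol(mat) == n)
  adj <- mat < config$threshold
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  # order components by first member
  first <- vapply(seq_len(cid), function(k) min(which(comp == k)), 0L)
  ord <- order(first)
  fams <- lapply(seq_along(ord), function(j) {
    k <- ord[j]
    members <- which(comp == k)
    sub <- mat[members, members, drop = FALSE]
    fam <- list(label = paste0("m", j),
                members = members,
                labels = rownames(mat)[members],
                max_intra_divergence = if (length(members) > 1L) max(sub) else 0)
    if (!is.null(seqs)) fam$seqs <- seqs[members]
    fam
  })
  structure(fams, class = "monomer_families")
}

#' @export
print.monomer_families <- function(x, ...) {
  cat(length(x), "monomer families\n")
  for (f in x) {
    cat(sprintf("  %s: %d members, max intra divergence %.4f%s\n", f$label,
                length(f$members), f$max_intra_divergence,
                if (!is.null(f$consensus)) sprintf(", consensus %d bp",
                                                   nchar(f$consensus)) else ""))
  }
  invisible(x)
}

#' Build a column-majority consensus for a family
#'
#' Members are star-aligned (global pairwise alignment) to the medoid member
#' (the one with minimal summed divergence to the rest); insertions relative
#' to the medoid are dropped and every medoid column is called by majority
#' vote over `A/C/G/T/-`.  A gap majority deletes the column; ties between
#' bases are broken alphabetically (A < C < G < T), and a tie between a base
#' and the gap keeps the base.  Deterministic given member order.
#'
#' @param family a single family from [cluster_families()] (with `seqs`), or
#'   a plain character vector of member sequences.
#' @return consensus sequence (character string).
#' @export
build_consensus <- function(family) {
  members <- if (is.character(family)) family else family$seqs
  if (is.null(members) || !length(members)) stop("family has no member sequences")
  members <- toupper(members)
  if (length(members) == 1L) return(members)
  D <- levenshtein_matrix_cpp(members)
  med <- which.min(rowSums(D))
  ref <- members[med]
  w <- nchar(ref)
  mat <- matrix("-", nrow = length(members), ncol = w)
  mat[med, ] <- strsplit(ref, "", fixed = TRUE)[[1]]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  for (i in seq_along(members)[-med]) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(members[i]),
                                        Biostrings::DNAString(ref),
                                        type = "global",
                                        substitutionMatrix = submat,
                                        gapOpening = 1, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    mat[i, ] <- ap[as_ != "-"]
  }
  cons <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "-")))
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    if (identical(winners, "-")) "" else winners[winners != "-"][1]
  })
  paste(cons, collapse = "")
}

#' Cluster copies and build per-family consensus in one step
#'
#' @param copies data frame from [extract_repeat_copies()] (columns `start`,
#'   `end`, `seq`) or a character vector of sequences.
#' @param config a [cluster_config()].
#' @return `monomer_families` list where each family additionally carries
#'   `consensus` and, when available, member coordinates.
#' @export
monomer_families <- function(copies, config = cluster_config()) {
  mat <- divergence_matrix(copies)
  seqs <- if (is.data.frame(copies)) copies$seq else as.character(copies)
  fams <- cluster_families(mat, config, seqs = seqs)
  for (i in seq_along(fams)) {
    fams[[i]]$consensus <- build_consensus(fams[[i]])
    if (is.data.frame(copies)) {
      fams[[i]]$coords <- copies[fams[[i]]$members, c("start", "end"), drop = FALSE]
    }
  }
  fams
}

#' Relabel families to canonical HOR phase
#'
#' Family labels from [cluster_families()] follow first occurrence; within an
#' HOR, however, `m1` is by convention the monomer that opens a copy.  Given
#' a draft scan of the source region, adjacent same-strand hit pairs (in gene
#' orientation) vote for a successor relation between families; if the
#' successor votes describe one dominant cycle through all families, labels
#' are rotated so that the most frequent copy-opening family becomes `m1`
#' and the cycle reads m1 -> m2 -> ... .  With no dominant order the input
#' labels are kept and a warning is emitted.
#'
#' @param families a `monomer_families` list.
#' @param hits draft hit table from [scan_monomers()].
#' @param gap_tol adjacency tolerance in bases between neighbouring monomers
#'   of one copy.
#' @return relabelled `monomer_families` (attribute `relabel` maps old to
#'   new labels).
#' @export
relabel_by_hor_phase <- function(families, hits, gap_tol = 400L) {
  labs <- vapply(families, function(f) f$label, "")
  n <- length(families)
  if (n == 1L) return(families)
  if (!nrow(hits)) {
    warning("no hits; keeping positional labels")
    return(families)
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  # traversal in gene orientation: reverse maximal minus-strand blocks
  tr <- gene_orientation_order(hits$strand)
  h <- hits[tr, , drop = FALSE]
  gap <- interval_gap(h$start[-nrow(h)], h$end[-nrow(h)],
                      h$start[-1], h$end[-1])
  linked <- gap <= gap_tol & h$strand[-1] == h$strand[-nrow(h)]
  succ <- table(factor(h$family[-nrow(h)][linked], levels = labs),
                factor(h$family[-1][linked], levels = labs))
  opener <- table(factor(h$family[c(TRUE, !linked)], levels = labs))
  # dominant successor per family must form one cycle over all families
  nxt <- apply(succ, 1, function(row) {
    mx <- max(row)
    if (mx == 0 || sum(row == mx) > 1L) NA_character_ else names(row)[which.max(row)]
  })
  anchor_n <- max(opener)
  anchors <- names(opener)[opener == anchor_n]
  ok <- !anyNA(nxt) && length(anchors) == 1L
  if (ok) {
    order_labels <- character(n)
    cur <- anchors
    for (i in seq_len(n)) {
      order_labels[i] <- cur
      cur <- nxt[[cur]]
    }
    ok <- !anyNA(order_labels) && !anyDuplicated(order_labels)
  }
  if (!ok) {
    warning("no dominant HOR phase; keeping positional labels")
    return(families)
  }
  mapping <- stats::setNames(paste0("m", seq_len(n)), order_labels)
  out <- families
  for (i in seq_along(out)) out[[i]]$label <- mapping[[out[[i]]$label]]
  out <- out[order(vapply(out, function(f) f$label, ""))]
  attr(out, "relabel") <- mapping
  class(out) <- "monomer_families"
  out
}

# traversal order over hits sorted by start: indices with maximal runs of
# '-' strand reversed, so rows read in gene orientation
gene_orientation_order <- function(strand) {
  n <- length(strand)
  if (!n) return(integer(0))
  r <- rle(strand)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  unlist(lapply(seq_along(r$values), function(b) {
    idx <- starts[b]:stops[b]
    if (r$values[b] == "-") rev(idx) else idx
  }), use.names = FALSE)
}

#' Re-estimate per-family consensus monomers from scan hits
#'
#' For each family in a hit table the hit slices (reverse-complemented on
#' the minus strand so all members share orientation) are star-aligned and
#' majority-voted into a consensus.  The lowest-divergence hits are used,
#' capped at `max_members` per family.  This is how a consensus panel is
#' obtained for an assembly that was annotated by scanning with a foreign
#' (e.g. reference) consensus set.
#'
#' @param seq the scanned sequence.
#' @param hits hit table from [scan_monomers()].
#' @param max_members cap on members per family consensus.
#' @return named character vector of consensus sequences.
#' @export
consensus_from_hits <- function(seq, hits, max_members = 20L) {
  fams <- sort(unique(hits$family))
  if (!length(fams)) stop("no hits to build a consensus from")
  stats::setNames(vapply(fams, function(f) {
    h <- hits[hits$family == f, , drop = FALSE]
    h <- utils::head(h[order(h$divergence, h$start), , drop = FALSE],
                     max_members)
    members <- vapply(seq_len(nrow(h)), function(i) {
      s <- substr(seq, h$start[i], h$end[i])
      if (h$strand[i] == "-") revcomp(s) else s
    }, "")
    build_consensus(members)
  }, ""), fams)
}

#' Divergence up to rotation (and optionally orientation)
#'
#' Tandem-repeat consensus units are defined only up to cyclic rotation (the
#' segmentation phase is arbitrary) and, for a double-stranded genome, up to
#' reverse complement.  This computes the minimal divergence of `a` against
#' any rotation of `b`, by a semi-global search of `a` inside `b` doubled;
#' with `orientation = "both"` the reverse complement of `a` is tried too.
#'
#' @param a,b non-empty sequences (e.g. a discovered and a reference HOR
#'   consensus).
#' @param orientation `"both"` (default) or `"forward"`.
#' @return minimal divergence (edits / `nchar(a)`), capped at 1.
#' @export
rotational_divergence <- function(a, b, orientation = c("both", "forward")) {
  orientation <- match.arg(orientation)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  a <- toupper(a); b <- toupper(b)
  doubled <- paste0(b, b)
  k <- nchar(a) # effectively uncapped
  best <- min(semiglobal_end_dists_cpp(doubled, a, k))
  if (orientation == "both") {
    best <- min(best, min(semiglobal_end_dists_cpp(doubled, revcomp(a), k)))
  }
  min(best / nchar(a), 1)
}

#' Named consensus set from a family list
#'
#' @param families `monomer_families` with consensus sequences.
#' @return named character vector `m1`, `m2`, ... of consensus sequences.
#' @export
consensus_set <- function(families) {
  stats::setNames(vapply(families, function(f) {
    if (is.null(f$consensus)) build_consensus(f) else f$consensus
  }, ""), vapply(families, function(f) f$label, ""))
}
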