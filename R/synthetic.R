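#' Specification of a set of monomer families
#'
#' Describes how many monomer families to simulate, their length and how far
#' apart they sit from each other.  The defaults emulate the three ~1.6 kb
#' NBPF monomer families m1, m2, m3, whose mutual divergence (~25%) is an
#' order of magnitude above the copy-to-copy divergence within a tandem HOR
#' array (<5%).
#'
#' @param n_families number of families (>= 1).
#' @param monomer_length monomer length in bases (>= 20).
#' @param inter_family_divergence target pairwise divergence between family
#'   base monomers, a fraction in `[0, 0.75]`.
#' @param seed integer seed making the family set reproducible.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n_families = 3L, monomer_length = 1600L,
                        inter_family_divergence = 0.25, seed = 1L) {
  n_families <- as.integer(n_families)
  monomer_length <- as.integer(monomer_length)
  if (is.na(n_families) || n_families < 1L) stop("n_families must be >= 1")
  if (is.na(monomer_length) || monomer_length < 20L) stop("monomer_length must be >= 20")
  if (inter_family_divergence < 0 || inter_family_divergence > 0.75)
    stop("inter_family_divergence must be in [0, 0.75]")
  structure(list(n_families = n_families, monomer_length = monomer_length,
                 inter_family_divergence = inter_family_divergence,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate base monomer sequences for a family set
#'
#' Families are derived from a shared random ancestor by independent
#' substitution, with the per-family rate solved so that the expected pairwise
#' divergence equals the target; draws are rejected and redrawn until every
#' measured pairwise divergence (unit-cost edit distance over the longer
#' length) lies within +/-20% (relative) of the target.
#'
#' @param spec a [family_spec()].
#' @return named character vector (`m1`, `m2`, ...) of base monomers.
#' @export
make_family_set <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  n <- spec$n_families
  len <- spec$monomer_length
  d <- spec$inter_family_divergence
  with_seed(spec$seed, {
    anc <- random_dna(len)
    if (n == 1L) return(stats::setNames(anc, "m1"))
    if (d == 0) return(stats::setNames(rep(anc, n), paste0("m", seq_len(n))))
    # expected pairwise divergence of two independently r-substituted copies:
    # 2r(1-r) + (2/3) r^2  =>  solve 2r - (4/3) r^2 = d for the smaller root
    r <- (2 - sqrt(4 - (16 / 3) * d)) / (8 / 3)
    for (try in 1:100) {
      fams <- vapply(seq_len(n), function(i) mutate_seq(anc, sub_rate = r), "")
      dv <- pairwise_divergence_matrix(fams)
      off <- dv[upper.tri(dv)]
      if (all(off >= 0.8 * d & off <= 1.2 * d)) {
        return(stats::setNames(fams, paste0("m", seq_len(n))))
      }
      r <- r * d / mean(off)
    }
    stop("could not realise the requested inter-family divergence")
  })
}

#' Mutate a DNA sequence
#'
#' Per-base independent substitutions (uniform over the three alternative
#' bases) and single-base insertions/deletions.  `indel_rate` is split evenly
#' between insertions and deletions unless `ins_rate`/`del_rate` are given.
#'
#' @param seq character string over A/C/G/T/N.
#' @param sub_rate substitution probability per base, in `[0, 1]`.
#' @param indel_rate combined indel probability per position.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param ins_rate,del_rate explicit per-position insertion/deletion rates.
#' @return mutated sequence.
#' @export
mutate_seq <- function(seq, sub_rate = 0, indel_rate = 0, seed = NULL,
                       ins_rate = indel_rate / 2, del_rate = indel_rate / 2) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (sub_rate < 0 || sub_rate > 1 || ins_rate < 0 || ins_rate > 1 ||
      del_rate < 0 || del_rate > 1)
    stop("mutation rates must be in [0, 1]")
  if (nchar(seq) == 0L) return(seq)
  with_seed(seed, {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(bases)
    hit <- which(stats::runif(n) < sub_rate)
    if (length(hit)) {
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3)
      pick <- sample.int(3L, length(hit), replace = TRUE)
      ci <- match(bases[hit], c("A", "C", "G", "T"))
      ok <- !is.na(ci)
      bases[hit[ok]] <- alt[cbind(pick[ok], ci[ok])]
    }
    del <- stats::runif(n) < del_rate
    ins <- stats::runif(n) < ins_rate
    ins_base <- sample(c("A","C","G","T"), n, replace = TRUE)
    out <- ifelse(del, "", bases)
    out <- ifelse(ins, paste0(out, ins_base), out)
    paste(out, collapse = "")
  })
}

#' Plan one planted HOR array
#'
#' @param position 0-based insertion offset in the background sequence.
#' @param rows list of character vectors of family labels, each row one HOR
#'   copy in gene orientation; labels within a row must be distinct and in
#'   increasing label order (canonical copy: `c("m1","m2","m3")`).
#' @param strand `"+"` or `"-"`; a minus array is written as the reverse
#'   complement of the concatenated rows.
#' @param intra_divergence substitution rate applied to every planted monomer.
#' @param indel_rate single-base indel rate applied to every planted monomer.
#' @return object of class `array_plan`.
#' @export
array_plan <- function(position, rows, strand = "+", intra_divergence = 0.01,
                       indel_rate = 0.001) {
  if (!length(rows)) stop("rows must be non-empty")
  rows <- lapply(rows, as.character)
  for (r in rows) {
    if (length(r) < 1L || length(r) > 3L) stop("each row must have 1-3 monomers")
    idx <- family_index(r)
    if (length(idx) > 1L && any(diff(idx) <= 0))
      stop("row labels must be distinct and in increasing label order")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (intra_divergence < 0 || intra_divergence > 0.1 ||
      indel_rate < 0 || indel_rate > 0.1)
    stop("intra_divergence and indel_rate must be in [0, 0.1]")
  structure(list(position = as.numeric(position), rows = rows, strand = strand,
                 intra_divergence = intra_divergence, indel_rate = indel_rate),
            class = "array_plan")
}

# family label -> sortable index ("m12" -> 12; non-m labels -> factor order)
family_index <- function(labels) {
  i <- suppressWarnings(as.integer(sub("^m", "", labels)))
  if (anyNA(i)) i <- as.integer(factor(labels, levels = sort(unique(labels))))
  i
}

#' Plan a synthetic genome
#'
#' Arrays and N-gap runs are inserted into a random background at the given
#' 0-based offsets (the emitted sequence grows accordingly); insertion points
#' must be distinct and inside the background.
#'
#' @param background_length background length in bases.
#' @param gc_content background GC fraction.
#' @param arrays list of [array_plan()]s.
#' @param gap_runs list of `c(position, length)` N-run insertions
#'   (0-based background offsets).
#' @param seed integer seed.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(background_length, gc_content = 0.5, arrays = list(),
                        gap_runs = list(), seed = 1L) {
  stopifnot(background_length >= 0)
  for (a in arrays) stopifnot(inherits(a, "array_plan"))
  pos <- c(vapply(arrays, function(a) a$position, 0),
           vapply(gap_runs, function(g) as.numeric(g[[1]]), 0))
  if (anyDuplicated(pos)) stop("planted insertion points overlap")
  if (length(pos) && (any(pos < 0) || any(pos > background_length)))
    stop("planted insertion points outside background")
  structure(list(background_length = as.numeric(background_length),
                 gc_content = gc_content, arrays = arrays,
                 gap_runs = gap_runs, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome with exact ground truth
#'
#' Plants the arrays and gap runs of a [genome_spec()] into a random
#' background.  Minus-strand arrays are emitted as the reverse complement of
#' their concatenated rows; the truth records forward-strand coordinates with
#' a strand flag.  All truth coordinates are 1-based closed.
#'
#' @param spec a [genome_spec()].
#' @param monomers named character vector of base monomers (see
#'   [make_family_set()]).
#' @param chrom sequence name used in the truth tables.
#' @return list with `seq` (character), `truth` (list of data frames
#'   `monomers`, `copies`, `arrays`) and `monomers` (the base set).
#' @export
generate_genome <- function(spec, monomers, chrom = "synth") {
  stopifnot(inherits(spec, "genome_spec"), is.character(monomers),
            !is.null(names(monomers)))
  with_seed(spec$seed, {
    bg <- random_dna(spec$background_length, spec$gc_content)
    plants <- c(lapply(spec$arrays, function(a) list(kind = "array", obj = a)),
                lapply(spec$gap_runs, function(g) list(kind = "gap",
                                                       obj = list(position = as.numeric(g[[1]]),
                                                                  length = as.numeric(g[[2]])))))
    if (length(plants)) {
      ord <- order(vapply(plants, function(p) p$obj$position, 0))
      plants <- plants[ord]
    }
    pieces <- character(0)
    mono_rows <- list(); copy_rows <- list(); array_rows <- list()
    cursor_bg <- 0      # background bases consumed so far
    out_len <- 0        # emitted bases so far
    copy_id <- 0L; array_id <- 0L
    for (p in plants) {
      pos <- p$obj$position
      if (pos > cursor_bg) {
        pieces <- c(pieces, substr(bg, cursor_bg + 1, pos))
        out_len <- out_len + (pos - cursor_bg)
        cursor_bg <- pos
      }
      if (p$kind == "gap") {
        pieces <- c(pieces, strrep("N", p$obj$length))
        out_len <- out_len + p$obj$length
        next
      }
      a <- p$obj
      array_id <- array_id + 1L
      block_parts <- character(0)
      rel <- list()  # per-monomer relative intervals within the block
      off <- 0
      for (ri in seq_along(a$rows)) {
        copy_id <- copy_id + 1L
        for (fam in a$rows[[ri]]) {
          if (!fam %in% names(monomers)) stop("unknown family label: ", fam)
          mseq <- mutate_seq(monomers[[fam]], sub_rate = a$intra_divergence,
                             indel_rate = a$indel_rate)
          block_parts <- c(block_parts, mseq)
          rel[[length(rel) + 1L]] <- list(start = off + 1L,
                                          end = off + nchar(mseq),
                                          family = fam, copy = copy_id,
                                          divergence = pairwise_divergence(mseq, monomers[[fam]]))
          off <- off + nchar(mseq)
        }
      }
      block <- paste(block_parts, collapse = "")
      L <- nchar(block)
      if (a$strand == "-") {
        block <- revcomp(block)
        rel <- lapply(rel, function(m) {
          list(start = L - m$end + 1L, end = L - m$start + 1L,
               family = m$family, copy = m$copy, divergence = m$divergence)
        })
      }
      base0 <- out_len
      for (m in rel) {
        mono_rows[[length(mono_rows) + 1L]] <- data.frame(
          chrom = chrom, start = base0 + m$start, end = base0 + m$end,
          family = m$family, strand = a$strand, copy = m$copy,
          array = array_id, divergence = m$divergence,
          stringsAsFactors = FALSE)
      }
      for (ri in seq_along(a$rows)) {
        cid <- copy_id - length(a$rows) + ri
        mm <- Filter(function(m) m$copy == cid, rel)
        ss <- min(vapply(mm, function(m) m$start, 0))
        ee <- max(vapply(mm, function(m) m$end, 0))
        pat <- a$rows[[ri]]
        copy_rows[[length(copy_rows) + 1L]] <- data.frame(
          chrom = chrom, copy = cid, array = array_id,
          start = base0 + ss, end = base0 + ee, strand = a$strand,
          pattern = paste(pat, collapse = ""),
          n_monomers = length(pat),
          canonical = identical(pat, c("m1", "m2", "m3")),
          stringsAsFactors = FALSE)
      }
      array_rows[[length(array_rows) + 1L]] <- data.frame(
        chrom = chrom, array = array_id, start = base0 + 1L, end = base0 + L,
        strand = a$strand, n_copies = length(a$rows),
        n_canonical = sum(vapply(a$rows, function(r)
          identical(r, c("m1", "m2", "m3")), TRUE)),
        stringsAsFactors = FALSE)
      pieces <- c(pieces, block)
      out_len <- out_len + L
    }
    if (cursor_bg < spec$background_length) {
      pieces <- c(pieces, substr(bg, cursor_bg + 1, spec$background_length))
    }
    seq <- paste(pieces, collapse = "")
    empty_mono <- data.frame(chrom = character(), start = integer(),
                             end = integer(), family = character(),
                             strand = character(), copy = integer(),
                             array = integer(), divergence = numeric(),
                             stringsAsFactors = FALSE)
    truth <- list(
      monomers = if (length(mono_rows)) do.call(rbind, mono_rows) else empty_mono,
      copies = if (length(copy_rows)) do.call(rbind, copy_rows) else
        data.frame(chrom = character(), copy = integer(), array = integer(),
                   start = integer(), end = integer(), strand = character(),
                   pattern = character(), n_monomers = integer(),
                   canonical = logical(), stringsAsFactors = FALSE),
      arrays = if (length(array_rows)) do.call(rbind, array_rows) else
        data.frame(chrom = character(), array = integer(), start = integer(),
                   end = integer(), strand = character(), n_copies = integer(),
                   n_canonical = integer(), stringsAsFactors = FALSE))
    truth$monomers <- truth$monomers[order(truth$monomers$start), , drop = FALSE]
    rownames(truth$monomers) <- NULL
    list(seq = seq, truth = truth, monomers = monomers)
  })
}

#' Write ground-truth annotation to BED and JSON
#'
#' BED intervals are 0-based half-open with the strand in column 6; the JSON
#' file mirrors the truth structure losslessly ([read_truth()] restores it).
#'
#' @param truth truth list as returned by [generate_genome()].
#' @param bed_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_truth <- function(truth, bed_path, json_path) {
  mono <- truth$monomers
  bed <- data.frame(chrom = mono$chrom, start = mono$start - 1L, end = mono$end,
                    name = mono$family, score = rep(0L, nrow(mono)),
                    strand = mono$strand)
  con <- file(bed_path, "w")
  if (nrow(bed)) {
    write.table(bed, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  close(con)
  jsonlite::write_json(truth, json_path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(c(bed = bed_path, json = json_path))
}

#' Read ground truth back from JSON
#'
#' @param json_path path written by [write_truth()].
#' @return truth list of data frames.
#' @export
read_truth <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  lapply(x, function(df) as.data.frame(df, stringsAsFactors = FALSE))
}
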