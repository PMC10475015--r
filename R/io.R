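#' Read a FASTA file (optionally gzip-compressed)
#'
#' Sequences are uppercased and every IUPAC ambiguity letter other than N is
#' mapped to N with a warning.  Record ids are the first whitespace-delimited
#' token of each header.
#'
#' @param path path to a FASTA or FASTA.gz file.
#' @return named character vector of sequences over A/C/G/T/N.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  amb <- grepl("[^ACGTN]", seqs)
  if (any(amb)) {
    warning("ambiguity codes other than N mapped to N in: ",
            paste(names(seqs)[amb], collapse = ", "))
    seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# internal: entities data frame -> GRanges (1-based closed input)
entities_to_granges <- function(entities) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(entities))) stop("entities need chrom/start/end")
  if (is.unsorted(entities$start)) stop("entities must be sorted by start")
  gr <- GenomicRanges::GRanges(
    seqnames = entities$chrom,
    ranges = IRanges::IRanges(start = entities$start, end = entities$end),
    strand = entities$strand %||% "*")
  nm <- entities$name %||% entities$family %||% entities$key
  if (!is.null(nm)) gr$name <- as.character(nm)
  gr$score <- as.numeric(entities$score %||% entities$divergence %||% 0)
  gr
}

#' Export entities as BED6
#'
#' Internal 1-based closed coordinates are converted to BED's 0-based
#' half-open convention; the strand goes to column 6.
#'
#' @param entities sorted data frame with `chrom`, `start`, `end` and
#'   optionally `strand`, `name`/`family`, `score`/`divergence`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_bed <- function(entities, path) {
  gr <- entities_to_granges(entities)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export entities as GFF3
#'
#' GFF3 is 1-based inclusive, matching the internal convention directly.
#'
#' @inheritParams export_bed
#' @param type feature type written to column 3.
#' @return the path, invisibly.
#' @export
export_gff3 <- function(entities, path, type = "repeat_region") {
  gr <- entities_to_granges(entities)
  gr$type <- type
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Import a BED6 file to the internal convention
#'
#' @param path BED file path.
#' @return data frame with 1-based closed `start`/`end`, `name`, `score`,
#'   `strand`.
#' @export
import_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
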