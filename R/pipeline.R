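#' Configuration for an end-to-end HOR discovery/annotation run
#'
#' Two modes are supported.  Discovery mode (no consensus supplied) runs the
#' full chain: repeat spectrum, tandem-region location, copy extraction,
#' family clustering, consensus building, phase relabelling, genome scan and
#' HOR assembly.  Scan mode (consensus supplied) skips discovery and scans
#' directly with the given consensus monomers.
#'
#' @param fasta path to the input FASTA (used unless `seq` is given).
#' @param seq input sequence as a character string (overrides `fasta`).
#' @param chrom record id to analyse (default: first record) / name of `seq`.
#' @param region optional 1-based closed `c(start, end)` restriction.
#' @param consensus named character vector of consensus monomers (scan mode).
#' @param consensus_fasta path to a consensus FASTA (scan mode).
#' @param outdir output directory for artifacts; `NULL` writes nothing.
#' @param grm a [grm_config()].
#' @param cluster a [cluster_config()].
#' @param scan a [scan_config()].
#' @param assembly an [assembly_config()].
#' @param unit_range admissible repeat-unit lengths for discovery, bases.
#' @param min_copies minimal tandem copy number for a discovered region.
#' @param min_family_size families with fewer member copies are not used as
#'   scan queries; `NULL` (default) adapts to 10% of the extracted copies
#'   (at least 2), which drops rare junction hybrids while keeping true
#'   families.
#' @param hor_order HOR order checked by the spectrum signature (3 for the
#'   classic 3mer HOR).
#' @param signature_tol relative tolerance of the signature check.
#' @param gap_min_len strict minimal length of reported assembly gaps.
#' @param labels optional gene labels for prominent arrays.
#' @param seed integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed governs any simulated input upstream).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, seq = NULL, chrom = NULL,
                            region = NULL, consensus = NULL,
                            consensus_fasta = NULL, outdir = NULL,
                            grm = grm_config(), cluster = cluster_config(),
                            scan = scan_config(), assembly = assembly_config(),
                            unit_range = c(1200, 2000), min_copies = 5L,
                            min_family_size = NULL, hor_order = 3L,
                            signature_tol = 0.05, gap_min_len = 2000L,
                            labels = NULL, seed = 1L) {
  if (is.null(fasta) && is.null(seq)) stop("either fasta or seq is required")
  if (!is.null(fasta) && !file.exists(fasta)) stop("input not found: ", fasta)
  if (!is.null(consensus_fasta) && !file.exists(consensus_fasta))
    stop("consensus FASTA not found: ", consensus_fasta)
  structure(list(fasta = fasta, seq = seq, chrom = chrom, region = region,
                 consensus = consensus, consensus_fasta = consensus_fasta,
                 outdir = outdir, grm = grm, cluster = cluster, scan = scan,
                 assembly = assembly, unit_range = unit_range,
                 min_copies = as.integer(min_copies),
                 min_family_size = if (!is.null(min_family_size))
                   as.integer(min_family_size),
                 hor_order = as.integer(hor_order),
                 signature_tol = signature_tol,
                 gap_min_len = as.integer(gap_min_len),
                 labels = labels, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the HOR pipeline end to end
#'
#' Executes the stages of [pipeline_config()] in order, optionally persisting
#' every intermediate artifact (spectrum TSV, peak table, gaps BED, consensus
#' FASTA, hits TSV/BED, report JSON, scheme TXT/SVG) plus a run manifest with
#' configuration snapshot and artifact checksums.  Identical configuration
#' and inputs give byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return object of class `hor_pipeline`: list with `chrom`, `gaps`,
#'   `diagram`, `peaks`, `regions`, `families`, `consensus`, `hits`,
#'   `assembly`, `signature`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seq)) {
    seq <- toupper(config$seq)
    chrom <- config$chrom %||% (names(config$seq) %||% "seq")
  } else {
    recs <- read_fasta(config$fasta)
    chrom <- config$chrom %||% names(recs)[1]
    if (!chrom %in% names(recs)) stop("record not found: ", chrom)
    seq <- recs[[chrom]]
  }
  if (!is.null(config$region)) {
    stopifnot(config$region[1] >= 1, config$region[2] <= nchar(seq))
    seq <- substr(seq, config$region[1], config$region[2])
  }
  gaps <- find_assembly_gaps(seq, min_len = config$gap_min_len, chrom = chrom)
  diagram <- grm_histogram(seq, config$grm)
  peaks <- grm_detect_peaks(diagram, config$grm)

  consensus <- config$consensus
  if (is.null(consensus) && !is.null(config$consensus_fasta))
    consensus <- read_fasta(config$consensus_fasta)

  regions <- NULL
  families <- NULL
  if (is.null(consensus)) {
    regions <- locate_tandem_regions(seq, config$grm,
                                     min_copies = config$min_copies,
                                     unit_range = config$unit_range)
    if (!nrow(regions)) stop("discovery mode found no tandem regions in ",
                             chrom, " for the given unit range")
    # one region key fixes the segmentation phase (copies from different
    # regions segment at different, arbitrary phases and would not
    # co-cluster) and then segments the whole sequence, pooling same-phase
    # unit copies from every array while the length filter drops background
    # fragments; among the candidate region keys the one that survives in
    # the most copies genome-wide wins
    cand <- lapply(seq_len(nrow(regions)), function(i)
      extract_repeat_copies(seq, list(start = 1L, end = nchar(seq),
                                      unit_length = regions$unit_length[i],
                                      key = regions$key[i])))
    seed_copies <- cand[[which.max(vapply(cand, nrow, 0L))]]
    seed_fams <- monomer_families(seed_copies, config$cluster)
    # HOR-first refinement: an exact key only recovers the monomer types it
    # is conserved in, so the largest seed family's consensus anchors the
    # HOR period instead, and every anchor-to-anchor span is cut into its
    # hor_order monomer sub-units (the sub-unit phase of a tandem repeat is
    # conventional); this pools same-phase copies of every monomer type
    copies <- hor_phase_slices(seq, seed_fams, config)
    if (is.null(copies)) copies <- seed_copies
    copies <- copies[order(copies$start), , drop = FALSE]
    families <- monomer_families(copies, config$cluster)
    min_fam <- config$min_family_size %||% max(2L, ceiling(0.1 * nrow(copies)))
    keep <- vapply(families, function(f)
      length(f$members) >= min_fam, TRUE)
    families <- structure(families[keep], class = "monomer_families")
    for (i in seq_along(families)) families[[i]]$label <- paste0("m", i)
    if (!length(families)) stop("no monomer family with enough member copies")
    draft <- scan_monomers(seq, consensus_set(families), config$scan,
                           chrom = chrom)
    families <- relabel_by_hor_phase(families, draft,
                                     gap_tol = config$assembly$intra_copy_gap_tol)
    mapping <- attr(families, "relabel")
    hits <- draft
    if (!is.null(mapping)) hits$family <- unname(mapping[hits$family])
    hits <- hits[order(hits$start), , drop = FALSE]
    consensus <- consensus_set(families)
  } else {
    hits <- scan_monomers(seq, consensus, config$scan, chrom = chrom)
  }
  assembly <- hor_assemble(hits, config$assembly, labels = config$labels)
  unit <- stats::median(nchar(consensus))
  signature <- validate_hor_signature(peaks, L = unit, n = config$hor_order,
                                      tol = config$signature_tol)
  result <- structure(list(chrom = chrom, gaps = gaps, diagram = diagram,
                           peaks = peaks, regions = regions,
                           families = families, consensus = consensus,
                           hits = hits, assembly = assembly,
                           signature = signature, manifest = NULL),
                      class = "hor_pipeline")
  if (!is.null(config$outdir)) {
    result$manifest <- write_pipeline_artifacts(result, config)
  }
  result
}

#' @export
print.hor_pipeline <- function(x, ...) {
  cat("HOR pipeline result for", x$chrom, "\n")
  cat("  assembly gaps >", "min length:", nrow(x$gaps), "\n")
  cat("  spectrum peaks:", nrow(x$peaks), "; HOR signature:", x$signature, "\n")
  if (!is.null(x$families)) cat("  families discovered:", length(x$families), "\n")
  print(x$assembly$report)
  invisible(x)
}

# persist artifacts + manifest; returns the manifest
write_pipeline_artifacts <- function(result, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  write.table(result$diagram$histogram, out("diagram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$peaks), out("peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(result$gaps)) export_bed(result$gaps, out("gaps.bed"))
  if (!is.null(result$regions))
    write.table(result$regions, out("regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write_fasta(result$consensus, out("consensus.fa"))
  write.table(result$hits, out("hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(result$hits)) export_bed(result$hits, out("hits.bed"))
  rep <- result$assembly$report
  jsonlite::write_json(list(per_array = rep$per_array,
                            totals = as.list(rep$totals),
                            prominent_totals = as.list(rep$prominent_totals),
                            signature = result$signature),
                       out("report.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_scheme(result$assembly), out("scheme.txt"))
  render_scheme_svg(result$assembly, out("scheme.svg"))
  artifacts <- list.files(config$outdir, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  manifest <- list(
    tool = paste0("horseq ", as.character(utils::packageVersion("horseq"))),
    chrom = result$chrom,
    seed = config$seed,
    config = list(K = config$grm$K, max_length = config$grm$max_length,
                  cluster_threshold = config$cluster$threshold,
                  max_divergence = config$scan$max_divergence,
                  intra_copy_gap_tol = config$assembly$intra_copy_gap_tol,
                  array_gap_tol = config$assembly$array_gap_tol,
                  unit_range = config$unit_range,
                  divergence_normalizer = "max-length",
                  linkage = config$cluster$linkage),
    input = if (!is.null(config$fasta))
      list(path = config$fasta,
           md5 = unname(tools::md5sum(config$fasta))) else
      list(path = NA, md5 = unname(md5_string(result$chrom))),
    artifacts = stats::setNames(
      lapply(artifacts, function(f) unname(tools::md5sum(f))),
      basename(artifacts)),
    stats = list(n_hits = nrow(result$hits),
                 n_copies = nrow(result$assembly$copies),
                 n_arrays = nrow(result$assembly$arrays),
                 n_canonical = unname(result$assembly$report$totals["n_canonical"]),
                 n_gaps = nrow(result$gaps)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# HOR-first monomer slicing: scan with the largest seed family's consensus,
# keep anchor-to-anchor spans close to hor_order units, and cut each span
# into hor_order equal-phase slices (minus-strand anchors are processed on
# the reverse complement so all slices share orientation).  Returns a copy
# data frame, or NULL when too few clean spans exist.
hor_phase_slices <- function(seq, seed_fams, config) {
  sizes <- vapply(seed_fams, function(f) length(f$members), 0L)
  anchor <- seed_fams[[which.max(sizes)]]$consensus
  unit <- nchar(anchor)
  h <- config$hor_order
  hits <- scan_monomers(seq, stats::setNames(anchor, "anchor"), config$scan)
  n <- nchar(seq)
  slices <- character(0)
  gstart <- integer(0)
  for (strand in c("+", "-")) {
    hs <- hits[hits$strand == strand, , drop = FALSE]
    if (nrow(hs) < 2L) next
    if (strand == "-") {
      text <- revcomp(seq)
      st <- sort(n - hs$end + 1L)
    } else {
      text <- seq
      st <- sort(hs$start)
    }
    sp <- diff(st)
    for (i in which(sp >= 0.9 * h * unit & sp <= 1.1 * h * unit)) {
      bnd <- st[i] + round(sp[i] * (0:h) / h)
      for (j in seq_len(h)) {
        slices <- c(slices, substr(text, bnd[j], bnd[j + 1] - 1L))
        gstart <- c(gstart, if (strand == "+") bnd[j]
                    else n - (bnd[j + 1] - 1L) + 1L)
      }
    }
  }
  if (length(slices) < 2L * h) return(NULL)
  data.frame(start = gstart, end = gstart + nchar(slices) - 1L,
             seq = slices, stringsAsFactors = FALSE)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  tools::md5sum(f)
}
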