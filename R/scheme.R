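#' Render an aligned HOR scheme as text
#'
#' One row per HOR copy: the 1-based genomic start position of its first
#' monomer (in gene orientation), a `*` flag for copies that lie in the
#' reverse-complement orientation, and the monomer boxes, with each family in
#' its own column so that m1/m2/m3 line up vertically.  Arrays are separated
#' by a blank line.  Output is deterministic.
#'
#' @param assembly a [hor_assemble()] result.
#' @param file optional path; when given the lines are also written there.
#' @return character vector of lines, invisibly when `file` is given.
#' @export
render_scheme <- function(assembly, file = NULL) {
  stopifnot(inherits(assembly, "hor_assembly"))
  copies <- assembly$copies
  fam_levels <- sort(unique(unlist(copies$families)))
  lines <- character(0)
  if (nrow(copies)) {
    for (ai in unique(copies$array)) {
      sub <- copies[copies$array == ai, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        fams <- sub$families[[i]]
        cells <- vapply(fam_levels, function(f) {
          if (f %in% fams) f else strrep(" ", nchar(f))
        }, "")
        lines <- c(lines, sprintf("%10d%s  %s", sub$start[i],
                                  if (sub$strand[i] == "-") "*" else " ",
                                  paste(cells, collapse = " ")))
      }
      lines <- c(lines, "")
    }
    lines <- lines[-length(lines)]
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Render an aligned HOR scheme as SVG
#'
#' Boxes are coloured by family (m1 orange, m2 light blue, m3 blue, further
#' families grey), one row per copy with its 1-based start position printed
#' in front (bold for reverse-complement copies), and a blank band between
#' arrays.
#'
#' @param assembly a [hor_assemble()] result.
#' @param file output path for the SVG document.
#' @return the file path, invisibly.
#' @export
render_scheme_svg <- function(assembly, file) {
  stopifnot(inherits(assembly, "hor_assembly"))
  copies <- assembly$copies
  fam_levels <- sort(unique(unlist(copies$families)))
  pal <- c(m1 = "#E69F00", m2 = "#9ECAE1", m3 = "#2171B5")
  col <- function(f) if (f %in% names(pal)) pal[[f]] else "#999999"
  rh <- 16; bw <- 46; x0 <- 110
  y <- 10
  body <- character(0)
  if (nrow(copies)) {
    for (ai in unique(copies$array)) {
      sub <- copies[copies$array == ai, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        bold <- if (sub$strand[i] == "-") ' font-weight="bold"' else ""
        body <- c(body, sprintf(
          '<text x="%d" y="%d" text-anchor="end" font-size="11"%s>%d</text>',
          x0 - 10, y + 12, bold, sub$start[i]))
        for (f in sub$families[[i]]) {
          ci <- match(f, fam_levels) - 1L
          body <- c(body, sprintf(
            '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="black"/>',
            x0 + ci * (bw + 4), y, bw, rh, col(f)))
        }
        y <- y + rh + 4
      }
      y <- y + rh # blank band between arrays
    }
  }
  w <- x0 + length(fam_levels) * (bw + 4) + 20
  doc <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   w, y + 10),
           body, "</svg>")
  writeLines(doc, file)
  invisible(file)
}

#' Align several HOR schemes side by side
#'
#' Lays out the text schemes of multiple assemblies in parallel columns,
#' vertically aligning the first copy of each anchor array on a common row
#' across panels while preserving the row order (and blank-line array
#' separation) inside each panel.  With no anchors the panels are simply
#' concatenated with separators.
#'
#' @param assemblies list of [hor_assemble()] results.
#' @param anchors list (one integer vector per assembly, all the same
#'   length) of array ids to use as horizontal anchors, in top-to-bottom
#'   order; `NULL` for plain concatenation.
#' @param names optional panel names.
#' @return character vector of lines.
#' @export
align_panels <- function(assemblies, anchors = NULL, names = NULL) {
  stopifnot(length(assemblies) >= 1L)
  for (a in assemblies) stopifnot(inherits(a, "hor_assembly"))
  panels <- lapply(assemblies, render_scheme)
  if (length(assemblies) == 1L && is.null(anchors)) return(panels[[1]])
  if (is.null(anchors) || !length(anchors[[1]])) {
    out <- character(0)
    for (i in seq_along(panels)) {
      nm <- if (!is.null(names)) names[i] else paste("panel", i)
      out <- c(out, paste0("== ", nm, " =="), panels[[i]], "")
    }
    return(out[-length(out)])
  }
  if (length(anchors) != length(assemblies) ||
      length(unique(lengths(anchors))) != 1L)
    stop("each panel needs the same number of anchor arrays")
  # line index of the first copy of each array within each panel
  first_line <- lapply(assemblies, function(a) {
    copies <- a$copies
    arr <- unique(copies$array)
    n_per <- vapply(arr, function(x) sum(copies$array == x), 0L)
    starts <- cumsum(c(1L, head(n_per + 1L, -1L))) # +1 for blank separators
    stats::setNames(starts, arr)
  })
  padded <- panels
  offsets <- rep(0L, length(panels))
  for (k in seq_along(anchors[[1]])) {
    pos <- vapply(seq_along(panels), function(p) {
      offsets[p] + first_line[[p]][[as.character(anchors[[p]][k])]]
    }, 0L)
    target <- max(pos)
    for (p in seq_along(panels)) {
      need <- target - pos[p]
      if (need > 0L) {
        at <- offsets[p] + first_line[[p]][[as.character(anchors[[p]][k])]]
        padded[[p]] <- append(padded[[p]], rep("", need), after = at - 1L)
        offsets[p] <- offsets[p] + need
      }
    }
  }
  h <- max(lengths(padded))
  width <- max(vapply(padded, function(x) max(nchar(x), 0L), 0L), 20L)
  cols <- lapply(padded, function(x) {
    x <- c(x, rep("", h - length(x)))
    formatC(x, width = width, flag = "-")
  })
  header <- if (!is.null(names)) {
    paste(formatC(names, width = width, flag = "-"), collapse = " | ")
  }
  body <- do.call(function(...) paste(..., sep = " | "), cols)
  c(header, body)
}
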