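#' Pair detected nuclei with single-cell segmentations
#'
#' Each nucleus is assigned to the cell whose region contains its
#' centroid; nuclei whose centroid falls on background stay unassigned and
#' are reported, not fatal. Cells that end up with more than one nucleus
#' are flagged multinucleate (and are excluded from TDP-43 ratio
#' statistics downstream); the pairing kept for such cells is the nucleus
#' list, so QC can inspect them.
#'
#' @param nuclei a [LabelMask-class] of nuclei
#' @param cells a [LabelMask-class] of single-cell regions on the same
#'   frame
#' @return list with `pairs` (data.frame `nucleus`, `cell`),
#'   `unassigned` (nucleus labels), `multinucleate` (cell labels)
#' @export
pairNucleiToCells <- function(nuclei, cells) {
  nd <- nuclei@data; cd <- cells@data
  if (!all(dim(nd) == dim(cd))) stop("masks are not on the same frame")
  nIds <- sort(unique(nd[nd > 0L]))
  pairs <- data.frame(nucleus = integer(), cell = integer())
  unassigned <- integer()
  for (k in nIds) {
    w <- which(nd == k, arr.ind = TRUE)
    ctr <- round(colMeans(w))
    cell <- cd[ctr[1], ctr[2]]
    if (cell == 0L) unassigned <- c(unassigned, k)
    else pairs <- rbind(pairs, data.frame(nucleus = k, cell = cell))
  }
  multi <- as.integer(names(which(table(pairs$cell) > 1L)))
  list(pairs = pairs, unassigned = unassigned, multinucleate = multi)
}

#' Nuclear versus cytoplasmic TDP-43 partitioning
#'
#' Computes the mean antibody intensity over the nucleus and over the
#' cytoplasm (cell region minus nucleus) and reports their ratio
#' cytoplasm / nucleus. Means, not integrated intensities, so the ratio is
#' independent of compartment areas and invariant under any positive
#' rescaling of the antibody channel.
#'
#' @param cellMask logical matrix: the single-cell region
#' @param nucleusMask logical matrix: its nucleus (must lie inside the
#'   cell region)
#' @param antibody the (background-subtracted) antibody [Frame-class]
#' @return data.frame: `nuclearMean`, `cytoplasmMean`, `ratio`
#' @export
measureTdp43 <- function(cellMask, nucleusMask, antibody) {
  if (any(nucleusMask & !cellMask))
    stop("pairing error: nucleus not contained in cell region")
  cyto <- cellMask & !nucleusMask
  if (!any(cyto)) stop("geometry error: empty cytoplasm")
  if (!any(nucleusMask)) stop("geometry error: empty nucleus")
  img <- antibody@data
  nuc <- mean(img[nucleusMask])
  cy <- mean(img[cyto])
  if (nuc <= 0) stop("nuclear mean intensity must be > 0")
  data.frame(nuclearMean = nuc, cytoplasmMean = cy, ratio = cy / nuc)
}

#' Per-cell TDP-43 ratios for a whole segmented field
#'
#' Convenience wrapper: pairs nuclei to cells, drops unassigned nuclei and
#' multinucleate cells (reported in the QC component), and emits one
#' [measureTdp43()] row per surviving cell.
#'
#' @param cells,nuclei [LabelMask-class] masks of the field
#' @param antibody antibody [Frame-class]
#' @return list with `ratios` (data.frame `cell`, `nuclearMean`,
#'   `cytoplasmMean`, `ratio`) and `qc` (the pairing report)
#' @export
measureFieldTdp43 <- function(cells, nuclei, antibody) {
  pairing <- pairNucleiToCells(nuclei, cells)
  ok <- pairing$pairs[!pairing$pairs$cell %in% pairing$multinucleate, ,
                      drop = FALSE]
  rows <- lapply(seq_len(nrow(ok)), function(i) {
    cm <- cells@data == ok$cell[i]
    nm <- nuclei@data == ok$nucleus[i] & cm
    if (!any(nm) || all(cm == nm)) return(NULL)
    r <- tryCatch(measureTdp43(cm, nm, antibody), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    cbind(data.frame(cell = ok$cell[i]), r)
  })
  list(ratios = do.call(rbind, rows), qc = pairing)
}
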