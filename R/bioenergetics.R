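#' Correct and normalize extracellular-flux wells
#'
#' Per well: the post-inhibitors phase mean (non-mitochondrial OCR /
#' non-glycolytic ECAR) is subtracted from every OCR / ECAR measurement;
#' wells where any corrected phase mean is negative are discarded with
#' the reason `"negative corrected rate"`; surviving values are divided
#' by the well's cell count. After correction the post-inhibitors phase
#' mean is exactly zero.
#'
#' @param wells long data.frame: `well`, `line`, `cycle`, `phase`,
#'   `OCR`, `ECAR`, `cell_count` with phases `baseline`,
#'   `post-oligomycin`, `post-FCCP`, `post-inhibitors`
#' @return list: `wells` (corrected, normalized), `rejected` (data.frame
#'   `well`, `reason`)
#' @export
correctFlux <- function(wells) {
  phases <- c("baseline", "post-oligomycin", "post-FCCP",
              "post-inhibitors")
  missing <- setdiff(phases, unique(wells$phase))
  if (length(missing))
    stop("protocol error: missing phase(s) ",
         paste(missing, collapse = ", "))
  out <- list(); rej <- list()
  for (w in split(wells, wells$well)) {
    if (any(w$cell_count <= 0)) stop("non-positive cell count")
    inh <- w$phase == "post-inhibitors"
    if (!any(inh)) stop("protocol error: well without post-inhibitors")
    w$OCR <- w$OCR - mean(w$OCR[inh])
    w$ECAR <- w$ECAR - mean(w$ECAR[inh])
    pm <- tapply(w$OCR, w$phase, mean)
    pe <- tapply(w$ECAR, w$phase, mean)
    core <- setdiff(phases, "post-inhibitors")
    if (any(pm[core] < 0) || any(pe[core] < 0)) {
      rej[[length(rej) + 1L]] <-
        data.frame(well = w$well[1], reason = "negative corrected rate")
      next
    }
    w$OCR <- w$OCR / w$cell_count
    w$ECAR <- w$ECAR / w$cell_count
    out[[length(out) + 1L]] <- w
  }
  list(wells = if (length(out)) do.call(rbind, out) else
         wells[0, , drop = FALSE],
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(well = character(), reason = character()))
}

#' Derive mito-stress-test parameters per well and per line
#'
#' From corrected, cell-normalized wells: basal OCR = baseline-phase
#' mean, maximal OCR = post-FCCP mean, oligomycin-sensitive
#' (ATP-linked) OCR = basal - post-oligomycin mean, spare capacity =
#' maximal - basal (exactly, by construction), baseline ECAR, and the
#' OCR/ECAR ratio computed per well (basal OCR over baseline ECAR) and
#' then averaged, respecting well pairing. Line aggregates are mean and
#' SEM across wells.
#'
#' @param corrected the `wells` element of [correctFlux()]
#' @param statistic `"mean"` over the phase's cycles or `"last"` cycle
#' @return list: `perWell` (one row per well) and `perLine` (mean/SEM/n
#'   per parameter per line)
#' @export
deriveParams <- function(corrected, statistic = c("mean", "last")) {
  statistic <- match.arg(statistic)
  if (nrow(corrected) == 0L)
    stop("zero surviving wells: all replicates rejected")
  stat <- function(v) if (statistic == "mean") mean(v) else v[length(v)]
  perWell <- do.call(rbind, lapply(split(corrected, corrected$well),
    function(w) {
      ph <- function(p, col) stat(w[[col]][w$phase == p])
      basal <- ph("baseline", "OCR")
      maximal <- ph("post-FCCP", "OCR")
      oligo <- basal - ph("post-oligomycin", "OCR")
      ecar <- ph("baseline", "ECAR")
      data.frame(well = w$well[1], line = w$line[1], basalOCR = basal,
                 maximalOCR = maximal, oligoSensitiveOCR = oligo,
                 spareCapacity = maximal - basal, baselineECAR = ecar,
                 ocrEcarRatio = if (ecar > 0) basal / ecar else NA_real_)
    }))
  rownames(perWell) <- NULL
  params <- c("basalOCR", "maximalOCR", "oligoSensitiveOCR",
              "spareCapacity", "baselineECAR", "ocrEcarRatio")
  perLine <- do.call(rbind, lapply(split(perWell, perWell$line),
    function(L) {
      do.call(rbind, lapply(params, function(p) {
        v <- L[[p]][is.finite(L[[p]])]
        data.frame(line = L$line[1], parameter = p, mean = mean(v),
                   sem = if (length(v) > 1) sem(v) else NA_real_,
                   n = length(v))
      }))
    }))
  rownames(perLine) <- NULL
  list(perWell = perWell, perLine = perLine)
}

#' PercevalHR 490/405 ratio trace and phase summaries
#'
#' Pointwise ratio of the 490 nm over the 405 nm excitation series (the
#' ATP/ADP proxy), split into steady-state, post-oligomycin and post-2DG
#' phases at the injection times.
#'
#' @param series490,series405 aligned numeric vectors
#' @param times sample times (min)
#' @param injections injection times (min): oligomycin then 2DG
#' @return list: `trace` (data.frame `time`, `ratio`), `phaseMeans`
#'   (named: steady-state, post-oligomycin, post-2DG)
#' @export
percevalRatio <- function(series490, series405, times,
                          injections = c(5, 15)) {
  if (length(series490) != length(series405) ||
      length(series490) != length(times))
    stop("series must be aligned and of equal length")
  if (any(series405 <= 0)) stop("signal error: non-positive 405 values")
  ratio <- series490 / series405
  phase <- cut(times, c(-Inf, injections, Inf),
               labels = c("steady-state", "post-oligomycin", "post-2DG"),
               right = FALSE)
  list(trace = data.frame(time = times, ratio = ratio, phase = phase),
       phaseMeans = tapply(ratio, phase, mean))
}

#' MitoSOX signal-increase slope per cell
#'
#' Ordinary least-squares slope of intensity against time for each cell,
#' reported per hour. Negative slopes are flagged in the QC column
#' (photobleaching, not corrected).
#'
#' @param series long data.frame: `cell`, `time` (min), `intensity`
#' @return data.frame: `cell`, `slope` (intensity/h), `negativeSlope`
#' @export
mitosoxSlope <- function(series) {
  do.call(rbind, lapply(split(series, series$cell), function(s) {
    if (nrow(s) < 3L) stop("need >= 3 timepoints per cell")
    th <- s$time / 60
    b <- stats::cov(th, s$intensity) / stats::var(th)
    data.frame(cell = s$cell[1], slope = b, negativeSlope = b < 0)
  }))
}
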