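.onLoad <- function(libname, pkgname) {
  # default pipeline stages; callers can register more
  registerStage("simulate", function(config, inputs) {
    spec <- inputs$spec %||% sceneSpec(seed = config$seed %||% 1L)
    scene <- generateCultureImage(spec)
    if (!is.null(config$outDir)) {
      dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
      writeImageStack(scene$frames,
                      file.path(config$outDir, "culture.tif"))
      writeRecords(scene$truth, file.path(config$outDir, "truth.csv"))
    }
    list(truth = scene$truth, scene = scene)
  })
  registerStage("segment", function(config, inputs) {
    frame <- inputs$frame
    if (is.null(frame)) stop("validation error: missing channel 'frame'")
    params <- inputs$params %||% detectionParams()
    mask <- detectBlobs(subtractBackground(frame), params)
    k <- objectCount(mask)
    cells <- if (k == 0L)
      data.frame(label = integer(), area = numeric())
    else {
      px <- pixelSize(mask)
      data.frame(label = seq_len(k),
                 area = as.numeric(table(factor(mask@data[mask@data > 0],
                                                levels = seq_len(k)))) *
                   px^2)
    }
    if (!is.null(config$outDir)) {
      dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
      writeRecords(cells, file.path(config$outDir, "cells.csv"))
    }
    list(cells = cells, mask = mask)
  })
  invisible()
}
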