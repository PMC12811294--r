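#' Simulate a survival cohort of tracked iMN
#'
#' Draws one survival record per simulated cell. Event (death) times are
#' exponential with rate `baselineHazard * exp(logHR)` measured from the
#' cell's entry (recognition) day; cells still alive at `finalDay` are
#' administratively censored there, so every record satisfies
#' `end <= finalDay` and `event == 0` whenever `end == finalDay`.
#'
#' @param cohort a [CohortSpec-class]
#' @return data.frame with columns `cellId`, `group`, `start` (entry day),
#'   `end` (death or censoring day), `time` (= end - start) and `event`
#'   (1 = death observed, 0 = censored)
#' @examples
#' rec <- generateSurvivalCohort(cohortSpec(seed = 3))
#' head(rec)
#' @export
generateSurvivalCohort <- function(cohort) {
  validObject(cohort)
  withSeed(cohort@seed, {
    g <- cohort@groups
    out <- lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      entry <- if (length(cohort@entryDays) == 1L)
        rep(cohort@entryDays, n)
      else sample(cohort@entryDays, n, replace = TRUE)
      rate <- cohort@baselineHazard * exp(g$logHR[i])
      dur <- rexp(n, rate)
      end <- pmin(entry + dur, cohort@finalDay)
      data.frame(group = g$name[i], start = entry, end = end,
                 time = end - entry,
                 event = as.integer(entry + dur <= cohort@finalDay))
    })
    out <- do.call(rbind, out)
    out$cellId <- seq_len(nrow(out))
    out[, c("cellId", "group", "start", "end", "time", "event")]
  })
}
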