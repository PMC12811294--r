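#' Kaplan-Meier survival curves
#'
#' Product-limit estimate per group from start-end-censor records
#' (duration = `end - start`, or a `time` column when present). The curve
#' starts at 1, is non-increasing, and censored records reduce the risk
#' set without a step.
#'
#' @param records data.frame with `time` (or `start`/`end`), `event`, and
#'   optionally `group`
#' @return data.frame: `group`, `time`, `nRisk`, `nEvent`, `surv`
#' @examples
#' km <- kaplanMeier(data.frame(time = c(2, 4, 6), event = 1))
#' km$surv   # 2/3, 1/3, 0
#' @export
kaplanMeier <- function(records) {
  records <- normaliseRecords(records)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = records)
  s <- summary(fit, censored = FALSE)
  grp <- if (is.null(s$strata)) rep(records$group[1], length(s$time))
    else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, nRisk = s$n.risk,
             nEvent = s$n.event, surv = s$surv)
}

normaliseRecords <- function(records) {
  if (is.null(records$time)) {
    if (is.null(records$start) || is.null(records$end))
      stop("records need either time or start/end columns")
    records$time <- records$end - records$start
  }
  if (any(records$time < 0)) stop("negative durations")
  if (is.null(records$group)) records$group <- "all"
  records$group <- factor(records$group)
  records
}

#' Pairwise logrank tests between groups
#'
#' The logrank chi-square (1 df) for every pair of groups, with raw and
#' multiplicity-adjusted p values (Bonferroni by default).
#'
#' @param records SurvivalRecord data.frame with a `group` column
#' @param adjust a [stats::p.adjust] method
#' @return data.frame: `groupA`, `groupB`, `chisq`, `p`, `pAdj`
#' @export
pairwiseLogrank <- function(records, adjust = "bonferroni") {
  records <- normaliseRecords(records)
  groups <- levels(records$group)
  if (length(groups) < 2L) stop("need >= 2 groups")
  sizes <- table(records$group)
  if (any(sizes == 0)) stop("group with zero observations")
  combs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    sub <- records[records$group %in% combs[, k], , drop = FALSE]
    sub$group <- droplevels(sub$group)
    if (sum(sub$event) == 0 ||
        length(unique(sub$group)) < 2L) {
      chisq <- 0; p <- 1
    } else {
      sd <- survival::survdiff(
        survival::Surv(time, event) ~ group, data = sub)
      chisq <- sd$chisq
      p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    }
    data.frame(groupA = combs[1, k], groupB = combs[2, k],
               chisq = chisq, p = p)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Breslow tie handling (Efron by
#' flag), reporting per-covariate log hazard ratios, standard errors from
#' the inverse information, 95% confidence intervals on the log scale
#' (estimate +/- 1.96 SE) and a convergence flag. The default model uses
#' the `group` column with `reference` as baseline; any extra covariate
#' columns can be named.
#'
#' @param records SurvivalRecord data.frame
#' @param covariates character vector of extra covariate columns
#' @param reference reference group level
#' @param ties `"breslow"` (default) or `"efron"`
#' @return data.frame of class `HazardFit`: `term`, `logHR`, `se`,
#'   `ciLow`, `ciHigh`, `z`, `p`, plus attributes `loglik` and
#'   `converged`
#' @export
coxPH <- function(records, covariates = character(),
                  reference = NULL, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  records <- normaliseRecords(records)
  if (sum(records$event) < 1L) stop("need >= 1 event")
  if (!is.null(reference))
    records$group <- stats::relevel(records$group, ref = reference)
  terms <- c(if (nlevels(records$group) > 1L) "group", covariates)
  if (!length(terms)) stop("no non-constant covariates")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = records, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  est <- coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(term = names(est), logHR = unname(est),
                    se = unname(se),
                    ciLow = unname(est - 1.96 * se),
                    ciHigh = unname(est + 1.96 * se),
                    z = unname(est / se),
                    p = unname(2 * pnorm(-abs(est / se))))
  attr(out, "loglik") <- fit$loglik[length(fit$loglik)]
  conv <- is.finite(est) & se < 1e3
  attr(out, "converged") <- all(conv)
  if (!all(conv))
    warning("monotone likelihood suspected; estimates unreliable")
  class(out) <- c("HazardFit", class(out))
  out
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' The per-cell phenotype test of the pipeline: a one-way ANOVA over all
#' groups, followed by Dunnett-adjusted comparisons of every other group
#' against the control (multivariate-t family adjustment, evaluated by
#' seeded Monte-Carlo integration, so results are reproducible).
#'
#' @param values numeric measurements
#' @param group group labels
#' @param control the control group label
#' @param seed seed for the multivariate-t integration
#' @return list: `F` (overall F statistic), `pOverall`, `comparisons`
#'   (data.frame `group`, `estimate`, `pAdj`), `means` (per-group mean,
#'   sd, n)
#' @export
anovaDunnett <- function(values, group, control, seed = 1L) {
  group <- factor(group)
  if (!control %in% levels(group))
    stop("control group '", control, "' not present")
  if (any(table(group) < 2L)) stop("each group needs n >= 2")
  group <- stats::relevel(group, ref = control)
  dat <- data.frame(y = values, g = group)
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  means <- do.call(rbind, lapply(split(values, group), function(v)
    data.frame(mean = mean(v), sd = sd(v), n = length(v))))
  means$group <- rownames(means)
  comparisons <- withSeed(seed, {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    s <- summary(gl)
    data.frame(group = sub(" - .*$", "", names(s$test$coefficients)),
               estimate = as.numeric(s$test$coefficients),
               pAdj = as.numeric(s$test$pvalues))
  })
  list(F = an[["F value"]][1], pOverall = an[["Pr(>F)"]][1],
       comparisons = comparisons, means = means)
}
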