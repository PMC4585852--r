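#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator via [survival::survfit()]:
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times.
#' With censored-only data the curve stays at 1.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame: `time`, `n_risk`, `n_event`, `surv` (one row per
#'   distinct observed time).
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one subject required")
  if (any(time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected event counts over the shared risk sets with
#' the hypergeometric variance term, via [survival::survdiff()]; p from
#' chi-square with 1 df. With no events at all the test is undefined and
#' reported as `NA`. The statistic is symmetric in group labels; the
#' sign of `obs_minus_exp` (for group B) says which group had more
#' events than expected, i.e. worse survival.
#'
#' @param timeA,eventA,timeB,eventB per-group follow-up and event flags.
#' @return list: `chisq`, `p`, `obs_minus_exp` (group B).
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (!length(timeA) || !length(timeB))
    stop("both groups must be non-empty")
  if (sum(eventA) + sum(eventB) == 0) {
    message("no events; log-rank undefined")
    return(list(chisq = NA_real_, p = NA_real_,
                obs_minus_exp = NA_real_))
  }
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c("A", "B"), c(length(timeA), length(timeB)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chisq = sd_$chisq,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       obs_minus_exp = unname(sd_$obs - sd_$exp)[2])
}

#' RESTORE-concordance of prognostic association
#'
#' Dichotomizes each RESTORE gene's cohort expression at the cohort
#' median (high = above the median) and runs a per-gene log-rank test.
#' A gene is concordant when its prognostic direction matches the
#' expression state that would trigger the compensation seen in the cell
#' lines: RESTORE_DOWN genes with the high-expression group showing
#' worse survival at `p < alpha`, RESTORE_UP genes with the
#' low-expression group worse. Constant-expression genes are skipped
#' with a warning. The summary is the concordant fraction of all tested
#' RESTORE genes.
#'
#' @param calls data.frame from [restoreCalls()] (only RESTORE classes
#'   are used).
#' @param cohort list `time`, `event`, `expr` from
#'   [readSurvivalCohort()] or [simulateCohort()].
#' @param alpha per-gene significance level (unadjusted by default).
#' @param adjust apply BH across genes before thresholding.
#' @return list: `per_gene` (gene_id, class, worse_group, p,
#'   concordant), `fraction_concordant`, `n_restore`.
#' @export
restorePrognosisConcordance <- function(calls, cohort, alpha = 0.05,
                                        adjust = FALSE) {
  calls <- calls[calls$class %in% c("RESTORE_UP", "RESTORE_DOWN"), ]
  missing_genes <- setdiff(calls$gene_id, rownames(cohort$expr))
  if (length(missing_genes))
    stop("cohort does not cover gene: ", missing_genes[1])
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    g <- calls$gene_id[i]
    x <- cohort$expr[g, ]
    if (stats::sd(x) == 0) {
      warning("constant expression, gene skipped: ", g)
      return(NULL)
    }
    high <- x > stats::median(x)
    lr <- logrankTest(cohort$time[!high], cohort$event[!high],
                      cohort$time[high], cohort$event[high])
    worse <- if (is.na(lr$obs_minus_exp)) NA_character_ else
      if (lr$obs_minus_exp > 0) "high" else "low"
    data.frame(gene_id = g, class = calls$class[i], worse_group = worse,
               p = lr$p, stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene)) return(list(per_gene = NULL,
                                     fraction_concordant = NA_real_,
                                     n_restore = 0L))
  p_use <- if (adjust) stats::p.adjust(per_gene$p, "BH") else per_gene$p
  per_gene$concordant <- !is.na(p_use) & p_use < alpha &
    ((per_gene$class == "RESTORE_DOWN" & per_gene$worse_group == "high") |
       (per_gene$class == "RESTORE_UP" & per_gene$worse_group == "low"))
  list(per_gene = per_gene,
       fraction_concordant = mean(per_gene$concordant),
       n_restore = nrow(per_gene))
}
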