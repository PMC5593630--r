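# The study's statistical suite: nonparametric group comparisons, ordinal
# trend tests, Pearson correlations, quartile stratification, Kaplan-Meier /
# log-rank survival, and the orchestrating association report.

test_result <- function(test, statistic, p_value, n, direction = NA_real_,
                        note = NA_character_) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n = n,
                 direction = sign(direction), note = note),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n = %s)%s\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (!is.na(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

# Exact two-sided rank-sum p-value by enumeration of all C(n1+n2, n1)
# assignments of the pooled ranks (handles ties; the permutation distribution
# of the rank sum is symmetric, so the tail rule matches the usual doubling).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * mean(r) # n1 * (n+1)/2 without ties; mean(r) is robust to ties
  combos <- utils::combn(length(pooled), n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

#' Compare score distributions between groups
#'
#' `rank_sum`: two unpaired groups, Wilcoxon rank sum; exact p by enumeration
#' when both groups have <= 10 samples, normal approximation with tie and
#' continuity correction otherwise. `signed_rank`: paired samples keyed by
#' `patient_id`. `anova`: one-way ANOVA across >= 2 groups.
#'
#' @param scores numeric vector.
#' @param labels group labels aligned with `scores` (2 levels for
#'   `rank_sum`/`signed_rank`, >= 2 for `anova`).
#' @param test one of `"rank_sum"`, `"signed_rank"`, `"anova"`.
#' @param patient_id for `signed_rank`: pairing key; every patient must
#'   appear exactly once per group.
#' @return a `TestResult`. `direction` is the sign of (group2 - group1)
#'   location difference, groups ordered by their factor levels.
#' @export
compare_groups <- function(scores, labels,
                           test = c("rank_sum", "signed_rank", "anova"),
                           patient_id = NULL) {
  test <- match.arg(test)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- droplevels(factor(labels[keep]))
  if (test == "anova") {
    if (nlevels(labels) < 2L) stop2("ANOVA needs >= 2 groups")
    fit <- stats::aov(scores ~ labels)
    tab <- summary(fit)[[1L]]
    return(test_result("anova", tab$`F value`[1L], tab$`Pr(>F)`[1L],
                       as.integer(table(labels))))
  }
  if (nlevels(labels) != 2L) stop2(test, " needs exactly 2 groups")
  g1 <- scores[labels == levels(labels)[1L]]
  g2 <- scores[labels == levels(labels)[2L]]

  if (test == "rank_sum") {
    if (length(g1) <= 10L && length(g2) <= 10L) {
      p <- exact_ranksum_p(g1, g2)
      w <- sum(rank(c(g1, g2))[seq_along(g1)]) -
        length(g1) * (length(g1) + 1) / 2
      return(test_result("rank_sum_exact", w, p,
                         c(length(g1), length(g2)),
                         direction = stats::median(g2) - stats::median(g1)))
    }
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                              correct = TRUE))
    return(test_result("rank_sum", wt$statistic, wt$p.value,
                       c(length(g1), length(g2)),
                       direction = stats::median(g2) - stats::median(g1)))
  }

  # signed rank: pair by patient_id
  if (is.null(patient_id)) stop2("signed_rank needs patient_id")
  pid <- patient_id[keep]
  p1 <- pid[labels == levels(labels)[1L]]
  p2 <- pid[labels == levels(labels)[2L]]
  orphans <- c(setdiff(p1, p2), setdiff(p2, p1))
  if (length(orphans))
    stop2("unmatched patients in paired test: ",
          paste(utils::head(orphans, 10L), collapse = ", "))
  g2 <- g2[match(p1, p2)]
  d <- g2 - g1
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(test_result("signed_rank", 0, 1, length(d), direction = 0))
  }
  wt <- suppressWarnings(stats::wilcox.test(g2, g1, paired = TRUE,
                                            exact = length(d) <= 25L &&
                                              !any(d == 0) &&
                                              !anyDuplicated(abs(d))))
  test_result("signed_rank", wt$statistic, wt$p.value, length(d),
              direction = stats::median(d))
}

#' Ordinal trend between scores and ordered categories
#'
#' Kendall tau-b (the tie-corrected variant, appropriate for heavily tied
#' ordinal categories) between per-sample scores and category ranks, with
#' the tie-corrected normal-approximation p-value.
#'
#' @param scores numeric vector.
#' @param categories ordered factor aligned with `scores`.
#' @return a `TestResult` with the tau estimate as `statistic`.
#' @export
ordinal_trend <- function(scores, categories) {
  if (!is.ordered(categories))
    categories <- factor(as.character(categories),
                         levels = INFILTRATION_LEVELS, ordered = TRUE)
  keep <- !is.na(scores) & !is.na(categories)
  scores <- scores[keep]
  ranks <- as.integer(categories[keep])
  if (length(unique(ranks)) < 2L) stop2("need >= 2 represented levels")
  ct <- suppressWarnings(stats::cor.test(scores, ranks, method = "kendall",
                                         exact = FALSE))
  test_result("kendall_tau_b", ct$estimate, ct$p.value, length(scores),
              direction = ct$estimate)
}

#' Pearson correlation between two score vectors
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `TestResult` with r as `statistic` and the two-sided p from the
#'   t transform.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop2("need >= 3 finite pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("pearson", ct$estimate, ct$p.value, length(x),
              direction = ct$estimate)
}

#' Split scores into high (upper quartile) vs low
#'
#' High if and only if the score strictly exceeds the 75th percentile
#' (linear-interpolation, type-7); ties at the threshold go to "low", so
#' "high" is strictly the upper tail.
#'
#' @param scores numeric vector, length >= 4.
#' @return factor with levels `low`, `high`.
#' @export
quartile_stratify <- function(scores) {
  if (sum(is.finite(scores)) < 4L) stop2("need >= 4 finite scores")
  q3 <- stats::quantile(scores, 0.75, type = 7, names = FALSE, na.rm = TRUE)
  out <- factor(ifelse(scores > q3, "high", "low"), levels = c("low", "high"))
  if (all(out == "low", na.rm = TRUE))
    warning("no score exceeds the 75th percentile; everyone labelled low")
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival curves per group and the 1-df log-rank chi-square
#' comparing two groups, via the survival package.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param labels two-level grouping aligned with `time`.
#' @return a `SurvivalResult`: `curves` data.frame (group, time, surv,
#'   n_risk, n_event), `statistic` (log-rank chi-square), `p_value`,
#'   `groups`, `n`, `events`, and `reliable` (FALSE when a group has zero
#'   events).
#' @export
km_logrank <- function(time, event, labels) {
  keep <- !is.na(time) & !is.na(event) & !is.na(labels)
  time <- time[keep]; event <- as.integer(event[keep])
  labels <- droplevels(factor(labels[keep]))
  if (any(time < 0)) stop2("negative survival times")
  if (nlevels(labels) != 2L) stop2("log-rank here compares exactly 2 groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ labels)
  strata_id <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^labels=", "", strata_id),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  ev_by_group <- tapply(event, labels, sum)
  reliable <- all(ev_by_group > 0)
  if (!reliable)
    warning("group(s) with zero events: ",
            paste(names(ev_by_group)[ev_by_group == 0], collapse = ", "),
            "; log-rank flagged unreliable")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ labels)
  structure(list(curves = curves, statistic = unname(sd_$chisq),
                 p_value = stats::pchisq(sd_$chisq, df = 1L,
                                         lower.tail = FALSE),
                 groups = levels(labels), n = as.integer(table(labels)),
                 events = as.integer(ev_by_group), reliable = reliable),
            class = "SurvivalResult")
}

#' @export
print.SurvivalResult <- function(x, ...) {
  cat(sprintf("Log-rank %s vs %s: chisq = %.4g, p = %.3g (n = %d/%d, events = %d/%d)%s\n",
              x$groups[1L], x$groups[2L], x$statistic, x$p_value,
              x$n[1L], x$n[2L], x$events[1L], x$events[2L],
              if (!x$reliable) " [unreliable: zero-event group]" else ""))
  invisible(x)
}

# One row of the machine-readable association report.
report_row <- function(analysis, signature, tr, group = NA_character_) {
  data.frame(analysis = analysis, stratum = group, signature = signature,
             test = tr$test, statistic = tr$statistic, p_value = tr$p_value,
             n = paste(tr$n, collapse = "/"),
             direction = tr$direction %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the full association suite on a scored cohort
#'
#' For each lymphocyte signature score and for the total score, runs (where
#' the needed annotation columns exist; missing ones skip the analysis with a
#' message, never silently):
#' infiltration-category trend (one-way ANOVA + Kendall tau-b); ER-status
#' rank sum and Pearson correlation with the ER activity score; subtype
#' comparison (luminal A/B vs basal/HER2/normal-like); CAAI rank sum overall
#' and within ER strata; quartile-stratified Kaplan-Meier log-rank within ER
#' strata; and the paired pre vs day-90 signed-rank test. Cross-sectional
#' analyses use samples with `timepoint == "none"` (or all samples when no
#' timepoint column exists).
#'
#' @param scores a `ScoreTable` from [score_table()].
#' @param annotations a `CohortAnnotation` covering the scored samples.
#' @param signatures character vector of score columns to analyse; default
#'   all lymphocyte columns plus `total`.
#' @param alpha significance level recorded in the report (default 0.05).
#' @param p_adjust optional p-value correction method (e.g. "bonferroni")
#'   applied per analysis family; default `"none"` (the study reports
#'   per-test p-values).
#' @return list with `report` (data.frame of test rows), `survival` (named
#'   list of `SurvivalResult`), and `skipped` (named reasons).
#' @export
run_association_suite <- function(scores, annotations, signatures = NULL,
                                  alpha = 0.05, p_adjust = "none") {
  stopifnot(is.data.frame(scores), is.data.frame(annotations))
  ann <- annotations[match(scores$sample_id, annotations$sample_id), ,
                     drop = FALSE]
  if (any(is.na(ann$sample_id)))
    stop2("annotations missing for sample(s): ",
          paste(utils::head(scores$sample_id[is.na(ann$sample_id)], 5L),
                collapse = ", "))
  if (is.null(signatures))
    signatures <- setdiff(names(scores), c("sample_id", "er_activity"))
  rows <- list()
  surv_results <- list()
  skipped <- character()
  has <- function(col) col %in% names(ann) &&
    any(!is.na(ann[[col]]) & ann[[col]] != "unknown")

  cross <- if (has("timepoint")) ann$timepoint == "none" else
    rep(TRUE, nrow(ann))

  for (sig in signatures) {
    sc <- scores[[sig]]

    if (has("infiltration_category")) {
      cat_ok <- cross & !is.na(ann$infiltration_category)
      if (sum(cat_ok) >= 8L &&
          nlevels(droplevels(ann$infiltration_category[cat_ok])) >= 2L) {
        rows[[length(rows) + 1L]] <- report_row(
          "infiltration_trend_anova", sig,
          compare_groups(sc[cat_ok],
                         droplevels(ann$infiltration_category[cat_ok]),
                         test = "anova"))
        rows[[length(rows) + 1L]] <- report_row(
          "infiltration_trend_kendall", sig,
          ordinal_trend(sc[cat_ok], ann$infiltration_category[cat_ok]))
      }
    } else skipped["infiltration_trend"] <- "no infiltration_category column"

    if (has("er_status")) {
      er_ok <- cross & ann$er_status %in% c("ER+", "ER-")
      if (length(unique(ann$er_status[er_ok])) == 2L)
        rows[[length(rows) + 1L]] <- report_row(
          "er_status_ranksum", sig,
          compare_groups(sc[er_ok],
                         factor(ann$er_status[er_ok],
                                levels = c("ER+", "ER-")),
                         test = "rank_sum"))
    } else skipped["er_status"] <- "no er_status column"

    if ("er_activity" %in% names(scores))
      rows[[length(rows) + 1L]] <- report_row(
        "er_activity_pearson", sig,
        correlate(scores$er_activity[cross], sc[cross]))

    if (has("subtype")) {
      st <- ann$subtype
      lum <- st %in% c("luminal A", "luminal B")
      nonlum <- st %in% c("basal", "HER2", "normal-like")
      sub_ok <- cross & (lum | nonlum)
      if (any(lum & cross) && any(nonlum & cross))
        rows[[length(rows) + 1L]] <- report_row(
          "subtype_luminal_vs_nonluminal", sig,
          compare_groups(sc[sub_ok],
                         factor(ifelse(lum[sub_ok], "luminal", "non-luminal"),
                                levels = c("luminal", "non-luminal")),
                         test = "rank_sum"))
    } else skipped["subtype"] <- "no subtype column"

    if (has("caai_status")) {
      strata <- list(all = cross)
      if (has("er_status")) {
        strata[["ER+"]] <- cross & ann$er_status == "ER+"
        strata[["ER-"]] <- cross & ann$er_status == "ER-"
      }
      for (nm in names(strata)) {
        sel <- strata[[nm]] & ann$caai_status %in% c("positive", "negative")
        if (length(unique(ann$caai_status[sel])) == 2L)
          rows[[length(rows) + 1L]] <- report_row(
            "caai_ranksum", sig,
            compare_groups(sc[sel],
                           factor(ann$caai_status[sel],
                                  levels = c("negative", "positive")),
                           test = "rank_sum"),
            group = nm)
      }
    } else skipped["caai"] <- "no caai_status column"

    if (has("survival_time") && has("event") && has("er_status")) {
      for (er in c("ER-", "ER+")) {
        sel <- cross & ann$er_status == er & !is.na(ann$survival_time) &
          !is.na(ann$event)
        if (sum(sel) >= 8L && sum(ann$event[sel]) >= 2L) {
          grp <- quartile_stratify(sc[sel])
          sr <- tryCatch(
            km_logrank(ann$survival_time[sel], ann$event[sel], grp),
            warning = function(w) suppressWarnings(
              km_logrank(ann$survival_time[sel], ann$event[sel], grp)))
          key <- paste0("survival_", er, "_", sig)
          surv_results[[key]] <- sr
          # direction: negative when the high group fares better (fewer
          # events per at-risk than expected)
          high_med <- stats::median(ann$survival_time[sel][grp == "high"])
          low_med <- stats::median(ann$survival_time[sel][grp == "low"])
          rows[[length(rows) + 1L]] <- report_row(
            "survival_quartile_logrank", sig,
            test_result("logrank", sr$statistic, sr$p_value, sr$n,
                        direction = high_med - low_med,
                        note = if (!sr$reliable) "zero-event group" else NA),
            group = er)
        }
      }
    } else if (!has("survival_time"))
      skipped["survival"] <- "no survival columns"

    if (has("timepoint") && has("patient_id") &&
        any(ann$timepoint == "pre") && any(ann$timepoint == "day90")) {
      sel <- ann$timepoint %in% c("pre", "day90")
      rows[[length(rows) + 1L]] <- report_row(
        "paired_treatment_signed_rank", sig,
        compare_groups(sc[sel],
                       factor(ann$timepoint[sel], levels = c("pre", "day90")),
                       test = "signed_rank",
                       patient_id = ann$patient_id[sel]))
    }
  }
  for (nm in names(skipped)) message("skipped ", nm, ": ", skipped[[nm]])

  report <- do.call(rbind, rows)
  if (p_adjust != "none" && !is.null(report))
    report$p_adjusted <- stats::ave(report$p_value, report$analysis,
                                    FUN = function(p)
                                      stats::p.adjust(p, method = p_adjust))
  list(report = report, survival = surv_results, skipped = skipped,
       alpha = alpha)
}
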