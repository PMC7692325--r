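#' @title Downstream clinical analysis of activity scores
#' @name tall_analysis
#' @description
#' The clinical pipeline applied to a scored leukemia cohort:
#' NOTCH1/FBXW7 mutation-strength classification, Kruskal-Wallis
#' comparison of scores across groups, correlation of scores with ICN1
#' protein levels, percentile-based activity grouping, Kaplan-Meier and
#' log-rank survival analysis, and a 2x2 chi-square association of the
#' low-activity group with functional PTEN loss. Missing clinical fields
#' are dropped listwise per analysis, with the per-analysis n reported.
NULL

#' Classify NOTCH1/FBXW7 mutation strength
#'
#' Strong activation: a juxtamembrane-domain mutation, or a
#' heterodimerization-domain mutation combined with a PEST-domain or
#' FBXW7 mutation. Weak activation: any single HD, PEST or FBXW7
#' mutation not meeting the strong rule. None otherwise. Samples with
#' unknown mutation status get `NA` and are excluded from mutation-based
#' analyses.
#'
#' @param hd,pest,jme,fbxw7 logical vectors of per-sample mutation flags
#'   (heterodimerization domain, PEST domain, juxtamembrane domain,
#'   FBXW7).
#' @param status_known logical vector; flags are only interpreted where
#'   `TRUE`.
#' @return Factor with levels `none < weak < strong` (`NA` where status
#'   is unknown).
#' @export
classify_notch_mutation <- function(hd, pest, jme, fbxw7,
                                    status_known = TRUE) {
  n <- max(length(hd), length(pest), length(jme), length(fbxw7))
  hd <- rep_len(as.logical(hd), n)
  pest <- rep_len(as.logical(pest), n)
  jme <- rep_len(as.logical(jme), n)
  fbxw7 <- rep_len(as.logical(fbxw7), n)
  status_known <- rep_len(as.logical(status_known), n)
  strong <- jme | (hd & (pest | fbxw7))
  weak <- !strong & (hd | pest | fbxw7)
  out <- ifelse(strong, "strong", ifelse(weak, "weak", "none"))
  out[!status_known] <- NA_character_
  factor(out, levels = c("none", "weak", "strong"), ordered = TRUE)
}

#' Kruskal-Wallis comparison of scores across groups
#'
#' Tie-corrected H statistic with a chi-square p-value; empty groups are
#' dropped with a warning.
#'
#' @param scores numeric vector.
#' @param groups group labels, same length.
#' @return List: `statistic` (H), `p_value`, `df`, `n`, `medians` (named,
#'   per group).
#' @export
kruskal_wallis_by_group <- function(scores, groups) {
  keep <- is.finite(scores) & !is.na(groups)
  scores <- scores[keep]
  groups <- factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (any(sizes == 0L)) {
    warning("dropping empty group(s): ",
            paste(names(sizes)[sizes == 0L], collapse = ", "))
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    # fully tied data carry no rank information: H = 0 by convention
    return(list(statistic = 0, p_value = 1,
                df = nlevels(groups) - 1L, n = length(scores),
                medians = tapply(scores, groups, stats::median)))
  }
  kw <- stats::kruskal.test(scores, groups)
  list(statistic = unname(kw$statistic),
       p_value = kw$p.value,
       df = unname(kw$parameter),
       n = length(scores),
       medians = tapply(scores, groups, stats::median))
}

#' Correlation between ICN1 protein level and activity score
#'
#' Reports both Pearson and Spearman coefficients with p-values; pairs
#' with a missing member are dropped listwise.
#'
#' @param icn1 numeric vector of ICN1 levels.
#' @param scores numeric vector of activity scores, same length.
#' @return List: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`.
#' @export
icn1_correlation <- function(icn1, scores) {
  keep <- is.finite(icn1) & is.finite(scores)
  icn1 <- icn1[keep]
  scores <- scores[keep]
  if (length(icn1) < 3L) {
    stop("need at least 3 paired non-missing observations", call. = FALSE)
  }
  if (stats::sd(icn1) == 0 || stats::sd(scores) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  pe <- stats::cor.test(icn1, scores, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(icn1, scores, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(icn1))
}

#' Assign percentile-based activity groups
#'
#' `low` strictly below the 25th percentile, `high` strictly above the
#' 75th, `middle` otherwise (scores exactly at a cut go to `middle`).
#' Quartiles use the linear-interpolation definition (R's default type
#' 7), computed on the analyzed cohort's own scores; for 117 distinct
#' scores this yields 29 in the low group.
#'
#' @param scores numeric vector (at least 4 values).
#' @return Factor with levels `low < middle < high`, same length as
#'   `scores` (`NA` score gives `NA` group).
#' @export
assign_activity_groups <- function(scores) {
  ok <- is.finite(scores)
  if (sum(ok) < 4L) stop("need at least 4 samples", call. = FALSE)
  q <- stats::quantile(scores[ok], c(0.25, 0.75), type = 7)
  out <- ifelse(scores < q[1], "low",
                ifelse(scores > q[2], "high", "middle"))
  out[!ok] <- NA_character_
  factor(out, levels = c("low", "middle", "high"), ordered = TRUE)
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimates per group and the k-group log-rank
#' chi-square test.
#'
#' @param groups group labels.
#' @param time non-negative follow-up times.
#' @param event event indicators, 0 (censored) or 1 (event).
#' @return List: `fit` (a [survival::survfit] object), `statistic`
#'   (log-rank chi-square), `df`, `p_value`, `n`, `n_events`.
#' @export
km_logrank <- function(groups, time, event) {
  keep <- !is.na(groups) & is.finite(time) & !is.na(event)
  groups <- factor(as.character(groups[keep]))
  time <- time[keep]
  event <- as.integer(event[keep])
  stopifnot(all(time >= 0), all(event %in% c(0L, 1L)))
  if (nlevels(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (sum(event) == 0L) {
    stop("no events: log-rank p undefined", call. = FALSE)
  }
  df <- data.frame(time = time, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(groups) - 1L
  p <- stats::pchisq(lr$chisq, df = k, lower.tail = FALSE)
  list(fit = fit, statistic = unname(lr$chisq), df = k, p_value = p,
       n = length(time), n_events = sum(event))
}

#' Association between low activity and functional PTEN loss
#'
#' Collapses the activity groups to low vs middle+high and tests the
#' 2x2 table against PTEN loss with the Pearson chi-square statistic
#' (no continuity correction, df = 1, two-sided).
#'
#' @param groups activity groups from [assign_activity_groups()] (or any
#'   labels where `"low"` marks the low-activity group).
#' @param pten_loss logical vector of functional PTEN loss; `NA` dropped
#'   listwise.
#' @return List: `table` (2x2 observed counts), `expected`, `statistic`,
#'   `df`, `p_value`, `n`.
#' @export
pten_association <- function(groups, pten_loss) {
  keep <- !is.na(groups) & !is.na(pten_loss)
  low <- factor(ifelse(groups[keep] == "low", "low", "middle+high"),
                levels = c("low", "middle+high"))
  pten <- factor(ifelse(pten_loss[keep], "loss", "intact"),
                 levels = c("loss", "intact"))
  tab <- table(low, pten)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("zero margin in contingency table:\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"),
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, expected = ct$expected,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, n = sum(tab))
}

#' Two-condition Wilcoxon test
#'
#' Paired data get the signed-rank test, independent conditions the
#' rank-sum (Mann-Whitney) test; two-sided, exact p for small samples
#' without ties, normal approximation otherwise.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param paired logical.
#' @return List: `p_value`, `statistic`, `method`, `n`.
#' @export
wilcoxon_two_condition <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired test requires equal lengths", call. = FALSE)
    }
    if (all(a == b)) {
      warning("all paired differences are zero: degenerate, p = 1")
      return(list(p_value = 1, statistic = 0,
                  method = "Wilcoxon signed rank", n = length(a)))
    }
  } else if (length(a) == 0L || length(b) == 0L) {
    stop("both conditions must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = wt$method, n = length(a) + length(b))
}

#' Run the full downstream clinical pipeline
#'
#' Joins a score table to clinical annotations on `sample_id` and runs
#' every analysis whose required columns are present: mutation-class
#' score comparison, subtype comparison, ICN1 correlation, activity
#' grouping, event-free and relapse-free survival with log-rank tests,
#' and the PTEN association. Analyses with missing requirements are
#' skipped with a reason.
#'
#' @param scores data frame from [score_samples()].
#' @param clinical data frame with `sample_id` and any of: `hd`, `pest`,
#'   `jme`, `fbxw7`, `status_known`, `subtype`, `icn1`, `pten_loss`,
#'   `efs_time`/`efs_event`, `rfs_time`/`rfs_event`.
#' @return List of per-analysis results (each carrying its own n) plus
#'   `activity_groups` (data frame `sample_id`, `log2_odds`, `group`)
#'   and `skipped` (named reasons).
#' @export
analyze_cohort <- function(scores, clinical) {
  stopifnot(is.data.frame(scores), is.data.frame(clinical),
            "sample_id" %in% names(clinical))
  d <- merge(scores, clinical, by = "sample_id", sort = TRUE)
  d <- d[is.finite(d$log2_odds), , drop = FALSE]
  if (nrow(d) < 4L) stop("fewer than 4 scored, annotated samples", call. = FALSE)
  out <- list()
  skipped <- character(0)

  mut_cols <- c("hd", "pest", "jme", "fbxw7")
  if (all(mut_cols %in% names(d))) {
    known <- if ("status_known" %in% names(d)) d$status_known else TRUE
    mut <- classify_notch_mutation(d$hd, d$pest, d$jme, d$fbxw7, known)
    d$mutation_class <- mut
    out$mutation_kruskal <- tryCatch(
      kruskal_wallis_by_group(d$log2_odds, mut),
      error = function(e) conditionMessage(e))
  } else {
    skipped["mutation_kruskal"] <- "missing mutation flag columns"
  }

  if ("subtype" %in% names(d)) {
    out$subtype_kruskal <- tryCatch(
      kruskal_wallis_by_group(d$log2_odds, d$subtype),
      error = function(e) conditionMessage(e))
  } else {
    skipped["subtype_kruskal"] <- "missing subtype column"
  }

  if ("icn1" %in% names(d)) {
    out$icn1 <- tryCatch(icn1_correlation(d$icn1, d$log2_odds),
                         error = function(e) conditionMessage(e))
  } else {
    skipped["icn1"] <- "missing icn1 column"
  }

  d$group <- assign_activity_groups(d$log2_odds)
  out$activity_groups <- d[c("sample_id", "log2_odds", "group")]

  for (endpoint in c("efs", "rfs")) {
    tcol <- paste0(endpoint, "_time")
    ecol <- paste0(endpoint, "_event")
    key <- paste0(endpoint, "_logrank")
    if (all(c(tcol, ecol) %in% names(d))) {
      out[[key]] <- tryCatch(
        km_logrank(d$group, d[[tcol]], d[[ecol]]),
        error = function(e) conditionMessage(e))
    } else {
      skipped[key] <- paste("missing", tcol, "/", ecol)
    }
  }

  if ("pten_loss" %in% names(d)) {
    out$pten <- tryCatch(pten_association(d$group, d$pten_loss),
                         error = function(e) conditionMessage(e))
  } else {
    skipped["pten"] <- "missing pten_loss column"
  }

  out$skipped <- skipped
  out
}
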