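#' @title Synthetic cohort generators
#' @name synthetic_data
#' @description
#' Generators for the cohorts the assay and its downstream pipeline
#' assume: a two-class calibration cohort (pathway active vs inactive,
#' emulating a normal-tissue vs high-grade serous ovarian cancer
#' contrast), on/off validation contrasts (e.g. gamma-secretase inhibitor
#' treated vs untreated), and a T-ALL-style clinical cohort with mutation
#' classes, correlated ICN1 protein levels, censored survival and PTEN
#' status. Noise is additive Gaussian on the log2 scale at both the gene
#' and probeset layers; every generator is deterministic given its seed.
NULL

# seed the RNG for a generator call and restore the caller's stream when
# the calling function exits
use_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
}

#' Specification for a two-class calibration cohort
#'
#' @param n_active,n_inactive samples per class.
#' @param delta per-gene mean log2 shift when the pathway is active.
#' @param sigma_gene biological (per sample x gene) SD, log2 units.
#' @param sigma_probeset probeset measurement noise SD, log2 units.
#' @param baseline range (length 2) of per-probeset baseline offsets,
#'   drawn uniformly once per probeset; log2 intensity units.
#' @param seed integer seed making the cohort reproducible.
#' @return A list of class `calibration_cohort_spec`.
#' @export
calibration_cohort_spec <- function(n_active = 20L, n_inactive = 20L,
                                    delta = 2.0, sigma_gene = 0.5,
                                    sigma_probeset = 0.5,
                                    baseline = c(6, 10), seed = 1L) {
  stopifnot(n_active >= 0, n_inactive >= 0,
            sigma_gene > 0, sigma_probeset > 0,
            length(baseline) == 2L, is.finite(delta))
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 delta = delta, sigma_gene = sigma_gene,
                 sigma_probeset = sigma_probeset,
                 baseline = baseline, seed = as.integer(seed)),
            class = "calibration_cohort_spec")
}

# latent-activity -> expression matrix shared by both generators.
# activity: numeric vector of per-sample latent log2 shifts.
simulate_expression <- function(activity, sample_ids, panel,
                                sigma_gene, sigma_probeset, baseline) {
  map <- panel$probesets[panel$probesets$included, , drop = FALSE]
  if (nrow(map) == 0L) stop("panel has zero included probesets", call. = FALSE)
  n <- length(activity)
  offsets <- stats::runif(nrow(map), baseline[1], baseline[2])
  expr <- matrix(NA_real_, nrow = nrow(map), ncol = n,
                 dimnames = list(map$id, sample_ids))
  genes <- panel$genes$symbol
  gene_vals <- matrix(stats::rnorm(length(genes) * n, sd = sigma_gene),
                      nrow = length(genes), ncol = n,
                      dimnames = list(genes, sample_ids))
  gene_vals <- sweep(gene_vals, 2L, activity, `+`)
  for (i in seq_len(nrow(map))) {
    expr[i, ] <- offsets[i] + gene_vals[map$gene[i], ] +
      stats::rnorm(n, sd = sigma_probeset)
  }
  expr
}

#' Simulate a two-class calibration cohort
#'
#' Per sample, the latent pathway state follows its class; per gene, the
#' transcription level is `delta * 1[active] + N(0, sigma_gene)`; each
#' probeset adds its fixed baseline offset and `N(0, sigma_probeset)`.
#'
#' @param spec a [calibration_cohort_spec()].
#' @param panel a [target_gene_panel].
#' @return List with `expr` (probesets x samples matrix) and `labels`
#'   (named character vector, `"active"`/`"inactive"`).
#' @export
simulate_calibration_cohort <- function(spec, panel) {
  stopifnot(inherits(spec, "calibration_cohort_spec"),
            inherits(panel, "target_gene_panel"))
  use_seed(spec$seed)
  n <- spec$n_active + spec$n_inactive
  sample_ids <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(
    rep(c("active", "inactive"), c(spec$n_active, spec$n_inactive)),
    sample_ids)
  activity <- ifelse(labels == "active", spec$delta, 0)
  expr <- simulate_expression(activity, sample_ids, panel,
                              spec$sigma_gene, spec$sigma_probeset,
                              spec$baseline)
  list(expr = expr, labels = labels)
}

#' Specification for a T-ALL-style clinical cohort
#'
#' Defaults mirror the printed marginals of the leukemia cohort the
#' pipeline targets where those are available (117 patients; PTEN loss in
#' 38% of the lowest-activity quartile vs 14% of the rest; ICN1 measured
#' on roughly half the cohort; mutation status unknown for a few
#' patients); the remaining values are field-realistic synthetic choices.
#'
#' @param n_patients cohort size.
#' @param mutation_props proportions of `none`/`weak`/`strong`
#'   NOTCH1/FBXW7 mutation classes (must sum to 1).
#' @param class_shifts latent activity shift per mutation class, log2
#'   units.
#' @param sigma_activity SD of latent activity around the class shift.
#' @param sigma_gene,sigma_probeset,baseline expression noise, as in
#'   [calibration_cohort_spec()].
#' @param icn1_intercept,icn1_slope,icn1_sigma ICN1 protein level is
#'   `icn1_intercept + icn1_slope * activity + N(0, icn1_sigma)`,
#'   truncated at 0 (RPPA relative intensity units).
#' @param prob_icn1_measured fraction of patients with an ICN1 value.
#' @param prob_status_unknown fraction with unknown mutation status.
#' @param baseline_hazard exponential event hazard (per time unit).
#' @param hazard_multiplier_low hazard multiplier for patients in the
#'   lowest quartile of latent activity.
#' @param censor_max censoring times drawn uniformly on (0, censor_max).
#' @param pten_loss_low,pten_loss_rest probability of functional PTEN
#'   loss in the lowest-activity quartile and in the rest.
#' @param prob_pten_missing fraction with unknown PTEN status.
#' @param subtype_props proportions of the four molecular subtypes
#'   (ETP/immature, TLX, Proliferative, TALLMO).
#' @param tlx_activity_bump extra latent activity for TLX patients.
#' @param seed integer seed.
#' @return A list of class `tall_cohort_spec`.
#' @export
tall_cohort_spec <- function(n_patients = 117L,
                             mutation_props = c(none = 0.35, weak = 0.45,
                                                strong = 0.20),
                             class_shifts = c(none = 0, weak = 1.5,
                                              strong = 3.0),
                             sigma_activity = 1.0,
                             sigma_gene = 0.5, sigma_probeset = 0.5,
                             baseline = c(6, 10),
                             icn1_intercept = 5.0,
                             icn1_slope = 1.0, icn1_sigma = 1.0,
                             prob_icn1_measured = 62 / 117,
                             prob_status_unknown = 5 / 117,
                             baseline_hazard = 0.08,
                             hazard_multiplier_low = 5.0,
                             censor_max = 10,
                             pten_loss_low = 0.38, pten_loss_rest = 0.14,
                             prob_pten_missing = 4 / 117,
                             subtype_props = c(`ETP/immature` = 0.20,
                                               TLX = 0.26,
                                               Proliferative = 0.27,
                                               TALLMO = 0.27),
                             tlx_activity_bump = 1.0,
                             seed = 1L) {
  if (abs(sum(mutation_props) - 1) > 1e-8) {
    stop("mutation class proportions must sum to 1", call. = FALSE)
  }
  if (abs(sum(subtype_props) - 1) > 1e-8) {
    stop("subtype proportions must sum to 1", call. = FALSE)
  }
  stopifnot(n_patients > 0, baseline_hazard > 0, hazard_multiplier_low > 0,
            pten_loss_low >= 0, pten_loss_low <= 1,
            pten_loss_rest >= 0, pten_loss_rest <= 1)
  structure(as.list(environment()), class = "tall_cohort_spec")
}

# decompose a mutation class into plausible domain flags so that
# classify_notch_mutation() recovers the class exactly
flags_for_class <- function(class) {
  switch(class,
    none = list(hd = FALSE, pest = FALSE, jme = FALSE, fbxw7 = FALSE),
    weak = {
      pick <- sample(c("hd", "pest", "fbxw7"), 1L)
      list(hd = pick == "hd", pest = pick == "pest",
           jme = FALSE, fbxw7 = pick == "fbxw7")
    },
    strong = {
      if (stats::runif(1) < 0.5) {
        list(hd = FALSE, pest = FALSE, jme = TRUE, fbxw7 = FALSE)
      } else {
        with_fbxw7 <- stats::runif(1) < 0.5
        list(hd = TRUE, pest = !with_fbxw7, jme = FALSE, fbxw7 = with_fbxw7)
      }
    })
}

#' Simulate a T-ALL-style clinical cohort
#'
#' Draws a mutation class per patient, a latent activity around the class
#' shift, expression from that activity (as in the calibration
#' generator), an ICN1 level linearly coupled to activity, exponential
#' survival with an elevated hazard for the lowest latent-activity
#' quartile, independent uniform censoring, and PTEN loss with an
#' activity-group-dependent probability.
#'
#' @param spec a [tall_cohort_spec()].
#' @param panel a [target_gene_panel].
#' @return List with `expr` (probesets x samples) and `clinical` (data
#'   frame: `sample_id`, `subtype`, `status_known`, `hd`, `pest`, `jme`,
#'   `fbxw7`, `icn1`, `pten_loss`, `efs_time`, `efs_event`, `rfs_time`,
#'   `rfs_event`, plus the generating `latent_activity`).
#' @export
simulate_tall_cohort <- function(spec, panel) {
  stopifnot(inherits(spec, "tall_cohort_spec"),
            inherits(panel, "target_gene_panel"))
  use_seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("TALL%03d", seq_len(n))
  class <- sample(names(spec$mutation_props), n, replace = TRUE,
                  prob = spec$mutation_props)
  subtype <- sample(names(spec$subtype_props), n, replace = TRUE,
                    prob = spec$subtype_props)
  activity <- spec$class_shifts[class] +
    ifelse(subtype == "TLX", spec$tlx_activity_bump, 0) +
    stats::rnorm(n, sd = spec$sigma_activity)
  activity <- unname(activity)
  expr <- simulate_expression(activity, ids, panel,
                              spec$sigma_gene, spec$sigma_probeset,
                              spec$baseline)
  flags <- lapply(class, flags_for_class)
  status_known <- stats::runif(n) >= spec$prob_status_unknown
  icn1 <- pmax(0, spec$icn1_intercept + spec$icn1_slope * activity +
                 stats::rnorm(n, sd = spec$icn1_sigma))
  icn1[stats::runif(n) >= spec$prob_icn1_measured] <- NA_real_
  low_group <- activity < stats::quantile(activity, 0.25)
  hazard <- spec$baseline_hazard *
    ifelse(low_group, spec$hazard_multiplier_low, 1)
  event_time <- stats::rexp(n, rate = hazard)
  censor_time <- stats::runif(n, 0, spec$censor_max)
  relapse_time <- stats::rexp(n, rate = hazard)
  pten_p <- ifelse(low_group, spec$pten_loss_low, spec$pten_loss_rest)
  pten_loss <- stats::runif(n) < pten_p
  pten_loss[stats::runif(n) < spec$prob_pten_missing] <- NA
  clinical <- data.frame(
    sample_id = ids,
    subtype = subtype,
    status_known = status_known,
    hd = vapply(flags, `[[`, TRUE, "hd"),
    pest = vapply(flags, `[[`, TRUE, "pest"),
    jme = vapply(flags, `[[`, TRUE, "jme"),
    fbxw7 = vapply(flags, `[[`, TRUE, "fbxw7"),
    icn1 = icn1,
    pten_loss = pten_loss,
    efs_time = pmin(event_time, censor_time),
    efs_event = as.integer(event_time <= censor_time),
    rfs_time = pmin(relapse_time, censor_time),
    rfs_event = as.integer(relapse_time <= censor_time),
    latent_activity = activity,
    stringsAsFactors = FALSE
  )
  list(expr = expr, clinical = clinical)
}
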