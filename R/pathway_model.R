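#' @title The pathway activity Bayesian network
#' @name pathway_model
#' @description
#' A three-layer Bayesian network quantifies pathway activity from target
#' gene expression. A latent binary transcription-complex node TC
#' (active/inactive) drives latent per-gene transcription states G_g
#' (up/down), each of which drives one or more observed, discretized
#' probeset intensities O_j (high/low). Genes are conditionally
#' independent given TC and probesets conditionally independent given
#' their gene. Scoring a sample computes the exact posterior odds
#' P(TC = active | O) / P(TC = inactive | O) by marginalizing over the
#' gene layer, and reports log2 of those odds so that 0 means "no
#' evidence either way" and the scale is symmetric.
#'
#' The gene-layer conditional probabilities encode literature evidence
#' strength and default to a fixed value; the probeset layer (thresholds
#' and conditional probabilities) is calibrated on a labeled two-class
#' cohort and then frozen, after which scoring never mutates the model.
NULL

default_constant_cpt <- c(c = 0.75, d = 0.25)

#' Construct a pathway model from explicit parameters
#'
#' Low-level constructor for building a model directly from known
#' conditional probability tables (e.g. small hand-specified models);
#' [calibrate()] is the data-driven path. All invariants are validated:
#' probabilities strictly in (0, 1), `a > b` for every up-regulated gene
#' and `c > d` for every scoring probeset.
#'
#' @param panel a [target_gene_panel].
#' @param prior_active prior probability P(TC = active), in (0, 1).
#' @param gene_cpt data frame `gene`, `a` = P(gene up | TC active),
#'   `b` = P(gene up | TC inactive).
#' @param probeset_cpt data frame `probeset_id`, `gene`,
#'   `c` = P(high | gene up), `d` = P(high | gene down), `threshold`,
#'   `included` (logical), `reason`.
#' @param frozen logical; frozen models are immutable and scoreable.
#' @param version free-text model version label.
#' @return A validated object of class `pathway_model`.
#' @export
new_pathway_model <- function(panel, prior_active, gene_cpt, probeset_cpt,
                              frozen = FALSE, version = "0.1") {
  model <- structure(
    list(panel = panel,
         prior_active = prior_active,
         gene_cpt = gene_cpt,
         probeset_cpt = probeset_cpt,
         frozen = frozen,
         version = version),
    class = "pathway_model"
  )
  validate_pathway_model(model)
  model
}

validate_pathway_model <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  p <- model$prior_active
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop("prior_active must lie strictly in (0, 1)", call. = FALSE)
  }
  gc <- model$gene_cpt
  if (any(gc$a <= 0 | gc$a >= 1 | gc$b <= 0 | gc$b >= 1)) {
    stop("gene CPT probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  dir <- model$panel$genes$direction[match(gc$gene, model$panel$genes$symbol)]
  bad <- dir == 1L & gc$a <= gc$b
  if (any(bad)) {
    stop("gene CPT violates a > b for up-regulated gene(s): ",
         paste(gc$gene[bad], collapse = ", "), call. = FALSE)
  }
  pc <- scoring_cpt(model)
  if (nrow(pc)) {
    if (any(pc$c <= 0 | pc$c >= 1 | pc$d <= 0 | pc$d >= 1)) {
      stop("probeset CPT probabilities must lie strictly in (0, 1)",
           call. = FALSE)
    }
    if (any(pc$c <= pc$d)) {
      stop("probeset CPT violates c > d for: ",
           paste(pc$probeset_id[pc$c <= pc$d], collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(model)
}

# probeset CPT rows actually used for scoring
scoring_cpt <- function(model) {
  model$probeset_cpt[model$probeset_cpt$included, , drop = FALSE]
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %s (version %s, %s)\n",
              x$panel$pathway_name, x$version,
              if (x$frozen) "frozen" else "unfrozen"))
  cat(sprintf("  prior P(active) = %.3f; %d genes; %d/%d probesets used for scoring\n",
              x$prior_active, nrow(x$gene_cpt),
              sum(x$probeset_cpt$included), nrow(x$probeset_cpt)))
  invisible(x)
}

#' Calibrate the pathway model on a labeled cohort
#'
#' Sets, per probeset, a discretization threshold and the observation
#' probabilities `c = P(high | gene up)` and `d = P(high | gene down)` as
#' Laplace-smoothed frequencies of high calls among the active-class and
#' inactive-class samples respectively. The gene layer keeps fixed
#' literature-evidence defaults. Probesets whose calibration comes out
#' anti-correlated with the class labels (`c <= d`) violate the
#' knowledge-based direction assumption and are excluded from scoring by
#' default (or inverted on request). Probesets that are constant across
#' the calibration cohort carry no class information and fall back to a
#' default CPT with a warning.
#'
#' @param expr numeric matrix of normalized log2 intensities,
#'   probesets x samples.
#' @param labels per-sample class labels, `"active"` or `"inactive"`,
#'   named by sample id (or unnamed and aligned to `colnames(expr)`).
#' @param panel a [target_gene_panel] (pass a frozen model to get an
#'   explicit refusal: frozen models are immutable).
#' @param pseudocount Laplace pseudocount (> 0) added to high/low counts
#'   in each class; guarantees probabilities strictly inside (0, 1) and
#'   finite scores.
#' @param prior_active prior probability that the transcription complex
#'   is active; 0.5 makes the log2-odds a pure evidence measure.
#' @param gene_a,gene_b gene-layer conditional probabilities
#'   `P(gene up | TC active)` and `P(gene up | TC inactive)` applied to
#'   every panel gene.
#' @param threshold_method `"class_median_midpoint"` (midpoint between
#'   the class-conditional medians; default) or `"pooled_median"`.
#' @param anticorrelated what to do with a probeset calibrated to
#'   `c <= d`: `"exclude"` (default) or `"invert"` (swap c and d).
#' @return An unfrozen [pathway_model]; pass it to [freeze_model()]
#'   before scoring.
#' @export
calibrate <- function(expr, labels, panel,
                      pseudocount = 1,
                      prior_active = 0.5,
                      gene_a = 0.95, gene_b = 0.05,
                      threshold_method = c("class_median_midpoint",
                                           "pooled_median"),
                      anticorrelated = c("exclude", "invert")) {
  if (inherits(panel, "pathway_model")) {
    if (isTRUE(panel$frozen)) {
      stop("model is frozen: parameters are immutable and recalibration is refused",
           call. = FALSE)
    }
    panel <- panel$panel
  }
  stopifnot(inherits(panel, "target_gene_panel"))
  threshold_method <- match.arg(threshold_method)
  anticorrelated <- match.arg(anticorrelated)
  validate_expression_matrix(expr)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)

  if (!is.null(names(labels))) {
    labels <- labels[colnames(expr)]
  } else if (length(labels) == ncol(expr)) {
    names(labels) <- colnames(expr)
  }
  labels <- as.character(labels)
  if (anyNA(labels) || !all(labels %in% c("active", "inactive"))) {
    stop("labels must be 'active'/'inactive' for every sample of expr",
         call. = FALSE)
  }
  is_active <- labels == "active"
  if (sum(is_active) == 0L || sum(!is_active) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }

  map <- panel$probesets[panel$probesets$included, , drop = FALSE]
  rows <- lapply(seq_len(nrow(map)), function(i) {
    ps <- map$id[i]
    out <- data.frame(probeset_id = ps, gene = map$gene[i],
                      c = NA_real_, d = NA_real_, threshold = NA_real_,
                      included = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (!ps %in% rownames(expr)) {
      out$reason <- "absent_from_calibration_data"
      return(out)
    }
    v <- expr[ps, ]
    va <- v[is_active & is.finite(v)]
    vi <- v[!is_active & is.finite(v)]
    if (length(va) == 0L || length(vi) == 0L) {
      out$reason <- "missing_in_a_class"
      return(out)
    }
    all_v <- c(va, vi)
    if (max(all_v) == min(all_v)) {
      warning("probeset ", ps,
              " is constant across calibration samples; using default CPT")
      out$threshold <- all_v[1L]
      out$c <- default_constant_cpt[["c"]]
      out$d <- default_constant_cpt[["d"]]
      out$included <- TRUE
      out$reason <- "constant_default_cpt"
      return(out)
    }
    t_j <- switch(threshold_method,
      class_median_midpoint =
        (stats::median(va) + stats::median(vi)) / 2,
      pooled_median = stats::median(all_v)
    )
    # boundary convention: intensity exactly at the threshold calls low
    c_j <- (sum(va > t_j) + pseudocount) / (length(va) + 2 * pseudocount)
    d_j <- (sum(vi > t_j) + pseudocount) / (length(vi) + 2 * pseudocount)
    out$threshold <- t_j
    if (c_j <= d_j) {
      if (anticorrelated == "invert") {
        out$c <- d_j
        out$d <- c_j
        out$included <- d_j > c_j
        out$reason <- if (out$included) "inverted" else "uninformative"
        if (!out$included) out[c("c", "d")] <- NA_real_
      } else {
        out$reason <- "anti_correlated"
      }
      return(out)
    }
    out$c <- c_j
    out$d <- d_j
    out$included <- TRUE
    out
  })
  probeset_cpt <- do.call(rbind, rows)
  if (!any(probeset_cpt$included)) {
    stop("calibration produced no usable probeset: all excluded",
         call. = FALSE)
  }
  gene_cpt <- data.frame(gene = panel$genes$symbol,
                         a = gene_a, b = gene_b,
                         stringsAsFactors = FALSE)
  new_pathway_model(panel, prior_active, gene_cpt, probeset_cpt,
                    frozen = FALSE)
}

#' Freeze a calibrated model
#'
#' After freezing, scoring operations never mutate any parameter and
#' recalibration is refused; serialization adds a content hash.
#'
#' @param model a [pathway_model].
#' @return The model with `frozen = TRUE`.
#' @export
freeze_model <- function(model) {
  validate_pathway_model(model)
  model$frozen <- TRUE
  model
}

#' Discretize an expression matrix against model thresholds
#'
#' A probeset call is `"high"` iff its intensity strictly exceeds the
#' model threshold, `"low"` iff at or below it, and `NA` (missing) if the
#' probeset is absent from the matrix or the value is non-finite.
#'
#' @param expr numeric matrix, probesets x samples.
#' @param model a [pathway_model] with thresholds.
#' @return Character matrix of calls (`"high"`/`"low"`/`NA`), one row per
#'   scoring probeset of the model, one column per sample.
#' @export
discretize <- function(expr, model) {
  validate_expression_matrix(expr)
  stopifnot(inherits(model, "pathway_model"))
  cpt <- scoring_cpt(model)
  if (!any(cpt$probeset_id %in% rownames(expr))) {
    stop("no overlap between expression probesets and model probesets",
         call. = FALSE)
  }
  calls <- matrix(NA_character_, nrow = nrow(cpt), ncol = ncol(expr),
                  dimnames = list(cpt$probeset_id, colnames(expr)))
  present <- cpt$probeset_id[cpt$probeset_id %in% rownames(expr)]
  for (ps in present) {
    v <- expr[ps, ]
    t_j <- cpt$threshold[cpt$probeset_id == ps]
    call <- ifelse(v > t_j, "high", "low")
    call[!is.finite(v)] <- NA_character_
    calls[ps, ] <- call
  }
  calls
}

# per-gene log2 evidence factors; calls = named chr vector over scoring
# probesets. Returns log2 L(O | TC=active) - log2 L(O | TC=inactive).
log2_evidence <- function(model, calls) {
  cpt <- scoring_cpt(model)
  gc <- model$gene_cpt
  total <- 0
  for (i in seq_len(nrow(gc))) {
    g <- gc$gene[i]
    a <- gc$a[i]
    b <- gc$b[i]
    sub <- cpt[cpt$gene == g, , drop = FALSE]
    obs <- calls[sub$probeset_id]
    keep <- !is.na(obs)
    if (!any(keep)) next  # no evidence for this gene: factor 1 both ways
    high <- obs[keep] == "high"
    cc <- sub$c[keep]
    dd <- sub$d[keep]
    llu <- sum(log2(ifelse(high, cc, 1 - cc)))  # log2 P(O | gene up)
    lld <- sum(log2(ifelse(high, dd, 1 - dd)))  # log2 P(O | gene down)
    m <- max(llu, lld)
    fa <- m + log2(a * 2^(llu - m) + (1 - a) * 2^(lld - m))
    fi <- m + log2(b * 2^(llu - m) + (1 - b) * 2^(lld - m))
    total <- total + (fa - fi)
  }
  total
}

#' Infer the log2-odds activity score for one evidence vector
#'
#' Computes `log2[P(TC active | O) / P(TC inactive | O)]` by exact
#' marginalization over the latent gene states. Missing calls contribute
#' no evidence; a sample with all calls missing cannot be scored.
#'
#' @param model a frozen [pathway_model].
#' @param calls named character vector of `"high"`/`"low"`/`NA` calls,
#'   names are probeset ids (one column of [discretize()]).
#' @return Numeric log2-odds score (finite by CPT smoothing).
#' @export
infer_log2odds <- function(model, calls) {
  stopifnot(inherits(model, "pathway_model"))
  if (!isTRUE(model$frozen)) {
    stop("model must be frozen before scoring", call. = FALSE)
  }
  cpt <- scoring_cpt(model)
  obs <- calls[cpt$probeset_id]
  if (all(is.na(obs))) {
    stop("all probeset calls missing: sample cannot be scored",
         call. = FALSE)
  }
  log2(model$prior_active / (1 - model$prior_active)) +
    log2_evidence(model, calls)
}

#' Brute-force posterior log2-odds by joint enumeration
#'
#' Independent test oracle for [infer_log2odds()]: enumerates every joint
#' assignment of the transcription-complex state and all latent gene
#' states, sums joint probabilities and returns the posterior log2-odds.
#' Refuses models whose latent state space exceeds 2^20.
#'
#' @inheritParams infer_log2odds
#' @param model a [pathway_model] (need not be frozen; the oracle is
#'   read-only by construction).
#' @return Numeric log2-odds score.
#' @export
brute_force_posterior <- function(model, calls) {
  stopifnot(inherits(model, "pathway_model"))
  gc <- model$gene_cpt
  n_genes <- nrow(gc)
  if (2^(n_genes + 1) > 2^20) {
    stop("latent state space exceeds 2^20; refusing enumeration",
         call. = FALSE)
  }
  cpt <- scoring_cpt(model)
  obs <- calls[cpt$probeset_id]
  if (all(is.na(obs))) {
    stop("all probeset calls missing: sample cannot be scored",
         call. = FALSE)
  }
  # P(observed calls | gene state) per gene, for up and down
  lik_up <- numeric(n_genes)
  lik_down <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    sub <- cpt[cpt$gene == gc$gene[i], , drop = FALSE]
    o <- calls[sub$probeset_id]
    keep <- !is.na(o)
    high <- o[keep] == "high"
    lik_up[i] <- prod(ifelse(high, sub$c[keep], 1 - sub$c[keep]))
    lik_down[i] <- prod(ifelse(high, sub$d[keep], 1 - sub$d[keep]))
  }
  states <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_genes)))
  joint_given_tc <- function(p_up) {
    total <- 0
    for (r in seq_len(nrow(states))) {
      up <- states[r, ]
      pg <- prod(ifelse(up, p_up, 1 - p_up))
      po <- prod(ifelse(up, lik_up, lik_down))
      total <- total + pg * po
    }
    total
  }
  num <- model$prior_active * joint_given_tc(gc$a)
  den <- (1 - model$prior_active) * joint_given_tc(gc$b)
  log2(num / den)
}

#' Score every sample of an expression matrix
#'
#' Discretizes the matrix against the frozen model and scores each sample
#' independently; per-sample failures are recorded and do not abort the
#' batch. Scores do not depend on sample order or on which other samples
#' are present.
#'
#' @param model a frozen [pathway_model].
#' @param expr numeric matrix, probesets x samples.
#' @return Data frame with columns `sample_id`, `log2_odds`,
#'   `n_probesets_used`; unscorable samples appear with `NA` score and
#'   their error message in attribute `"errors"`.
#' @export
score_samples <- function(model, expr) {
  stopifnot(inherits(model, "pathway_model"))
  if (!isTRUE(model$frozen)) {
    stop("model must be frozen before scoring", call. = FALSE)
  }
  validate_expression_matrix(expr)
  if (nrow(expr) == 0L || ncol(expr) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }
  calls <- discretize(expr, model)
  out <- data.frame(sample_id = colnames(expr),
                    log2_odds = NA_real_,
                    n_probesets_used = 0L,
                    stringsAsFactors = FALSE)
  errors <- list()
  for (i in seq_len(ncol(calls))) {
    cv <- calls[, i]
    out$n_probesets_used[i] <- sum(!is.na(cv))
    res <- tryCatch(infer_log2odds(model, cv), error = identity)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(sample_id = out$sample_id[i],
                   message = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      out$log2_odds[i] <- res
    }
  }
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors) else NULL
  out
}

#' Write a score table
#'
#' Tab-delimited `sample_id  log2_odds  n_probesets_used`.
#'
#' @param scores data frame from [score_samples()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores[c("sample_id", "log2_odds", "n_probesets_used")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

model_as_list <- function(model) {
  list(
    pathway_name = model$panel$pathway_name,
    panel_version = model$panel$version,
    version = model$version,
    frozen = model$frozen,
    prior_active = model$prior_active,
    genes = model$panel$genes,
    probeset_map = model$panel$probesets,
    gene_cpt = model$gene_cpt,
    probeset_cpt = model$probeset_cpt
  )
}

model_content_hash <- function(model) {
  json <- jsonlite::toJSON(model_as_list(model), digits = NA, na = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a pathway model to JSON
#'
#' Writes a single JSON document (panel, prior, CPTs, thresholds, frozen
#' flag, version) with a content hash that [read_model()] verifies.
#'
#' @param model a [pathway_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_pathway_model(model)
  doc <- model_as_list(model)
  doc$content_hash <- model_content_hash(model)
  jsonlite::write_json(doc, path, digits = NA, na = "null",
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a serialized pathway model
#'
#' @param path JSON file written by [write_model()].
#' @return A [pathway_model]; errors if the stored content hash does not
#'   match the document.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON nulls may drop or delist columns; coerce back to typed vectors
  fix_reason <- function(df) {
    if (is.null(df$reason)) {
      df$reason <- NA_character_
    } else {
      r <- vapply(df$reason, function(x) {
        if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x)
      }, "")
      df$reason <- r
    }
    df
  }
  map <- as.data.frame(doc$probeset_map, stringsAsFactors = FALSE)
  map <- fix_reason(map)
  panel <- target_gene_panel(doc$pathway_name,
                             genes = doc$genes$symbol,
                             direction = doc$genes$direction,
                             probesets = map,
                             version = doc$panel_version)
  cpt <- as.data.frame(doc$probeset_cpt, stringsAsFactors = FALSE)
  cpt <- fix_reason(cpt)
  for (col in c("c", "d", "threshold")) cpt[[col]] <- as.numeric(cpt[[col]])
  model <- new_pathway_model(panel,
                             prior_active = doc$prior_active,
                             gene_cpt = as.data.frame(doc$gene_cpt,
                                                      stringsAsFactors = FALSE),
                             probeset_cpt = cpt,
                             frozen = isTRUE(doc$frozen),
                             version = doc$version)
  if (!is.null(doc$content_hash) &&
      !identical(doc$content_hash, model_content_hash(model))) {
    stop("model file content hash mismatch: file corrupted or edited",
         call. = FALSE)
  }
  model
}
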