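test_that("discretization follows the threshold and boundary conventions", {
  model <- make_test_model(n_genes = 1, threshold = 7)
  expr <- matrix(c(8.2, 7.0, NA), nrow = 1,
                 dimnames = list("G01_P1", c("A", "B", "C")))
  calls <- discretize(expr, model)
  expect_identical(unname(calls["G01_P1", ]), c("high", "low", NA))

  # probeset absent from the matrix is missing for every sample
  model2 <- make_test_model(n_genes = 2, threshold = 7)
  calls2 <- discretize(expr, model2)
  expect_true(all(is.na(calls2["G02_P1", ])))

  # no overlap at all is an input error
  none <- matrix(1, 1, 1, dimnames = list("XX", "A"))
  expect_error(discretize(none, model), "no overlap")
})

test_that("calibration orients every usable probeset toward the active class", {
  panel <- make_test_panel(n_genes = 4, probesets_per_gene = 2)
  spec <- calibration_cohort_spec(n_active = 20, n_inactive = 20,
                                  delta = 2.0, sigma_probeset = 0.5,
                                  seed = 1)
  sim <- simulate_calibration_cohort(spec, panel)
  model <- calibrate(sim$expr, sim$labels, panel)
  used <- model$probeset_cpt[model$probeset_cpt$included, ]
  expect_identical(nrow(used), 8L)
  expect_true(all(used$c > used$d))
  expect_false(model$frozen)
  expect_true(all(used$c > 0 & used$c < 1 & used$d > 0 & used$d < 1))
})

test_that("large pseudocount drives calibrated probabilities to 1/2", {
  panel <- make_test_panel(2, 1)
  sim <- simulate_calibration_cohort(calibration_cohort_spec(seed = 3), panel)
  model <- calibrate(sim$expr, sim$labels, panel, pseudocount = 1e7)
  used <- model$probeset_cpt[model$probeset_cpt$included, ]
  expect_equal(used$c, rep(0.5, nrow(used)), tolerance = 1e-4)
  expect_equal(used$d, rep(0.5, nrow(used)), tolerance = 1e-4)
})

test_that("degenerate calibrations are caught", {
  panel <- make_test_panel(2, 1)
  sim <- simulate_calibration_cohort(calibration_cohort_spec(seed = 4), panel)
  # single-class cohorts cannot calibrate
  expect_error(
    calibrate(sim$expr, setNames(rep("active", ncol(sim$expr)),
                                 colnames(sim$expr)), panel),
    "non-empty")
  # identical active/inactive copies leave c = d everywhere -> all excluded
  half <- sim$expr[, 1:10]
  twin <- cbind(half, half)
  colnames(twin) <- sprintf("S%02d", seq_len(20))
  labels <- setNames(rep(c("active", "inactive"), each = 10), colnames(twin))
  expect_error(calibrate(twin, labels, panel), "no usable probeset")

  # a constant probeset falls back to the default CPT with a warning
  expr2 <- sim$expr
  expr2["G01_P1", ] <- 5
  expect_warning(m2 <- calibrate(expr2, sim$labels, panel), "constant")
  row <- m2$probeset_cpt[m2$probeset_cpt$probeset_id == "G01_P1", ]
  expect_true(row$included)
  expect_identical(row$reason, "constant_default_cpt")
  expect_gt(row$c, row$d)
})

test_that("exact inference matches hand-derived closed forms", {
  # two genes a=0.9/b=0.1, one probeset each c=0.8/d=0.2, prior 1/2:
  # per-gene factor active 0.9*0.8+0.1*0.2, inactive 0.1*0.8+0.9*0.2
  model <- make_test_model(n_genes = 2, a = 0.9, b = 0.1, c = 0.8, d = 0.2)
  both_high <- setNames(c("high", "high"), c("G01_P1", "G02_P1"))
  expected <- 2 * log2((0.9 * 0.8 + 0.1 * 0.2) / (0.1 * 0.8 + 0.9 * 0.2))
  expect_equal(infer_log2odds(model, both_high), expected, tolerance = 1e-12)

  # complementary CPTs: both-low is the exact negation of both-high
  both_low <- setNames(c("low", "low"), c("G01_P1", "G02_P1"))
  expect_equal(infer_log2odds(model, both_low), -expected, tolerance = 1e-12)

  # uninformative evidence scores 0 under a flat prior: symmetric
  # likelihoods from opposite calls on twin probesets of one gene
  twin <- make_test_model(n_genes = 1, probesets_per_gene = 2)
  sym <- setNames(c("high", "low"), c("G01_P1", "G01_P2"))
  expect_equal(infer_log2odds(twin, sym), 0, tolerance = 1e-12)

  # with symmetric evidence only the prior speaks: log2(0.8/0.2) = 2
  twin8 <- make_test_model(n_genes = 1, probesets_per_gene = 2, prior = 0.8)
  expect_equal(infer_log2odds(twin8, sym), 2, tolerance = 1e-12)
  expect_equal(brute_force_posterior(twin8, sym), 2, tolerance = 1e-12)

  # all calls missing is a scoring error
  expect_error(infer_log2odds(model, setNames(rep(NA_character_, 2),
                                              names(both_high))),
               "all probeset calls missing")
})

test_that("marginalized inference equals brute-force joint enumeration", {
  # 1-gene/1-probeset closed form first
  m1 <- make_test_model(n_genes = 1)
  ev <- c(G01_P1 = "high")
  closed <- log2((0.9 * 0.8 + 0.1 * 0.2) / (0.1 * 0.8 + 0.9 * 0.2))
  expect_equal(brute_force_posterior(m1, ev), closed, tolerance = 1e-12)
  expect_equal(infer_log2odds(m1, ev), closed, tolerance = 1e-12)

  # property: 100 randomized small models and evidence vectors
  withr::local_seed(101)
  max_delta <- 0
  for (i in 1:100) {
    m <- random_small_model()
    e <- random_evidence(m)
    max_delta <- max(max_delta,
                     abs(infer_log2odds(m, e) - brute_force_posterior(m, e)))
  }
  expect_lt(max_delta, 1e-9)

  # oracle refuses oversized state spaces
  big <- make_test_model(n_genes = 25)
  expect_error(brute_force_posterior(big, random_evidence(big)), "2\\^20")
})

test_that("single low->high call flips never decrease the score", {
  withr::local_seed(202)
  for (i in 1:30) {
    m <- random_small_model()
    e <- random_evidence(m, p_missing = 0.3)
    base <- infer_log2odds(m, e)
    lows <- names(e)[!is.na(e) & e == "low"]
    for (ps in lows) {
      flipped <- e
      flipped[ps] <- "high"
      expect_gte(infer_log2odds(m, flipped), base - 1e-12)
    }
  }
})

test_that("a missing call is equivalent to dropping the probeset from the model", {
  model <- make_test_model(n_genes = 2, probesets_per_gene = 2,
                           c = c(0.8, 0.7, 0.9, 0.6), d = c(0.2, 0.3, 0.1, 0.4))
  ev <- setNames(c("high", NA, "low", "high"),
                 model$probeset_cpt$probeset_id)
  reduced <- model
  reduced$probeset_cpt <- reduced$probeset_cpt[-2, ]
  expect_equal(infer_log2odds(model, ev),
               infer_log2odds(reduced, ev[-2]), tolerance = 1e-12)
})

test_that("inverting all calls negates the score under complementary CPTs", {
  withr::local_seed(303)
  for (i in 1:20) {
    m <- make_test_model(n_genes = 3, probesets_per_gene = 2,
                         a = 0.85, b = 0.15, c = 0.75, d = 0.25)
    e <- random_evidence(m, p_missing = 0.25)
    inv <- ifelse(e == "high", "low", "high")
    names(inv) <- names(e)
    expect_equal(infer_log2odds(m, inv), -infer_log2odds(m, e),
                 tolerance = 1e-9)
  }
})

test_that("calibration recovers known per-class call probabilities", {
  # calls generated directly from known class-conditional probabilities
  # (c = 0.9 active, d = 0.1 inactive), encoded as +/-1 around threshold 0
  withr::local_seed(1)
  panel <- make_test_panel(n_genes = 2, probesets_per_gene = 2)
  n <- 200L
  ids <- sprintf("S%03d", 1:(2 * n))
  labels <- setNames(rep(c("active", "inactive"), each = n), ids)
  c_true <- 0.9
  d_true <- 0.1
  expr <- rbind(
    sapply(seq_len(2 * n), function(i) {
      p <- if (labels[i] == "active") c_true else d_true
      ifelse(rbinom(4, 1, p) == 1, 1, -1)
    })
  )
  rownames(expr) <- panel$probesets$id
  colnames(expr) <- ids
  model <- calibrate(expr, labels, panel)
  used <- model$probeset_cpt[model$probeset_cpt$included, ]
  expect_identical(nrow(used), 4L)
  expect_true(all(abs(used$c - c_true) < 0.05))
  expect_true(all(abs(used$d - d_true) < 0.05))
})

test_that("frozen models are immutable, deterministic and serializable", {
  panel <- make_test_panel(3, 2)
  sim <- simulate_calibration_cohort(calibration_cohort_spec(seed = 5), panel)
  model <- calibrate(sim$expr, sim$labels, panel)
  expect_error(infer_log2odds(model, random_evidence(model)), "frozen")
  frozen <- freeze_model(model)

  s1 <- score_samples(frozen, sim$expr)
  s2 <- score_samples(frozen, sim$expr)
  expect_identical(s1, s2)

  # recalibration of a frozen model is refused
  expect_error(calibrate(sim$expr, sim$labels, frozen), "frozen")

  # serialize -> load -> score reproduces scores; content hash verifies
  path <- withr::local_tempfile(fileext = ".json")
  write_model(frozen, path)
  reloaded <- read_model(path)
  expect_equal(score_samples(reloaded, sim$expr)$log2_odds, s1$log2_odds,
               tolerance = 1e-12)
  doc <- jsonlite::read_json(path)
  doc$prior_active <- 0.6
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "hash mismatch")
})

test_that("batch scoring is per-sample independent and order invariant", {
  panel <- make_test_panel(3, 2)
  sim <- simulate_calibration_cohort(
    calibration_cohort_spec(n_active = 20, n_inactive = 20, seed = 2), panel)
  model <- freeze_model(calibrate(sim$expr, sim$labels, panel))
  scores <- score_samples(model, sim$expr)

  # class construction oracle: active samples score higher
  med <- tapply(scores$log2_odds, sim$labels[scores$sample_id], median)
  expect_gt(med[["active"]], med[["inactive"]])

  perm <- sample(ncol(sim$expr))
  scores_perm <- score_samples(model, sim$expr[, perm])
  reord <- scores_perm[match(scores$sample_id, scores_perm$sample_id), ]
  expect_equal(reord$log2_odds, scores$log2_odds)

  # duplicated sample scores identically under a fresh id
  dup <- cbind(sim$expr, DUP = sim$expr[, 1])
  sd <- score_samples(model, dup)
  expect_equal(sd$log2_odds[sd$sample_id == "DUP"],
               sd$log2_odds[sd$sample_id == colnames(sim$expr)[1]])

  # a sample with every probeset missing is reported, not fatal
  holed <- sim$expr
  holed[, 2] <- NA
  sh <- score_samples(model, holed)
  expect_true(is.na(sh$log2_odds[2]))
  expect_identical(attr(sh, "errors")$sample_id, colnames(holed)[2])
  expect_false(anyNA(sh$log2_odds[-2]))

  expect_error(score_samples(model,
                             matrix(numeric(0), 0, 0,
                                    dimnames = list(NULL, NULL))),
               "must have probeset row names|empty")
})
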