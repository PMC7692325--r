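# Fixtures are built in code: synthetic panels, hand-specified small
# Bayesian network models, and randomized model/evidence generators.

make_test_panel <- function(n_genes = 2L, probesets_per_gene = 1L,
                            name = "TestPathway") {
  genes <- sprintf("G%02d", seq_len(n_genes))
  ps <- expand.grid(gene = genes, k = seq_len(probesets_per_gene),
                    stringsAsFactors = FALSE)
  target_gene_panel(
    pathway_name = name,
    genes = genes,
    direction = 1L,
    probesets = data.frame(id = sprintf("%s_P%d", ps$gene, ps$k),
                           gene = ps$gene, included = TRUE,
                           reason = NA_character_,
                           stringsAsFactors = FALSE),
    version = "test"
  )
}

# hand-specified model: scalar or per-probeset c/d, shared a/b
make_test_model <- function(n_genes = 2L, probesets_per_gene = 1L,
                            a = 0.9, b = 0.1, c = 0.8, d = 0.2,
                            threshold = 7, prior = 0.5, frozen = TRUE) {
  panel <- make_test_panel(n_genes, probesets_per_gene)
  map <- panel$probesets
  cpt <- data.frame(probeset_id = map$id, gene = map$gene,
                    c = rep_len(c, nrow(map)), d = rep_len(d, nrow(map)),
                    threshold = rep_len(threshold, nrow(map)),
                    included = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  gene_cpt <- data.frame(gene = panel$genes$symbol,
                         a = rep_len(a, n_genes), b = rep_len(b, n_genes),
                         stringsAsFactors = FALSE)
  new_pathway_model(panel, prior, gene_cpt, cpt, frozen = frozen)
}

# random small model + evidence honoring all invariants (a>b, c>d)
random_small_model <- function(max_genes = 5L, max_ps = 3L) {
  n_genes <- sample.int(max_genes, 1L)
  ppg <- sample.int(max_ps, 1L)
  panel <- make_test_panel(n_genes, ppg)
  map <- panel$probesets
  d_j <- runif(nrow(map), 0.05, 0.45)
  c_j <- runif(nrow(map), 0.55, 0.95)
  b_g <- runif(n_genes, 0.05, 0.45)
  a_g <- runif(n_genes, 0.55, 0.95)
  cpt <- data.frame(probeset_id = map$id, gene = map$gene,
                    c = c_j, d = d_j, threshold = 7,
                    included = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  gene_cpt <- data.frame(gene = panel$genes$symbol, a = a_g, b = b_g,
                         stringsAsFactors = FALSE)
  new_pathway_model(panel, prior_active = runif(1, 0.1, 0.9),
                    gene_cpt = gene_cpt, probeset_cpt = cpt,
                    frozen = TRUE)
}

random_evidence <- function(model, p_missing = 0.2) {
  ids <- model$probeset_cpt$probeset_id
  calls <- sample(c("high", "low"), length(ids), replace = TRUE)
  calls[runif(length(ids)) < p_missing] <- NA_character_
  if (all(is.na(calls))) calls[1L] <- "high"
  stats::setNames(calls, ids)
}

# rank-based AUC of scores for the active class (probability a random
# active sample outscores a random inactive one)
rank_auc <- function(scores, is_active) {
  r <- rank(scores)
  n1 <- sum(is_active)
  n0 <- sum(!is_active)
  (sum(r[is_active]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
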