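#' @title Target gene panels and probeset maps
#' @name genesets
#' @description
#' A pathway assay panel couples an ordered list of direct target genes
#' (each with a regulation sign) to the microarray probesets that measure
#' them. The shipped Notch panel contains the 18 high-evidence direct
#' NOTCH target genes; its HG-U133Plus2.0 probeset mapping is editable
#' configuration data, not code.
NULL

#' Construct a target gene panel
#'
#' @param pathway_name label for the pathway the panel measures.
#' @param genes character vector of unique, uppercase HGNC-style symbols.
#' @param direction integer vector of regulation signs, one per gene;
#'   `+1` means the gene is up-regulated when the pathway is active.
#'   Recycled if length 1.
#' @param probesets data frame with columns `id`, `gene`, `included`
#'   (logical) and `reason` (exclusion reason code, `NA` when included).
#' @param version free-text version label.
#'
#' @return An object of class `target_gene_panel`: a list with fields
#'   `pathway_name`, `genes` (data frame of `symbol`, `direction`),
#'   `probesets` and `version`.
#' @export
target_gene_panel <- function(pathway_name, genes, direction = 1L,
                              probesets, version = "unversioned") {
  if (length(genes) == 0L) {
    stop("panel must contain at least one gene", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  direction <- rep_len(as.integer(direction), length(genes))
  if (!all(direction %in% c(-1L, 1L))) {
    stop("direction must be +1 or -1 for every gene", call. = FALSE)
  }
  probesets <- as.data.frame(probesets, stringsAsFactors = FALSE)
  required <- c("id", "gene", "included", "reason")
  missing_cols <- setdiff(required, names(probesets))
  if (length(missing_cols)) {
    stop("probeset map lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probesets <- probesets[required]
  probesets$id <- as.character(probesets$id)
  probesets$gene <- as.character(probesets$gene)
  probesets$included <- as.logical(probesets$included)
  probesets$reason <- as.character(probesets$reason)
  if (anyDuplicated(probesets$id)) {
    stop("duplicate probeset ids in map", call. = FALSE)
  }
  unknown <- setdiff(probesets$gene, genes)
  if (length(unknown)) {
    stop("probeset map refers to genes outside the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(genes, probesets$gene[probesets$included])
  if (length(uncovered)) {
    stop("panel genes without any included probeset: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      pathway_name = as.character(pathway_name),
      genes = data.frame(symbol = as.character(genes),
                         direction = direction,
                         stringsAsFactors = FALSE),
      probesets = probesets,
      version = as.character(version)
    ),
    class = "target_gene_panel"
  )
}

#' @export
print.target_gene_panel <- function(x, ...) {
  cat(sprintf("<target_gene_panel> %s (version %s)\n",
              x$pathway_name, x$version))
  cat(sprintf("  %d genes, %d probesets (%d included)\n",
              nrow(x$genes), nrow(x$probesets), sum(x$probesets$included)))
  invisible(x)
}

#' Load a panel configuration file
#'
#' Reads a YAML (or JSON, which YAML parses) panel configuration with keys
#' `pathway_name`, `version`, `genes: [{symbol, direction}]` and
#' `probesets: [{id, gene, included, reason}]`, and validates the panel
#' invariants.
#'
#' @param path path to the configuration file. The default loads the
#'   shipped 18-gene Notch panel.
#' @return A [target_gene_panel].
#' @examples
#' panel <- load_panel()
#' nrow(panel$genes)  # 18
#' @export
load_panel <- function(path = system.file("extdata", "notch_panel.yaml",
                                          package = "notchscore")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("panel configuration not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  for (key in c("pathway_name", "genes", "probesets")) {
    if (is.null(cfg[[key]])) {
      stop("panel configuration lacks key '", key, "'", call. = FALSE)
    }
  }
  genes <- vapply(cfg$genes, function(g) as.character(g$symbol), "")
  direction <- vapply(cfg$genes, function(g) {
    if (is.null(g$direction)) 1L else as.integer(g$direction)
  }, 1L)
  ps <- do.call(rbind, lapply(cfg$probesets, function(p) {
    data.frame(
      id = as.character(p$id),
      gene = as.character(p$gene),
      included = if (is.null(p$included)) TRUE else isTRUE(p$included),
      reason = if (is.null(p$reason)) NA_character_ else as.character(p$reason),
      stringsAsFactors = FALSE
    )
  }))
  target_gene_panel(
    pathway_name = cfg$pathway_name,
    genes = genes,
    direction = direction,
    probesets = ps,
    version = if (is.null(cfg$version)) "unversioned" else cfg$version
  )
}

#' Serialize a panel to a configuration file
#'
#' Writes the YAML dialect read by [load_panel()]; `load_panel(write_panel(p))`
#' round-trips to an identical panel.
#'
#' @param panel a [target_gene_panel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "target_gene_panel"))
  cfg <- list(
    pathway_name = panel$pathway_name,
    version = panel$version,
    genes = lapply(seq_len(nrow(panel$genes)), function(i) {
      list(symbol = panel$genes$symbol[i],
           direction = panel$genes$direction[i])
    }),
    probesets = lapply(seq_len(nrow(panel$probesets)), function(i) {
      row <- panel$probesets[i, ]
      out <- list(id = row$id, gene = row$gene, included = row$included)
      if (!is.na(row$reason)) out$reason <- row$reason
      out
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Included probesets for a panel gene
#'
#' @param panel a [target_gene_panel].
#' @param gene gene symbol; must be in the panel.
#' @return Character vector of included probeset ids, in map order
#'   (possibly empty if all of the gene's probesets are excluded).
#' @export
probesets_for_gene <- function(panel, gene) {
  stopifnot(inherits(panel, "target_gene_panel"))
  if (!gene %in% panel$genes$symbol) {
    stop("gene not in panel: ", gene, call. = FALSE)
  }
  ps <- panel$probesets
  ps$id[ps$gene == gene & ps$included]
}
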