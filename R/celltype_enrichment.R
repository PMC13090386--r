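# Cell-type context for rewiring events: altered-transcript definition,
# MAF stratification, the two Fisher enrichment tests, and network degree
# summaries.

#' Default minor-allele-frequency strata
#'
#' Three half-open bins partitioning the rare-variant range below the 10%
#' cohort filter: rare `MAFa [0, 0.02)`, moderately rare `MAFb
#' [0.02, 0.04)` and common `MAFc [0.04, 0.10)` (upper boundary
#' configurable).
#'
#' @param maf_cap upper bound of the common stratum (default 0.10).
#' @return Data frame `label, lo, hi`.
#' @export
maf_strata <- function(maf_cap = 0.10) {
  data.frame(label = c("MAFa", "MAFb", "MAFc"),
             lo = c(0, 0.02, 0.04), hi = c(0.02, 0.04, maf_cap),
             stringsAsFactors = FALSE)
}

#' Assign events to MAF strata
#'
#' Left-closed, right-open binning; every event lands in exactly one
#' stratum. A MAF outside `[0, max hi)` violates the upstream rare-variant
#' filter and is an error.
#'
#' @param events an `rk_events` data frame (with a `maf` column).
#' @param strata a [maf_strata()]-shaped data frame.
#' @return `events` with an added `stratum` column.
#' @export
stratify_by_maf <- function(events, strata = maf_strata()) {
  if (nrow(events) && (any(events$maf < strata$lo[1]) ||
                       any(events$maf >= strata$hi[nrow(strata)])))
    stop("MAF outside the stratified range [",
         strata$lo[1], ", ", strata$hi[nrow(strata)], ")")
  idx <- findInterval(events$maf, strata$lo)
  events$stratum <- strata$label[idx]
  events
}

#' Flag differentially expressed genes per cell type
#'
#' For each gene and cell type, a two-sided Wilcoxon rank-sum test compares
#' the per-cell expression in that cell type against all other cells. The
#' flag is set when the BH q-value (across genes, within the cell type) is
#' below `alpha` and the in-group median is higher. Constant genes are
#' never flagged.
#'
#' @param expr genes x cells numeric matrix (rownames = gene IDs).
#' @param cell_types character vector, one cell-type label per column.
#' @param alpha FDR threshold (default 0.05).
#' @return Logical genes x cell-types matrix.
#' @export
flag_de_genes <- function(expr, cell_types, alpha = 0.05) {
  cts <- sort(unique(cell_types))
  if (length(cts) < 2L) stop("at least two cell types required")
  flags <- matrix(FALSE, nrow(expr), length(cts),
                  dimnames = list(rownames(expr), cts))
  for (ct in cts) {
    inn <- cell_types == ct
    ps <- rep(NA_real_, nrow(expr))
    up <- rep(FALSE, nrow(expr))
    for (g in seq_len(nrow(expr))) {
      x <- expr[g, inn]; y <- expr[g, !inn]
      if (stats::var(c(x, y)) == 0) { ps[g] <- 1; next }
      ps[g] <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      up[g] <- stats::median(x) > stats::median(y)
    }
    flags[, ct] <- bh_fdr(ps) < alpha & up
  }
  flags
}

#' Altered transcripts in one cell type
#'
#' A transcript is altered when (a) it is a gene of a concordant event's
#' promoter anchor, (b) it is expressed in the cell type (mean expression
#' above `floor`, and DE-flagged there when `de_flags` is supplied), and
#' (c) at least one transcription factor whose binding motif the event's
#' variant affects is expressed in the cell type. Events without a motif
#' annotation are excluded and counted in the `n_unannotated` attribute.
#'
#' @param events concordant `rk_events` rows.
#' @param expression genes x cell-types matrix of mean expression.
#' @param tf_map data frame `variant_id, tf` linking each variant to the
#'   TFs whose motifs it alters (TF names must appear in `expression`
#'   rownames to count as expressed).
#' @param cell_type column of `expression` to evaluate.
#' @param floor expression floor defining "expressed" (default 0,
#'   exclusive).
#' @param de_flags optional logical genes x cell-types matrix from
#'   [flag_de_genes()]; when given, genes must also be DE in the cell type.
#' @return Character vector of altered gene IDs with attribute
#'   `n_unannotated`.
#' @export
altered_transcripts <- function(events, expression, tf_map, cell_type,
                                floor = 0, de_flags = NULL) {
  expressed <- function(ids) {
    ids <- ids[ids %in% rownames(expression)]
    ids[expression[ids, cell_type] > floor]
  }
  n_unannot <- 0L
  out <- character()
  for (i in seq_len(nrow(events))) {
    tfs <- tf_map$tf[tf_map$variant_id == events$variant_id[i]]
    if (length(tfs) == 0L) { n_unannot <- n_unannot + 1L; next }
    if (length(expressed(tfs)) == 0L) next
    genes <- strsplit(events$genes[i], ",", fixed = TRUE)[[1]]
    genes <- expressed(genes)
    if (!is.null(de_flags) && length(genes))
      genes <- genes[de_flags[genes, cell_type]]
    out <- c(out, genes)
  }
  structure(sort(unique(out)), n_unannotated = n_unannot)
}

expressed_universe <- function(expression, cell_type, floor, de_flags = NULL) {
  g <- rownames(expression)[expression[, cell_type] > floor]
  if (!is.null(de_flags)) g <- g[de_flags[g, cell_type]]
  g
}

enrichment_fisher <- function(events, expression, tf_map, strata, floor,
                              de_flags, class_label, component) {
  ev <- events[events$component == component &
                 events$concordance == class_label &
                 events$cohort %in% c("case_specific", "control_specific"), ,
               drop = FALSE]
  if (is.null(ev$stratum)) {
    if (is.null(strata)) ev$stratum <- rep("all", nrow(ev))
    else ev <- stratify_by_maf(ev, strata)
  }
  strat_labels <- if (is.null(strata)) "all" else strata$label
  rows <- list()
  for (st in strat_labels) {
    es <- ev[ev$stratum == st, , drop = FALSE]
    if (nrow(es) == 0L) next
    for (ct in colnames(expression)) {
      univ <- expressed_universe(expression, ct, floor, de_flags)
      if (length(univ) == 0L) next
      alt_case <- altered_transcripts(es[es$cohort == "case_specific", , drop = FALSE],
                                      expression, tf_map, ct, floor, de_flags)
      alt_ctrl <- altered_transcripts(es[es$cohort == "control_specific", , drop = FALSE],
                                      expression, tf_map, ct, floor, de_flags)
      a <- length(intersect(alt_case, univ))
      cc <- length(intersect(alt_ctrl, univ))
      ft <- fisher_two_tailed(a, length(univ) - a, cc, length(univ) - cc)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, stratum = st, component = component,
        class = class_label, altered_case = a, altered_control = cc,
        expressed = length(univ), odds_ratio = ft$odds_ratio, p = ft$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cell_type = character(), stratum = character(),
                      component = character(), class = character(),
                      altered_case = integer(), altered_control = integer(),
                      expressed = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric()))
  out <- do.call(rbind, rows)
  # BH family: across cell types within each stratum (x component x class)
  out$q <- stats::ave(out$p, out$stratum, FUN = bh_fdr)
  rownames(out) <- NULL
  out
}

#' Cell-type enrichment test 1 (promoter events)
#'
#' For concordant promoter-component events, compares per cell type and MAF
#' stratum the proportion of altered transcripts among expressed genes
#' between cohorts with a two-tailed Fisher's exact test: the 2x2 table is
#' altered vs expressed-but-not-altered genes, case vs control. q-values
#' are BH across cell types within each stratum.
#'
#' @param events an `rk_events` data frame.
#' @param expression genes x cell-types mean expression matrix.
#' @param tf_map variant-to-TF annotation (see [altered_transcripts()]).
#' @param strata [maf_strata()]-shaped data frame, or `NULL` to pool all
#'   MAFs into one stratum.
#' @param floor expression floor (default 0).
#' @param de_flags optional DE prefilter matrix.
#' @return Data frame with one row per cell type x stratum:
#'   `cell_type, stratum, component, class, altered_case, altered_control,
#'   expressed, odds_ratio, p, q`.
#' @export
enrichment_test1 <- function(events, expression, tf_map, strata = maf_strata(),
                             floor = 0, de_flags = NULL) {
  enrichment_fisher(events, expression, tf_map, strata, floor, de_flags,
                    "concordant", "promoter")
}

#' Cell-type enrichment test 2 (enhancer events)
#'
#' As [enrichment_test1()] but for enhancer-component events, run
#' separately for the concordant and discordant classes (the `class`
#' column distinguishes the result rows).
#'
#' @inheritParams enrichment_test1
#' @return Data frame as in [enrichment_test1()], with both classes.
#' @export
enrichment_test2 <- function(events, expression, tf_map, strata = maf_strata(),
                             floor = 0, de_flags = NULL) {
  rbind(enrichment_fisher(events, expression, tf_map, strata, floor, de_flags,
                          "concordant", "enhancer"),
        enrichment_fisher(events, expression, tf_map, strata, floor, de_flags,
                          "discordant", "enhancer"))
}

#' Network degree summary
#'
#' Node count, unique undirected edge count and average node degree
#' `2|E|/|V|` (rounded to 2 decimals) of a protein-protein interaction
#' network. Duplicate edges are collapsed as unordered pairs; self-loops
#' are an error.
#'
#' @param nodes character vector of node IDs (non-empty, unique).
#' @param edges two-column matrix or data frame of node ID pairs.
#' @return List `n_nodes, n_edges, average_degree`.
#' @examples
#' network_degree_stats(paste0("g", 1:3), rbind(c("g1", "g2"), c("g2", "g3")))
#' @export
network_degree_stats <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0L) stop("empty node list")
  edges <- as.matrix(edges)
  if (nrow(edges)) {
    if (!all(edges %in% nodes)) stop("edge endpoint not in node list")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- ifelse(edges[, 1] < edges[, 2],
                  paste(edges[, 1], edges[, 2]), paste(edges[, 2], edges[, 1]))
    n_edges <- length(unique(key))
  } else n_edges <- 0L
  list(n_nodes = length(nodes), n_edges = n_edges,
       average_degree = round(2 * n_edges / length(nodes), 2))
}
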