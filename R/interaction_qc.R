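# Post-calling interaction filters and cohort-level interaction summaries.

#' Interaction QC thresholds
#'
#' Defaults reproduce the interactome filtering used throughout: at least 5
#' supporting read pairs, Bonferroni-adjusted p below 0.05, cis only,
#' anchor-midpoint distance below 5 Mb, and both restriction-fragment
#' anchors shorter than 7,500 bp. Distance and fragment-length boundaries
#' drop at equality (">= 5 Mb" and ">= 7500 bp" are removed); support keeps
#' at equality (">= 5 pairs" is kept); p keeps strictly below the cutoff.
#'
#' @param min_support minimum supporting pairs (kept when `>=`).
#' @param max_adj_p adjusted-p cutoff (kept when `<`).
#' @param max_distance distance cutoff in bp (dropped when `>=`).
#' @param max_fragment_len anchor length cutoff in bp (dropped when `>=`).
#' @return A list of class `rk_qc_thresholds`.
#' @export
qc_thresholds <- function(min_support = 5L, max_adj_p = 0.05,
                          max_distance = 5e6, max_fragment_len = 7500) {
  stopifnot(min_support > 0, max_adj_p > 0, max_distance > 0, max_fragment_len > 0)
  structure(list(min_support = min_support, max_adj_p = max_adj_p,
                 max_distance = max_distance, max_fragment_len = max_fragment_len),
            class = "rk_qc_thresholds")
}

#' Filter per-patient interactions
#'
#' An interaction is kept iff it passes every rule:
#' `support_pairs >= min_support`, `adj_p < max_adj_p`, cis,
#' `distance < max_distance`, and both anchor widths `< max_fragment_len`.
#' Each dropped row is attributed to its first failing rule in the fixed
#' order support, p, trans, distance, fragment, so the drop counts
#' partition the removed set reproducibly.
#'
#' @param interactions an `rk_interactions` data frame.
#' @param thresholds a [qc_thresholds()] object.
#' @return List with `kept` (filtered `rk_interactions`), `drops` (named
#'   integer vector of first-failing-rule counts) and `n_input`.
#' @export
filter_interactions <- function(interactions, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "rk_qc_thresholds"))
  x <- interactions
  w1 <- x$end1 - x$start1
  w2 <- x$end2 - x$start2
  fail_support <- x$support_pairs < thresholds$min_support
  fail_p <- !(x$adj_p < thresholds$max_adj_p)
  fail_trans <- x$trans
  fail_dist <- !x$trans & x$distance >= thresholds$max_distance
  fail_frag <- w1 >= thresholds$max_fragment_len | w2 >= thresholds$max_fragment_len
  first <- rep(NA_character_, nrow(x))
  for (rule in c("fragment", "distance", "trans", "p", "support")) {
    fl <- switch(rule, support = fail_support, p = fail_p, trans = fail_trans,
                 distance = fail_dist, fragment = fail_frag)
    first[fl] <- rule  # later assignments (earlier rules) overwrite
  }
  kept <- x[is.na(first), , drop = FALSE]
  rownames(kept) <- NULL
  drops <- table(factor(first, levels = c("support", "p", "trans", "distance", "fragment")))
  list(kept = structure(kept, class = class(interactions)),
       drops = stats::setNames(as.integer(drops), names(drops)),
       n_input = nrow(x))
}

#' Cohort-level interaction summary
#'
#' Counts group-specific unique interactions (uniqueness key = promoter
#' anchor x PIR anchor): an interaction is group-specific when it is
#' observed only in patients of that group. When `regions` is supplied,
#' group-specific gene and enhancer counts are derived from the promoter
#' anchor annotation and the PIR anchor identity. The case:control ratio of
#' group-specific interaction counts is reported to one decimal.
#'
#' @param kept QC-passing `rk_interactions`.
#' @param cohort an [cohort()] object.
#' @param regions optional `rk_regions` for gene/enhancer counting.
#' @return List with per-group counts (`case`, `control`, each holding
#'   `interactions`, and `genes`/`enhancers` when resolvable), `shared`
#'   (interactions seen in both groups), `ratio` and `ratio_defined`.
#' @export
cohort_interaction_summary <- function(kept, cohort, regions = NULL) {
  stopifnot_cohort(cohort)
  grp <- unname(cohort$group[kept$patient])
  case_seen <- unique(kept$key[grp == "case"])
  ctrl_seen <- unique(kept$key[grp == "control"])
  case_keys <- case_seen[!(case_seen %in% ctrl_seen)]
  ctrl_keys <- ctrl_seen[!(ctrl_seen %in% case_seen)]
  shared_keys <- case_seen[case_seen %in% ctrl_seen]
  n_case <- length(case_keys)
  n_ctrl <- length(ctrl_keys)
  ratio_defined <- n_ctrl > 0 && any(cohort$group == "case")
  ratio <- if (ratio_defined) round(n_case / n_ctrl, 1) else NA_real_
  out <- list(case = list(interactions = n_case),
              control = list(interactions = n_ctrl),
              shared = length(shared_keys),
              ratio = ratio, ratio_defined = ratio_defined)
  if (!is.null(regions)) {
    first <- kept[!duplicated(kept$key), , drop = FALSE]
    rownames(first) <- NULL
    prom_key <- paste0(first$chrom1, ":", first$start1, "-", first$end1)
    reg_key <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
    genes_of <- function(ks) {
      idx <- match(prom_key[match(ks, first$key)], reg_key)
      gl <- regions$gene_ids[idx]
      unique(unlist(strsplit(gl[!is.na(gl) & gl != "."], ",", fixed = TRUE)))
    }
    enh_of <- function(ks) {
      f <- first[match(ks, first$key), , drop = FALSE]
      unique(paste0(f$chrom2, ":", f$start2, "-", f$end2))
    }
    out$case$genes <- length(genes_of(case_keys))
    out$case$enhancers <- length(enh_of(case_keys))
    out$control$genes <- length(genes_of(ctrl_keys))
    out$control$enhancers <- length(enh_of(ctrl_keys))
  }
  out
}
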