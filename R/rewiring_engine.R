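# Core analysis: integrate variants with patient interactomes and classify
# chromatin rewiring events by direction, genotype concordance and cohort
# specificity.

#' Classify one (variant, interaction) rewiring event
#'
#' Given the carrier set of a variant and the presence set of an interaction
#' (the patients in whom it passed QC), the event is:
#' * gain-of-interaction (GoI), concordant — presence is a subset of the
#'   carriers: the interaction is seen exclusively in variant carriers;
#' * loss-of-interaction (LoI), concordant — presence is a subset of the
#'   non-carriers: the interaction is seen exclusively in non-carriers;
#' * discordant — presence spans both genotype classes; the direction is
#'   then assigned by the majority presence rate (GoI when the carrier rate
#'   is at least the non-carrier rate).
#'
#' With `semantics = "equality"`, concordance additionally requires the
#' presence set to equal the carrier set (GoI) or its complement (LoI).
#' Variants with no carriers, or carried by every patient, provide no
#' genotype contrast and yield no event (`NULL`).
#'
#' @param carriers character vector of carrier patient IDs.
#' @param presence character vector of patients showing the interaction.
#' @param all_patients character vector of all cohort patients.
#' @param semantics `"subset"` (default) or `"equality"` concordance rule.
#' @return `list(direction, concordance)` or `NULL` for uninformative
#'   carrier sets.
#' @examples
#' pts <- paste0("P", 1:16)
#' classify_event("P1", "P1", pts)           # GoI, concordant
#' classify_event("P1", setdiff(pts, "P1"), pts)  # LoI, concordant
#' @export
classify_event <- function(carriers, presence, all_patients,
                           semantics = c("subset", "equality")) {
  semantics <- match.arg(semantics)
  carriers <- unique(carriers)
  presence <- unique(presence)
  if (length(presence) == 0L) stop("presence set must be non-empty")
  if (!all(presence %in% all_patients) || !all(carriers %in% all_patients))
    stop("carriers and presence must be subsets of all_patients")
  if (length(carriers) == 0L || length(carriers) == length(all_patients))
    return(NULL)
  non <- setdiff(all_patients, carriers)
  in_c <- presence %in% carriers
  if (semantics == "subset") {
    if (all(in_c)) return(list(direction = "GoI", concordance = "concordant"))
    if (!any(in_c)) return(list(direction = "LoI", concordance = "concordant"))
  } else {
    if (setequal(presence, carriers))
      return(list(direction = "GoI", concordance = "concordant"))
    if (setequal(presence, non))
      return(list(direction = "LoI", concordance = "concordant"))
  }
  rate_c <- sum(in_c) / length(carriers)
  rate_n <- sum(!in_c) / length(non)
  list(direction = if (rate_c >= rate_n) "GoI" else "LoI",
       concordance = "discordant")
}

#' Cohort specificity of a carrier set
#'
#' @param carriers character vector of carrier patient IDs (non-empty).
#' @param cohort an [cohort()] object.
#' @return `"case_specific"`, `"control_specific"` or `"shared"`.
#' @export
assign_cohort_specificity <- function(carriers, cohort) {
  stopifnot_cohort(cohort)
  if (length(carriers) == 0L) stop("carriers must be non-empty")
  g <- unique(unname(cohort$group[carriers]))
  if (anyNA(g)) stop("carrier not in cohort")
  if (identical(g, "case")) "case_specific"
  else if (identical(g, "control")) "control_specific"
  else "shared"
}

#' Enumerate rewiring events
#'
#' One event is produced per (variant, interaction key, component) where
#' the variant's reference footprint overlaps the promoter anchor
#' (`component = "promoter"`) or the PIR anchor (`component = "enhancer"`)
#' of a QC-passing interaction. Carriers are patients with alt dosage >= 1;
#' presence is the set of patients in whom the interaction passed QC.
#' Uninformative variants (no carriers or all patients carriers) are
#' skipped. Interaction anchors are resolved to regions by exact
#' coordinate identity.
#'
#' @param variants `rk_variants` (already MAF-filtered).
#' @param interactions QC-passing `rk_interactions`.
#' @param regions `rk_regions` covering both anchor sets.
#' @param cohort an [cohort()] object.
#' @param semantics concordance rule passed to [classify_event()].
#' @return Data frame of class `rk_events` with columns `variant_id, key,
#'   component, direction, concordance, cohort, maf, genes, carriers,
#'   presence` (ID lists comma-joined).
#' @export
enumerate_events <- function(variants, interactions, regions, cohort,
                             semantics = c("subset", "equality")) {
  semantics <- match.arg(semantics)
  stopifnot_cohort(cohort)
  empty <- data.frame(variant_id = character(), key = character(),
                      component = character(), direction = character(),
                      concordance = character(), cohort = character(),
                      maf = numeric(), genes = character(),
                      carriers = character(), presence = character(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || nrow(interactions) == 0L)
    return(structure(empty, class = c("rk_events", "data.frame")))

  reg_key <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  prom_anchor <- paste0(interactions$chrom1, ":", interactions$start1, "-", interactions$end1)
  pir_anchor <- paste0(interactions$chrom2, ":", interactions$start2, "-", interactions$end2)
  prom_reg <- regions$region_id[match(prom_anchor, reg_key)]
  pir_reg <- regions$region_id[match(pir_anchor, reg_key)]
  if (anyNA(prom_reg) || anyNA(pir_reg))
    stop("interaction anchor without a matching region record")

  # interaction key -> presence set and anchor regions
  first <- !duplicated(interactions$key)
  key_tab <- data.frame(key = interactions$key[first],
                        prom_reg = prom_reg[first], pir_reg = pir_reg[first],
                        stringsAsFactors = FALSE)
  presence_by_key <- split(interactions$patient, interactions$key)

  ov <- overlap_variants_regions(variants, regions)
  if (nrow(ov) == 0L)
    return(structure(empty, class = c("rk_events", "data.frame")))

  dos <- dosage_matrix(variants)
  carriers_by_var <- apply(dos >= 1L, 1L, function(z) colnames(dos)[z], simplify = FALSE)
  maf_by_var <- stats::setNames(variants$maf, variants$variant_id)
  genes_by_reg <- stats::setNames(regions$gene_ids, regions$region_id)

  # join variant-region overlaps to interactions on the matching anchor
  hit_prom <- merge(ov[ov$role == "promoter", c("variant_id", "region_id")],
                    key_tab, by.x = "region_id", by.y = "prom_reg")
  hit_pir <- merge(ov[ov$role == "enhancer", c("variant_id", "region_id")],
                   key_tab, by.x = "region_id", by.y = "pir_reg")
  cand <- rbind(
    if (nrow(hit_prom)) data.frame(variant_id = hit_prom$variant_id, key = hit_prom$key,
                                   component = "promoter", prom_reg = hit_prom$region_id,
                                   stringsAsFactors = FALSE),
    if (nrow(hit_pir)) data.frame(variant_id = hit_pir$variant_id, key = hit_pir$key,
                                  component = "enhancer", prom_reg = hit_pir$prom_reg,
                                  stringsAsFactors = FALSE))
  if (is.null(cand) || nrow(cand) == 0L)
    return(structure(empty, class = c("rk_events", "data.frame")))
  cand <- cand[!duplicated(cand[, c("variant_id", "key", "component")]), , drop = FALSE]
  cand <- cand[order(cand$variant_id, cand$key, cand$component), , drop = FALSE]

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    vid <- cand$variant_id[i]
    carriers <- carriers_by_var[[vid]]
    presence <- unique(presence_by_key[[cand$key[i]]])
    cls <- classify_event(carriers, presence, cohort$patients, semantics)
    if (is.null(cls)) next
    rows[[i]] <- data.frame(
      variant_id = vid, key = cand$key[i], component = cand$component[i],
      direction = cls$direction, concordance = cls$concordance,
      cohort = assign_cohort_specificity(carriers, cohort),
      maf = unname(maf_by_var[vid]),
      genes = unname(genes_by_reg[cand$prom_reg[i]]),
      carriers = paste(sort(carriers), collapse = ","),
      presence = paste(sort(presence), collapse = ","),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  structure(out, class = c("rk_events", "data.frame"))
}

#' Two-tailed Fisher's exact test with sample cross-product odds ratio
#'
#' The odds ratio reported is the sample cross-product `(a*d)/(b*c)` (not
#' the conditional MLE): `Inf` when `b*c = 0` with `a*d > 0`, and `NaN`
#' (flagged undefined) for 0/0. The two-sided p-value uses the exact
#' hypergeometric point-probability rule.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome; `a/b` vs `c/d` is the compared odds.
#' @return `list(odds_ratio, p)`.
#' @examples
#' fisher_two_tailed(851, 7839, 230, 3853)$odds_ratio  # 1.819
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) stop("cell counts must be non-negative")
  if (sum(cells) == 0) stop("empty table")
  or <- (a * d) / (b * c)
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  list(odds_ratio = or, p = p)
}

#' Rate ratio of two proportions
#'
#' `(a/b) / (c/d)` — e.g. the fold difference in tier-gene vs housekeeping
#' event prevalence between cohorts.
#'
#' @param a,b,c,d non-negative counts.
#' @return Numeric scalar.
#' @export
rate_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  (a / b) / (c / d)
}

#' Direction shares among concordant events
#'
#' Percentage of loss-of-interaction among concordant events per cohort,
#' and the overall gain-of-interaction share, from raw direction counts.
#'
#' @param case_loi,case_goi,control_loi,control_goi concordant event counts.
#' @return List with `case_loi_pct`, `control_loi_pct` (each
#'   `100 * LoI / (LoI + GoI)`) and `goi_pct` (GoI share of all concordant
#'   events, both cohorts pooled).
#' @export
direction_shares <- function(case_loi, case_goi, control_loi, control_goi) {
  share <- function(l, g) if (l + g == 0) 0 else 100 * l / (l + g)
  list(case_loi_pct = share(case_loi, case_goi),
       control_loi_pct = share(control_loi, control_goi),
       goi_pct = share(case_goi + control_goi, case_loi + control_loi))
}

event_gene_list <- function(events) strsplit(events$genes, ",", fixed = TRUE)

#' Summary table of rewiring events
#'
#' Produces the numerical overview of the event-filtering strategy: event
#' counts per cohort specificity x component x concordance; LoI/GoI counts
#' and LoI percentage among concordant events per cohort; the overall GoI
#' share; and, when a gene annotation is given, tier-1/2 versus
#' housekeeping event counts per cohort for the concordant and discordant
#' sets with the Fisher odds ratio, p-value and rate ratio. An event counts
#' toward the tier (housekeeping) column when any gene of its promoter
#' anchor is a tier-1/2 (housekeeping) gene; cohort-shared events are not
#' part of the per-cohort columns.
#'
#' @param events an `rk_events` data frame.
#' @param gene_annotation optional `rk_genes` data frame.
#' @return List with `counts` (cohort x component x concordance table),
#'   `direction` (per-cohort LoI/GoI counts and percentage shares, see
#'   [direction_shares()]), and `tier_enrichment` (per concordance class:
#'   counts, `odds_ratio`, `p`, `rate_ratio`) when annotated.
#' @export
table1_summary <- function(events, gene_annotation = NULL) {
  counts <- table(cohort = events$cohort, component = events$component,
                  concordance = events$concordance)
  conc <- events[events$concordance == "concordant", , drop = FALSE]
  n_dir <- function(coh, dir)
    sum(conc$cohort == coh & conc$direction == dir)
  dirs <- list(case_loi = n_dir("case_specific", "LoI"),
               case_goi = n_dir("case_specific", "GoI"),
               control_loi = n_dir("control_specific", "LoI"),
               control_goi = n_dir("control_specific", "GoI"))
  shares <- direction_shares(dirs$case_loi, dirs$case_goi,
                             dirs$control_loi, dirs$control_goi)
  shares$case_loi_pct <- round(shares$case_loi_pct, 2)
  shares$control_loi_pct <- round(shares$control_loi_pct, 2)
  out <- list(counts = counts, direction = c(dirs, shares))
  if (!is.null(gene_annotation)) {
    tier_genes <- gene_annotation$gene_id[gene_annotation$tier %in% c("tier1", "tier2")]
    hk_genes <- gene_annotation$gene_id[gene_annotation$housekeeping]
    out$tier_enrichment <- lapply(c(concordant = "concordant", discordant = "discordant"),
                                  function(cl) {
      e <- events[events$concordance == cl, , drop = FALSE]
      gl <- event_gene_list(e)
      is_tier <- vapply(gl, function(g) any(g %in% tier_genes), logical(1))
      is_hk <- vapply(gl, function(g) any(g %in% hk_genes), logical(1))
      a <- sum(e$cohort == "case_specific" & is_tier)
      b <- sum(e$cohort == "case_specific" & is_hk)
      cc <- sum(e$cohort == "control_specific" & is_tier)
      d <- sum(e$cohort == "control_specific" & is_hk)
      ft <- if (all(c(a + b, cc + d) > 0) && b > 0 && d > 0)
        fisher_two_tailed(a, b, cc, d) else list(odds_ratio = NA_real_, p = NA_real_)
      list(case_tier = a, case_housekeeping = b,
           control_tier = cc, control_housekeeping = d,
           odds_ratio = ft$odds_ratio, p = ft$p,
           rate_ratio = if (b > 0 && d > 0 && cc > 0) rate_ratio(a, b, cc, d) else NA_real_)
    })
  }
  out
}
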