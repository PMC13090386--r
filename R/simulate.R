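# Synthetic cohort generator: fully specified patient cohorts with planted
# rewiring events, allelic imbalance and cell-type burden, so every
# pipeline stage can be validated against known truth without
# controlled-access patient data.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the analysed design: two
#' patient groups of eight, heterozygous rare variants (MAF < 10%) spread
#' over the three MAF strata, patient-specific interaction sets with
#' planted concordant gain-/loss-of-interaction events on top of a
#' background interactome shared by all patients, overdispersed allelic
#' read counts with planted imbalance, and a mean expression profile with
#' a planted case burden in one target cell type.
#'
#' @param n_case,n_control patients per group (default 8 + 8).
#' @param n_genes,n_promoters,n_enhancers annotation sizes. One gene per
#'   promoter, assigned round-robin.
#' @param n_variants total short variants including planted ones.
#' @param maf_props probabilities of the MAFa/MAFb/MAFc strata for
#'   background variant population MAFs.
#' @param n_planted_goi,n_planted_loi concordant events planted with
#'   case-specific (GoI) and control-specific (LoI) carrier sets.
#' @param n_planted_discordant planted discordant events (presence spans
#'   both genotype classes).
#' @param n_background_interactions interactions present in every patient.
#' @param planted_component_split fraction of planted concordant events
#'   whose variant sits in the promoter anchor (the rest in the PIR).
#' @param planted_stratum MAF stratum of planted-event variants.
#' @param ase list: `n_imbalanced_genes`, `n_null_genes`, `snvs_per_gene`,
#'   `patients_per_gene`, `alt_fraction`, `rho`, `mean_depth`.
#' @param expression list: `n_cell_types`, `cells_per_type` (0 disables
#'   the per-cell matrix), `n_de_genes`, `de_effect_size`, `baseline`, and
#'   `expressed_fraction` (probability that a gene/TF is expressed in a
#'   given cell type; 1 = expressed everywhere).
#' @param burden list: `target_cell_type` (index into the cell types) for
#'   the planted case burden, `enabled` (set `FALSE` for a no-effect null
#'   cohort in which case-event TFs are expressed like everything else).
#' @param seed mandatory integer root seed.
#' @return A list of class `rk_sim_config`.
#' @export
sim_config <- function(n_case = 8L, n_control = 8L,
                       n_genes = 500L, n_promoters = 500L, n_enhancers = 1500L,
                       n_variants = 2000L,
                       maf_props = c(MAFa = 0.5, MAFb = 0.3, MAFc = 0.2),
                       n_planted_goi = 50L, n_planted_loi = 20L,
                       n_planted_discordant = 30L,
                       n_background_interactions = 1000L,
                       planted_component_split = 0.5,
                       planted_stratum = "MAFa",
                       ase = list(), expression = list(), burden = list(),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  ase <- utils::modifyList(list(n_imbalanced_genes = 10L, n_null_genes = 200L,
                                snvs_per_gene = 5L, patients_per_gene = 4L,
                                alt_fraction = 0.8, rho = 0.05,
                                mean_depth = 40), ase)
  expression <- utils::modifyList(list(n_cell_types = 4L, cells_per_type = 0L,
                                       n_de_genes = 20L, de_effect_size = 2,
                                       baseline = 5, expressed_fraction = 1),
                                  expression)
  burden <- utils::modifyList(list(target_cell_type = 1L, enabled = TRUE), burden)
  cfg <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_promoters = n_promoters, n_enhancers = n_enhancers,
              n_variants = n_variants, maf_props = maf_props,
              n_planted_goi = n_planted_goi, n_planted_loi = n_planted_loi,
              n_planted_discordant = n_planted_discordant,
              n_background_interactions = n_background_interactions,
              planted_component_split = planted_component_split,
              planted_stratum = planted_stratum,
              ase = ase, expression = expression, burden = burden,
              seed = as.integer(seed))
  n_planted <- n_planted_goi + n_planted_loi + n_planted_discordant
  if (n_planted > n_promoters || n_planted > n_enhancers)
    stop("infeasible config: more planted events than promoter/enhancer slots")
  if (n_planted > n_variants)
    stop("infeasible config: more planted events than variants")
  structure(cfg, class = "rk_sim_config")
}

rbetabinom_mu <- function(n, size, mu, rho) {
  if (rho == 0) return(stats::rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

stratum_interval <- function(label, strata = maf_strata()) {
  i <- match(label, strata$label)
  c(strata$lo[i], strata$hi[i])
}

#' Simulate a synthetic cohort bundle
#'
#' Deterministic given `config$seed` (each stage reseeds from a fixed
#' offset of the root seed so stages can be regenerated in isolation).
#' Planted concordant events are constructed by sampling a carrier set
#' within one cohort and setting the interaction presence equal to the
#' carriers (gain-of-interaction) or to their complement
#' (loss-of-interaction); background interactions are present in every
#' patient, so any variant falling on them yields a discordant event.
#' Planted anchors and variants use reserved regions that background
#' interactions and variants never touch, making recovery noiseless by
#' construction.
#'
#' @param config an [sim_config()] object.
#' @param dir optional directory; when given, the bundle is also written
#'   as plain-text files (`variants.vcf`, `variants.tsv`,
#'   `interactions.tsv`, `regions.bed`, `genes.tsv`, `ase_counts.tsv`,
#'   `snv2gene.tsv`, `expression_mean.tsv`, `truth_events.tsv`,
#'   `truth_ase.tsv`).
#' @return List of class `rk_sim` with elements `cohort`, `variants`,
#'   `interactions`, `regions`, `genes`, `ase_counts`, `snv2gene`,
#'   `expression` (list: `mean`, optional `cells`/`cell_types`), `tf_map`,
#'   `truth` (lists planted event labels, imbalanced genes, DE flags and
#'   the burden cell type) and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "rk_sim_config"))
  cfg <- config
  co <- cohort(sprintf("case%02d", seq_len(cfg$n_case)),
               sprintf("ctrl%02d", seq_len(cfg$n_control)))
  n_pat <- length(co$patients)

  ## ---- regions & genes (seed + 1) ----------------------------------------
  set.seed(cfg$seed + 1L)
  total <- cfg$n_promoters + cfg$n_enhancers
  roles <- rep("enhancer", total)
  roles[round(seq(1, total, length.out = cfg$n_promoters))] <- "promoter"
  widths <- ifelse(roles == "promoter", 1000L, 800L)
  gaps <- 500L
  starts <- cumsum(c(0L, widths[-total] + gaps))
  ends <- starts + widths
  pid <- cumsum(roles == "promoter")
  eid <- cumsum(roles == "enhancer")
  region_id <- ifelse(roles == "promoter", sprintf("prom%05d", pid),
                      sprintf("enh%05d", eid))
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  prom_gene <- gene_ids[((seq_len(cfg$n_promoters) - 1L) %% cfg$n_genes) + 1L]
  genes_col <- rep(".", total)
  genes_col[roles == "promoter"] <- prom_gene
  regions <- structure(
    data.frame(region_id = region_id, chrom = "chrS", start = starts,
               end = ends, strand = "+", role = roles, gene_ids = genes_col,
               stringsAsFactors = FALSE),
    class = c("rk_regions", "data.frame"))
  # tier / housekeeping annotation: disjoint blocks of the gene list
  n_tier <- max(1L, round(0.1 * cfg$n_genes))
  n_hk <- max(1L, round(0.3 * cfg$n_genes))
  tier <- rep("none", cfg$n_genes)
  tier[seq_len(n_tier)] <- rep(c("tier1", "tier2"), length.out = n_tier)
  hk <- rep(FALSE, cfg$n_genes)
  hk[(n_tier + 1L):(n_tier + n_hk)] <- TRUE
  genes <- structure(
    data.frame(gene_id = gene_ids, tier = tier, housekeeping = hk,
               endothelial_specific = rep(FALSE, cfg$n_genes),
               stringsAsFactors = FALSE),
    class = c("rk_genes", "data.frame"))

  prom_idx <- which(roles == "promoter")
  enh_idx <- which(roles == "enhancer")
  n_planted <- cfg$n_planted_goi + cfg$n_planted_loi + cfg$n_planted_discordant
  res_prom <- prom_idx[seq_len(n_planted)]
  # reserved enhancer for planted event k: nearest enhancer after its promoter
  res_enh <- vapply(res_prom, function(i) enh_idx[enh_idx > i][1], integer(1))
  if (anyNA(res_enh) || anyDuplicated(res_enh))
    stop("infeasible config: cannot reserve distinct enhancers for planted events")
  free_prom <- setdiff(prom_idx, res_prom)
  free_enh <- setdiff(enh_idx, res_enh)

  ## ---- interactions (seed + 2) -------------------------------------------
  set.seed(cfg$seed + 2L)
  mids <- (starts + ends) / 2
  bg_pairs <- matrix(integer(0), ncol = 2)
  while (nrow(bg_pairs) < cfg$n_background_interactions) {
    need <- cfg$n_background_interactions - nrow(bg_pairs)
    p <- sample(free_prom, need, replace = TRUE)
    e <- sample(free_enh, need, replace = TRUE)
    ok <- abs(mids[e] - mids[p]) < 5e6 & p != e
    bg_pairs <- unique(rbind(bg_pairs, cbind(p, e)[ok, , drop = FALSE]))
  }
  bg_pairs <- bg_pairs[seq_len(cfg$n_background_interactions), , drop = FALSE]
  inter_rows <- function(pi, ei, patients) {
    n <- length(patients)
    data.frame(chrom1 = "chrS", start1 = starts[pi], end1 = ends[pi],
               chrom2 = "chrS", start2 = starts[ei], end2 = ends[ei],
               patient = patients, support_pairs = 5L + sample.int(25L, n, replace = TRUE),
               adj_p = stats::runif(n, 1e-8, 0.049), stringsAsFactors = FALSE)
  }
  # background interactions are present in every patient
  pr <- rep(bg_pairs[, 1], each = n_pat)
  er <- rep(bg_pairs[, 2], each = n_pat)
  inter <- list(inter_rows(pr, er, rep(co$patients, nrow(bg_pairs))))

  ## ---- planted events & variants (seed + 3) ------------------------------
  set.seed(cfg$seed + 3L)
  cases <- cohort_group(co, "case")
  ctrls <- cohort_group(co, "control")
  kinds <- rep(c("GoI", "LoI", "discordant"),
               c(cfg$n_planted_goi, cfg$n_planted_loi, cfg$n_planted_discordant))
  n_prom_comp <- round(cfg$planted_component_split * (cfg$n_planted_goi + cfg$n_planted_loi))
  components <- character(n_planted)
  conc_idx <- which(kinds != "discordant")
  components[conc_idx] <- rep(c("promoter", "enhancer"),
                              c(n_prom_comp, length(conc_idx) - n_prom_comp))
  components[kinds == "discordant"] <- rep(c("promoter", "enhancer"),
                                           length.out = cfg$n_planted_discordant)
  strat_iv <- stratum_interval(cfg$planted_stratum)
  var_rows <- list()
  truth_rows <- list()
  for (k in seq_len(n_planted)) {
    pi <- res_prom[k]; ei <- res_enh[k]
    kind <- kinds[k]
    if (kind == "GoI") {
      carriers <- sample(cases, sample.int(3L, 1L))
      presence <- carriers
      lab <- c("GoI", "concordant")
    } else if (kind == "LoI") {
      carriers <- sample(ctrls, sample.int(3L, 1L))
      presence <- setdiff(co$patients, carriers)
      lab <- c("LoI", "concordant")
    } else {
      carriers <- c(sample(cases, 1L), sample(ctrls, 1L))
      presence <- c(carriers[1], sample(setdiff(co$patients, carriers), 2L))
      lab <- c("GoI", "discordant")  # carrier rate 1/2 > non-carrier 2/14
    }
    inter[[length(inter) + 1L]] <- inter_rows(rep(pi, length(presence)),
                                              rep(ei, length(presence)), presence)
    ri <- if (components[k] == "promoter") pi else ei
    pos <- starts[ri] + sample.int(widths[ri], 1L) - 1L
    maf <- stats::runif(1, strat_iv[1], strat_iv[2])
    dos <- stats::setNames(as.integer(co$patients %in% carriers), co$patients)
    var_rows[[k]] <- c(list(chrom = "chrS", pos = pos, end = pos + 1L,
                            ref = "A", alt = "G", maf = maf, kind = "snv"),
                       as.list(dos))
    truth_rows[[k]] <- data.frame(
      variant_id = variant_id("chrS", pos, "A", "G"),
      key = paste0("chrS:", starts[pi], "-", ends[pi], "|chrS:",
                   starts[ei], "-", ends[ei]),
      component = components[k], direction = lab[1], concordance = lab[2],
      cohort = assign_cohort_specificity(carriers, co),
      planted = kind, stringsAsFactors = FALSE)
  }

  ## ---- background variants (seed + 4) ------------------------------------
  set.seed(cfg$seed + 4L)
  n_bg_var <- cfg$n_variants - n_planted
  strata <- maf_strata()
  free_regions <- c(free_prom, free_enh)
  ri <- sample(free_regions, n_bg_var, replace = TRUE)
  pos <- starts[ri] + vapply(widths[ri], sample.int, integer(1), size = 1L) - 1L
  st <- sample(strata$label, n_bg_var, replace = TRUE,
               prob = cfg$maf_props[strata$label])
  si <- match(st, strata$label)
  maf_bg <- stats::runif(n_bg_var, strata$lo[si], strata$hi[si])
  dos_bg <- matrix(0L, n_bg_var, n_pat, dimnames = list(NULL, co$patients))
  for (k in seq_len(n_bg_var))
    dos_bg[k, sample(co$patients, sample.int(3L, 1L))] <- 1L
  planted_df <- do.call(rbind, lapply(var_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  bg_df <- data.frame(chrom = "chrS", pos = pos, end = pos + 1L, ref = "A",
                      alt = "G", maf = maf_bg, kind = "snv", dos_bg,
                      stringsAsFactors = FALSE, check.names = FALSE)
  variants <- rbind(stats::setNames(planted_df,
                                    c("chrom", "pos", "end", "ref", "alt",
                                      "maf", "kind", co$patients)),
                    bg_df)
  # positions may collide within a region; keep the first occurrence
  vids <- variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  dup <- duplicated(vids)
  variants <- variants[!dup, , drop = FALSE]
  variants <- cbind(variant_id = vids[!dup], variants)
  rownames(variants) <- NULL
  variants <- structure(variants, class = c("rk_variants", "data.frame"),
                        patients = co$patients, n_skipped_multiallelic = 0L,
                        n_malformed = 0L, n_dropped_maf = 0L)
  truth_events <- do.call(rbind, truth_rows)
  truth_events <- truth_events[truth_events$variant_id %in% variants$variant_id, ,
                               drop = FALSE]
  interactions <- as_interactions(do.call(rbind, inter))

  ## ---- allelic counts (seed + 5) ------------------------------------------
  set.seed(cfg$seed + 5L)
  a <- cfg$ase
  ase_gene_ids <- gene_ids[seq_len(min(cfg$n_genes,
                                       a$n_imbalanced_genes + a$n_null_genes))]
  imb <- c(rep(TRUE, a$n_imbalanced_genes),
           rep(FALSE, length(ase_gene_ids) - a$n_imbalanced_genes))
  n_ase_g <- length(ase_gene_ids)
  pats_of_gene <- lapply(seq_len(n_ase_g), function(i)
    sample(co$patients, a$patients_per_gene))
  grid <- expand.grid(pt = seq_len(a$patients_per_gene),
                      s = seq_len(a$snvs_per_gene), g = seq_len(n_ase_g))
  n_rows <- nrow(grid)
  if (n_rows > 0L) {
    depth <- 20L + stats::rpois(n_rows, a$mean_depth)
    mu <- ifelse(imb[grid$g], a$alt_fraction, 0.5)
    alt <- rbetabinom_mu(n_rows, depth, mu, a$rho)
    ase_counts <- data.frame(
      variant_id = sprintf("ase:%s:%d", ase_gene_ids[grid$g], grid$s),
      patient = vapply(seq_len(n_rows), function(i)
        pats_of_gene[[grid$g[i]]][grid$pt[i]], character(1)),
      ref_n = depth - alt, alt_n = alt, gq = 60L, dp = depth,
      stringsAsFactors = FALSE)
  } else {
    ase_counts <- data.frame(variant_id = character(), patient = character(),
                             ref_n = integer(), alt_n = integer(),
                             gq = integer(), dp = integer())
  }
  snv2gene <- unique(data.frame(
    variant_id = sprintf("ase:%s:%d", ase_gene_ids[grid$g], grid$s),
    gene_id = ase_gene_ids[grid$g], stringsAsFactors = FALSE))

  ## ---- expression & TF map (seed + 6) -------------------------------------
  set.seed(cfg$seed + 6L)
  ex <- cfg$expression
  cts <- sprintf("CT%d", seq_len(ex$n_cell_types))
  if (cfg$burden$target_cell_type > ex$n_cell_types)
    stop("burden target_cell_type index exceeds n_cell_types")
  target_ct <- cts[cfg$burden$target_cell_type]
  tf_case <- sprintf("TFcase%03d", seq_len(sum(kinds == "GoI")))
  tf_ctrl <- sprintf("TFctrl%03d", seq_len(sum(kinds == "LoI")))
  tf_disc <- sprintf("TFdisc%03d", seq_len(sum(kinds == "discordant")))
  all_rows <- c(gene_ids, tf_case, tf_ctrl, tf_disc)
  mean_expr <- matrix(ex$baseline, length(all_rows), length(cts),
                      dimnames = list(all_rows, cts))
  if (ex$expressed_fraction < 1) {
    mask <- matrix(stats::runif(length(mean_expr)) < ex$expressed_fraction,
                   nrow(mean_expr), ncol(mean_expr))
    mean_expr <- mean_expr * mask
  }
  # planted burden: TFs of case-specific concordant events are expressed
  # only in the target cell type
  if (isTRUE(cfg$burden$enabled)) {
    mean_expr[tf_case, ] <- 0
    mean_expr[tf_case, target_ct] <- ex$baseline
  }
  tf_of <- character(n_planted)
  tf_of[kinds == "GoI"] <- tf_case
  tf_of[kinds == "LoI"] <- tf_ctrl
  tf_of[kinds == "discordant"] <- tf_disc
  full_truth <- do.call(rbind, truth_rows)
  tf_map <- data.frame(variant_id = full_truth$variant_id, tf = tf_of,
                       stringsAsFactors = FALSE)
  tf_map <- tf_map[tf_map$variant_id %in% variants$variant_id, , drop = FALSE]
  expression <- list(mean = mean_expr, cell_types = cts)
  de_truth <- NULL
  if (ex$cells_per_type > 0) {
    n_cells <- ex$cells_per_type * length(cts)
    labels <- rep(cts, each = ex$cells_per_type)
    de_genes <- gene_ids[seq_len(min(ex$n_de_genes, cfg$n_genes))]
    de_ct <- stats::setNames(sample(cts, length(de_genes), replace = TRUE), de_genes)
    cells <- matrix(0, length(gene_ids), n_cells,
                    dimnames = list(gene_ids, NULL))
    for (g in gene_ids) {
      mu <- rep(log(ex$baseline), n_cells)
      if (g %in% de_genes) mu[labels == de_ct[g]] <- mu[labels == de_ct[g]] +
          log(ex$de_effect_size)
      cells[g, ] <- stats::rlnorm(n_cells, mu, 0.4)
    }
    expression$cells <- cells
    expression$cell_type_of_cell <- labels
    de_truth <- de_ct
  }

  out <- structure(list(
    cohort = co, variants = variants, interactions = interactions,
    regions = regions, genes = genes, ase_counts = ase_counts,
    snv2gene = snv2gene, expression = expression, tf_map = tf_map,
    truth = list(events = truth_events,
                 ase = data.frame(gene_id = ase_gene_ids, imbalanced = imb,
                                  stringsAsFactors = FALSE),
                 burden_cell_type = target_ct, de = de_truth),
    config = cfg), class = "rk_sim")
  if (!is.null(dir)) write_sim_bundle(out, dir)
  out
}

write_vcf <- function(variants, cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", cohort$patients), collapse = "\t")), con)
  gt <- dosage_matrix(variants)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  lines <- apply(cbind(variants$chrom, variants$pos + 1L, ".", variants$ref,
                       variants$alt, ".", "PASS",
                       sprintf("MAF=%.8g", variants$maf), "GT", gt_str),
                 1, paste, collapse = "\t")
  writeLines(lines, con)
  invisible(path)
}

write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_vcf(sim$variants, sim$cohort, fp("variants.vcf"))
  write_variants(sim$variants, fp("variants.tsv"))
  write_interactions(sim$interactions, fp("interactions.tsv"))
  write_regions(sim$regions, fp("regions.bed"))
  write_gene_table(sim$genes, fp("genes.tsv"))
  write_allelic_counts(sim$ase_counts, fp("ase_counts.tsv"))
  utils::write.table(sim$snv2gene, fp("snv2gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  em <- data.frame(gene_id = rownames(sim$expression$mean),
                   sim$expression$mean, check.names = FALSE)
  utils::write.table(em, fp("expression_mean.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, fp("truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$ase, fp("truth_ase.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Evaluate pipeline recovery against planted truth
#'
#' @param sim an `rk_sim` bundle.
#' @param events output of [enumerate_events()] on the bundle.
#' @param gene_imbalance optional output of [gene_level_imbalance()].
#' @param enrichment optional output of [enrichment_test1()].
#' @return List with `event_sensitivity` (planted concordant events
#'   recovered with the planted direction and concordance),
#'   `event_specificity` (recovered events outside the planted concordant
#'   set that are labelled discordant), `confusion` (planted x recovered
#'   label table), `ase_auc` (probability that a planted imbalanced gene
#'   ranks above a null gene by q), and `burden_top` (whether the planted
#'   burden cell type attains the minimum q).
#' @export
evaluate_recovery <- function(sim, events, gene_imbalance = NULL,
                              enrichment = NULL) {
  tr <- sim$truth$events
  ekey <- paste(events$variant_id, events$key, events$component)
  tkey <- paste(tr$variant_id, tr$key, tr$component)
  m <- match(tkey, ekey)
  if (anyNA(m)) stop("planted event absent from recovered events")
  rec <- events[m, , drop = FALSE]
  conc <- tr$concordance == "concordant"
  sens <- mean(rec$direction[conc] == tr$direction[conc] &
                 rec$concordance[conc] == tr$concordance[conc])
  planted_conc_keys <- tkey[conc]
  other <- events[!(ekey %in% planted_conc_keys), , drop = FALSE]
  spec <- if (nrow(other)) mean(other$concordance == "discordant") else 1
  out <- list(event_sensitivity = sens, event_specificity = spec,
              confusion = table(planted = paste(tr$direction, tr$concordance),
                                recovered = paste(rec$direction, rec$concordance)))
  if (!is.null(gene_imbalance)) {
    merged <- merge(gene_imbalance, sim$truth$ase, by = "gene_id")
    qs_p <- merged$q[merged$imbalanced]
    qs_n <- merged$q[!merged$imbalanced]
    cmp <- outer(qs_p, qs_n, FUN = function(x, y) (x < y) + 0.5 * (x == y))
    out$ase_auc <- mean(cmp)
  }
  if (!is.null(enrichment)) {
    best <- enrichment$cell_type[which.min(enrichment$q)]
    out$burden_top <- identical(best, sim$truth$burden_cell_type)
  }
  out
}
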