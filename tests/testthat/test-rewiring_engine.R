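# independent re-statement of the classifier predicate, used as the oracle
oracle_classify <- function(carriers, presence, all_pats) {
  if (length(carriers) == 0 || setequal(carriers, all_pats)) return(NULL)
  non <- setdiff(all_pats, carriers)
  if (length(setdiff(presence, carriers)) == 0) return(c("GoI", "concordant"))
  if (length(setdiff(presence, non)) == 0) return(c("LoI", "concordant"))
  rc <- length(intersect(presence, carriers)) / length(carriers)
  rn <- length(intersect(presence, non)) / length(non)
  c(if (rc >= rn) "GoI" else "LoI", "discordant")
}

test_that("classifier matches its definition on the worked examples", {
  pts <- paste0("P", 1:16)
  expect_equal(classify_event("P1", "P1", pts),
               list(direction = "GoI", concordance = "concordant"))
  expect_equal(classify_event("P1", setdiff(pts, "P1"), pts),
               list(direction = "LoI", concordance = "concordant"))
  expect_equal(classify_event(c("P1", "P2"), c("P1", "P3"), pts)$concordance,
               "discordant")
  # presence a strict subset of carriers is still concordant GoI
  expect_equal(classify_event(c("P1", "P2"), "P1", pts),
               list(direction = "GoI", concordance = "concordant"))
  # uninformative carrier sets: no event
  expect_null(classify_event(character(), "P1", pts))
  expect_null(classify_event(pts, "P1", pts))
})

test_that("classifier agrees with exhaustive enumeration over all set pairs for 4 patients", {
  pts <- paste0("P", 1:4)
  subsets <- unlist(lapply(1:4, function(k)
    combn(pts, k, simplify = FALSE)), recursive = FALSE)
  n_checked <- 0L
  for (carriers in subsets) {
    for (presence in subsets) {
      want <- oracle_classify(carriers, presence, pts)
      got <- classify_event(carriers, presence, pts)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(c(got$direction, got$concordance), want)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 15L * 15L)
})

test_that("equality semantics demand exact carrier/complement match", {
  pts <- paste0("P", 1:6)
  expect_equal(classify_event(c("P1", "P2"), c("P1", "P2"), pts,
                              semantics = "equality")$concordance, "concordant")
  expect_equal(classify_event(c("P1", "P2"), "P1", pts,
                              semantics = "equality")$concordance, "discordant")
})

test_that("cohort specificity follows carrier group membership", {
  co <- cohort(paste0("case", 1:8), paste0("ctrl", 1:8))
  expect_equal(assign_cohort_specificity(c("case1", "case3"), co), "case_specific")
  expect_equal(assign_cohort_specificity("ctrl2", co), "control_specific")
  expect_equal(assign_cohort_specificity(c("case1", "ctrl1"), co), "shared")
  expect_error(assign_cohort_specificity(character(), co), "non-empty")
})

test_that("fisher OR is the cross-product ratio, exactly, with degenerate handling", {
  set.seed(7)
  for (i in 1:20) {
    tb <- sample(0:50, 4, replace = TRUE) + c(1, 1, 1, 1)
    ft <- fisher_two_tailed(tb[1], tb[2], tb[3], tb[4])
    expect_identical(ft$odds_ratio, (tb[1] * tb[4]) / (tb[2] * tb[3]))
    expect_equal(ft$p, fisher.test(matrix(tb, 2, byrow = TRUE))$p.value)
  }
  sym <- fisher_two_tailed(1, 1, 1, 1)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  expect_identical(fisher_two_tailed(5, 0, 3, 4)$odds_ratio, Inf)
  expect_true(is.nan(fisher_two_tailed(0, 0, 0, 4)$odds_ratio))
  expect_error(fisher_two_tailed(-1, 1, 1, 1), "non-negative")
})

test_that("event enumeration recovers composition of overlap, presence and classification", {
  co <- tiny_cohort()
  regions <- structure(data.frame(
    region_id = c("prom1", "enh1"), chrom = "chr1", start = c(0, 5000),
    end = c(1000, 5800), strand = "+", role = c("promoter", "enhancer"),
    gene_ids = c("gA,gB", "."), stringsAsFactors = FALSE),
    class = c("rk_regions", "data.frame"))
  inter <- mk_interactions(start1 = 0, end1 = 1000, start2 = 5000, end2 = 5800,
                           patient = "P1")
  vdf <- data.frame(variant_id = "chr1:5100:A:G", chrom = "chr1", pos = 5100L,
                    end = 5101L, ref = "A", alt = "G", maf = 0.01, kind = "snv",
                    P1 = 1L, P2 = 0L, P3 = 0L, P4 = 0L)
  variants <- structure(vdf, class = c("rk_variants", "data.frame"),
                        patients = co$patients)
  ev <- enumerate_events(variants, inter, regions, co)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$component, "enhancer")
  expect_equal(ev$direction, "GoI")
  expect_equal(ev$concordance, "concordant")
  expect_equal(ev$cohort, "case_specific")
  expect_equal(ev$genes, "gA,gB")

  # variant overlapping no anchor: no events
  variants$pos <- 3000L; variants$end <- 3001L
  variants$variant_id <- "chr1:3000:A:G"
  expect_equal(nrow(enumerate_events(variants, inter, regions, co)), 0L)
})

test_that("renaming patients consistently leaves event counts invariant", {
  sim <- small_sim()
  kept <- filter_interactions(sim$interactions)$kept
  ev <- enumerate_events(sim$variants, kept, sim$regions, sim$cohort)

  # bijective rename: reverse each group internally
  co <- sim$cohort
  perm <- stats::setNames(c(rev(cohort_group(co, "case")),
                            rev(cohort_group(co, "control"))),
                          c(cohort_group(co, "case"), cohort_group(co, "control")))
  co2 <- co
  kept2 <- kept
  kept2$patient <- unname(perm[kept2$patient])
  v2 <- sim$variants
  pat_cols <- match(co$patients, names(v2))
  names(v2)[pat_cols] <- unname(perm[names(v2)[pat_cols]])
  attr(v2, "patients") <- co$patients
  ev2 <- enumerate_events(v2, kept2, sim$regions, co2)
  tab <- function(e) table(e$cohort, e$component, e$concordance, e$direction)
  expect_equal(tab(ev2), tab(ev))
})

test_that("swapping case and control labels swaps the specificity counts exactly", {
  sim <- small_sim()
  kept <- filter_interactions(sim$interactions)$kept
  ev <- enumerate_events(sim$variants, kept, sim$regions, sim$cohort)
  co_sw <- cohort(cohort_group(sim$cohort, "control"), cohort_group(sim$cohort, "case"))
  ev_sw <- enumerate_events(sim$variants, kept, sim$regions, co_sw)
  expect_equal(sum(ev_sw$cohort == "case_specific"),
               sum(ev$cohort == "control_specific"))
  expect_equal(sum(ev_sw$cohort == "control_specific"),
               sum(ev$cohort == "case_specific"))
  expect_equal(sum(ev_sw$cohort == "shared"), sum(ev$cohort == "shared"))
})

mk_events <- function(n, cohort, component, concordance, direction, genes = "g") {
  if (n == 0) return(NULL)
  data.frame(variant_id = paste0("v", seq_len(n)), key = "k",
             component = component, direction = direction,
             concordance = concordance, cohort = cohort, maf = 0.01,
             genes = genes, carriers = "P1", presence = "P1",
             stringsAsFactors = FALSE)
}

test_that("summary computes direction shares and tier enrichment from events", {
  ev <- rbind(mk_events(3, "case_specific", "promoter", "concordant", "LoI"),
              mk_events(97, "case_specific", "promoter", "concordant", "GoI"),
              mk_events(1, "control_specific", "enhancer", "concordant", "LoI"),
              mk_events(49, "control_specific", "enhancer", "concordant", "GoI"),
              mk_events(10, "case_specific", "promoter", "discordant", "GoI"))
  s <- table1_summary(ev)
  expect_equal(s$direction$case_loi, 3L)
  expect_equal(s$direction$case_loi_pct, 3.00)
  expect_equal(s$direction$control_loi_pct, 2.00)
  expect_equal(s$direction$goi_pct, 100 * 146 / 150)
  expect_equal(unname(s$counts["case_specific", "promoter", "discordant"]), 10L)

  # zero LoI events: share 0.00
  ev0 <- mk_events(5, "case_specific", "promoter", "concordant", "GoI")
  expect_equal(table1_summary(ev0)$direction$case_loi_pct, 0)

  genes <- structure(data.frame(
    gene_id = c("t1", "hk1"), tier = c("tier1", "none"),
    housekeeping = c(FALSE, TRUE), endothelial_specific = FALSE,
    stringsAsFactors = FALSE), class = c("rk_genes", "data.frame"))
  ev_t <- rbind(mk_events(8, "case_specific", "promoter", "concordant", "GoI", genes = "t1"),
                mk_events(16, "case_specific", "promoter", "concordant", "GoI", genes = "hk1"),
                mk_events(2, "control_specific", "promoter", "concordant", "GoI", genes = "t1"),
                mk_events(8, "control_specific", "promoter", "concordant", "GoI", genes = "hk1"))
  te <- table1_summary(ev_t, genes)$tier_enrichment$concordant
  expect_equal(te$case_tier, 8L)
  expect_equal(te$odds_ratio, (8 * 8) / (16 * 2))
  expect_equal(te$rate_ratio, (8 / 16) / (2 / 8))
})
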