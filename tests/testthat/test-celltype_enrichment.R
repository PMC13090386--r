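mk_ev <- function(n, cohort = "case_specific", component = "promoter",
                  concordance = "concordant", genes = "g1", maf = 0.01,
                  ids = NULL) {
  data.frame(variant_id = if (is.null(ids)) paste0("v", seq_len(n)) else ids,
             key = "k", component = component, direction = "GoI",
             concordance = concordance, cohort = cohort, maf = maf,
             genes = genes, carriers = "x", presence = "x",
             stringsAsFactors = FALSE)
}

test_that("MAF strata use left-closed binning and reject out-of-range values", {
  ev <- mk_ev(4, maf = c(0.01, 0.02, 0.07, 0.039))
  s <- stratify_by_maf(ev)
  expect_equal(s$stratum, c("MAFa", "MAFb", "MAFc", "MAFb"))
  expect_error(stratify_by_maf(mk_ev(1, maf = 0.10)), "range")
  expect_error(stratify_by_maf(mk_ev(1, maf = -0.01)), "range")
  # strata partition: every event in exactly one stratum
  set.seed(2)
  evr <- mk_ev(500, maf = runif(500, 0, 0.0999))
  sr <- stratify_by_maf(evr)
  expect_false(anyNA(sr$stratum))
  expect_equal(nrow(sr), 500L)
})

test_that("DE flags mark extreme separation, skip identical distributions, and recover 2-fold effects", {
  set.seed(8)
  cells <- 100
  labels <- rep(c("CT1", "CT2", "CT3", "CT4"), each = cells)
  # gene expressed only in CT2; gene identically distributed; constant gene
  g_only <- ifelse(labels == "CT2", rlnorm(4 * cells, 2, 0.3), 0)
  g_null <- rlnorm(4 * cells, 1, 0.3)
  g_const <- rep(1, 4 * cells)
  expr <- rbind(only = g_only, null = g_null, const = g_const)
  fl <- flag_de_genes(expr, labels)
  expect_true(fl["only", "CT2"])
  expect_false(any(fl["only", c("CT1", "CT3", "CT4")]))
  expect_false(any(fl["null", ]))
  expect_false(any(fl["const", ]))

  # planted 2-fold DE genes recovered with sensitivity >= 0.9 at 100 cells/type
  sim <- simulate_cohort(sim_config(
    n_genes = 60L, n_promoters = 60L, n_enhancers = 120L, n_variants = 30L,
    n_planted_goi = 5L, n_planted_loi = 5L, n_planted_discordant = 0L,
    n_background_interactions = 20L,
    ase = list(n_imbalanced_genes = 0L, n_null_genes = 2L, snvs_per_gene = 1L,
               patients_per_gene = 2L),
    expression = list(cells_per_type = 100L, n_de_genes = 20L,
                      de_effect_size = 2), seed = 77))
  fl2 <- flag_de_genes(sim$expression$cells, sim$expression$cell_type_of_cell)
  de <- sim$truth$de
  hit <- vapply(names(de), function(g) fl2[g, de[g]], logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("altered transcripts require gene and TF expression in the cell type", {
  expr <- matrix(c(5, 0, 5, 0, 5, 5, 0, 0), 4, 2,
                 dimnames = list(c("g1", "g2", "TF1", "TF2"), c("CT1", "CT2")))
  tfm <- data.frame(variant_id = c("v1", "v2"), tf = c("TF1", "TF2"))
  ev <- mk_ev(2, genes = c("g1", "g2"), ids = c("v1", "v2"))
  # CT1: g1 expressed + TF1 expressed -> altered; g2 unexpressed -> excluded
  expect_equal(as.character(altered_transcripts(ev, expr, tfm, "CT1")), "g1")
  # CT2: TF1 unexpressed -> g1 excluded even though g1 itself is expressed
  expect_equal(length(altered_transcripts(ev, expr, tfm, "CT2")), 0L)
  # event without motif annotation is excluded and counted
  ev3 <- mk_ev(1, genes = "g1", ids = "v_unannotated")
  out <- altered_transcripts(ev3, expr, tfm, "CT1")
  expect_equal(length(out), 0L)
  expect_equal(attr(out, "n_unannotated"), 1L)
})

test_that("identical case/control altered sets give OR = 1 and p = 1", {
  genes <- paste0("g", 1:20)
  expr <- matrix(5, 21, 2, dimnames = list(c(genes, "TF1"), c("CT1", "CT2")))
  ev <- rbind(mk_ev(10, "case_specific", genes = genes[1:10],
                    ids = paste0("vc", 1:10)),
              mk_ev(10, "control_specific", genes = genes[1:10],
                    ids = paste0("vt", 1:10)))
  tfm <- data.frame(variant_id = ev$variant_id, tf = "TF1")
  e1 <- enrichment_test1(ev, expr, tfm, strata = NULL)
  expect_true(all(e1$odds_ratio == 1))
  expect_equal(e1$p, rep(1, nrow(e1)), tolerance = 1e-9)
})

test_that("swapping cohorts inverts every odds ratio; enhancer classes stay disjoint", {
  set.seed(14)
  genes <- paste0("g", 1:40)
  tfs <- paste0("TF", 1:40)
  expr <- rbind(matrix(5, 40, 2, dimnames = list(genes, c("CT1", "CT2"))),
                matrix(rbinom(80, 1, 0.5) * 5, 40, 2,
                       dimnames = list(tfs, c("CT1", "CT2"))))
  ev <- rbind(mk_ev(25, "case_specific", "enhancer", genes = genes[1:25],
                    ids = paste0("vc", 1:25)),
              mk_ev(15, "control_specific", "enhancer", genes = genes[26:40],
                    ids = paste0("vt", 1:15)),
              mk_ev(10, "case_specific", "enhancer", "discordant",
                    genes = genes[1:10], ids = paste0("vd", 1:10)))
  tfm <- data.frame(variant_id = ev$variant_id,
                    tf = tfs[c(1:25, 26:40, 1:10)])
  e2 <- enrichment_test2(ev, expr, tfm, strata = NULL)
  expect_setequal(unique(e2$class), c("concordant", "discordant"))
  # swap cohort labels
  ev_sw <- ev
  ev_sw$cohort <- c(case_specific = "control_specific",
                    control_specific = "case_specific")[ev$cohort]
  e2_sw <- enrichment_test2(ev_sw, expr, tfm, strata = NULL)
  key <- paste(e2$cell_type, e2$stratum, e2$class)
  key_sw <- paste(e2_sw$cell_type, e2_sw$stratum, e2_sw$class)
  m <- match(key, key_sw)
  expect_equal(e2_sw$odds_ratio[m], 1 / e2$odds_ratio, tolerance = 1e-12)
  expect_equal(e2_sw$p[m], e2$p, tolerance = 1e-12)
})

test_that("empirical type-I error of the enrichment test is near nominal under a calibrated null", {
  set.seed(50)
  ng <- 200
  genes <- paste0("g", 1:ng)
  tfs <- paste0("TF", 1:(2 * ng))
  ev <- rbind(mk_ev(ng, "case_specific", genes = genes, ids = paste0("vc", 1:ng)),
              mk_ev(ng, "control_specific", genes = genes, ids = paste0("vt", 1:ng)))
  tfm <- data.frame(variant_id = ev$variant_id, tf = tfs)
  de <- rbind(matrix(TRUE, ng, 2), matrix(FALSE, 2 * ng, 2))
  dimnames(de) <- list(c(genes, tfs), c("CT1", "CT2"))
  ps <- numeric()
  for (r in 1:400) {
    expr <- rbind(matrix(5, ng, 2, dimnames = list(genes, c("CT1", "CT2"))),
                  matrix(rbinom(2 * ng * 2, 1, 0.3) * 5, 2 * ng, 2,
                         dimnames = list(tfs, c("CT1", "CT2"))))
    ps <- c(ps, enrichment_test1(ev, expr, tfm, strata = NULL, de_flags = de)$p)
  }
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("burden confined to one stratum stays confined in the results", {
  genes <- paste0("g", 1:30)
  expr <- rbind(matrix(5, 30, 2, dimnames = list(genes, c("CT1", "CT2"))),
                TFb = c(5, 0))
  # case enhancer burden planted in MAFb only
  ev <- rbind(mk_ev(20, "case_specific", "enhancer", genes = genes[1:20],
                    maf = 0.03, ids = paste0("vb", 1:20)),
              mk_ev(3, "control_specific", "enhancer", genes = genes[21:23],
                    maf = 0.03, ids = paste0("vtb", 1:3)),
              mk_ev(3, "case_specific", "enhancer", genes = genes[24:26],
                    maf = 0.01, ids = paste0("va", 1:3)),
              mk_ev(3, "control_specific", "enhancer", genes = genes[27:29],
                    maf = 0.01, ids = paste0("vta", 1:3)))
  tfm <- data.frame(variant_id = ev$variant_id, tf = "TFb")
  e2 <- enrichment_test2(ev, expr, tfm)
  sig <- e2[e2$q < 0.05, ]
  expect_true(all(sig$stratum == "MAFb"))
  expect_true(all(sig$cell_type == "CT1"))
})

test_that("network degree stats obey the handshake identity and reject bad input", {
  expect_equal(network_degree_stats("n1", matrix(character(), 0, 2)),
               list(n_nodes = 1L, n_edges = 0L, average_degree = 0))
  set.seed(19)
  for (r in 1:10) {
    nv <- sample(5:40, 1)
    nodes <- paste0("n", 1:nv)
    ne <- sample(1:60, 1)
    edges <- cbind(sample(nodes, ne, TRUE), sample(nodes, ne, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) == 0) next
    s <- network_degree_stats(nodes, edges)
    # handshake identity on the deduplicated graph
    key <- unique(ifelse(edges[, 1] < edges[, 2],
                         paste(edges[, 1], edges[, 2]),
                         paste(edges[, 2], edges[, 1])))
    deg <- table(factor(unlist(strsplit(key, " ")), levels = nodes))
    expect_equal(s$average_degree, round(mean(deg), 2))
    expect_equal(s$n_edges, length(key))
  }
  expect_error(network_degree_stats(character(), NULL), "empty")
  expect_error(network_degree_stats(c("a", "b"), rbind(c("a", "a"))), "loops")
  expect_error(network_degree_stats(c("a", "b"), rbind(c("a", "z"))), "node list")
})
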