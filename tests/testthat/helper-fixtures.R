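# Shared fixtures and independent oracles used across test files.

# plain data.frame with all extra attributes/classes dropped
strip_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names")]
  class(x) <- "data.frame"
  x
}

tiny_cohort <- function(n_case = 2, n_control = 2) {
  cohort(paste0("P", seq_len(n_case)),
         paste0("P", n_case + seq_len(n_control)))
}

# build an rk_interactions table from anchor coordinates
mk_interactions <- function(start1, end1, start2, end2, patient,
                            support_pairs = 10L, adj_p = 1e-4,
                            chrom1 = "chr1", chrom2 = "chr1") {
  rewirekit:::as_interactions(data.frame(
    chrom1 = chrom1, start1 = start1, end1 = end1,
    chrom2 = chrom2, start2 = start2, end2 = end2,
    patient = patient, support_pairs = support_pairs, adj_p = adj_p,
    stringsAsFactors = FALSE))
}

random_pwm <- function(L, name = "m", sd = 2, uniform_bg = FALSE) {
  bg <- if (uniform_bg) rep(0.25, 4) else { b <- rgamma(4, 5); b / sum(b) }
  pwm(name, matrix(rnorm(L * 4, 0, sd), L, 4), background = bg)
}

# exhaustive 4^L enumeration: tail probability of the background score
# distribution, using the PWM's snapped weight matrix
enum_pwm_tail <- function(pw) {
  scores <- 0
  probs <- 1
  for (i in seq_len(pw$L)) {
    scores <- as.vector(outer(pw$mat[i, ], scores, "+"))
    probs <- as.vector(outer(pw$background, probs, "*"))
  }
  function(q) sum(probs[scores >= q - 1e-12])
}

# brute-force min-p over all placements and both strands
brute_best_hit <- function(pw, sequence) {
  n <- nchar(sequence)
  center <- ceiling(n / 2)
  best <- -Inf
  for (s in c(sequence, rewirekit:::rev_comp(sequence))) {
    for (st in seq_len(n - pw$L + 1L)) {
      if (st > center || st + pw$L - 1L < center) next
      sc <- pwm_score(pw, substr(s, st, st + pw$L - 1L))
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  if (!is.finite(best)) return(1)
  pwm_pvalue(pw, best)
}

# quadratic brute-force half-open interval overlap
brute_overlap <- function(variants, regions) {
  hits <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(regions))) {
      if (variants$chrom[i] == regions$chrom[j] &&
          variants$pos[i] < regions$end[j] &&
          regions$start[j] < variants$end[i]) {
        hits[[length(hits) + 1L]] <- data.frame(
          variant_id = variants$variant_id[i],
          region_id = regions$region_id[j],
          role = regions$role[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(variant_id = character(), region_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# quadratic reference BH step-up
brute_bh <- function(ps) {
  m <- length(ps)
  qs <- numeric(m)
  for (i in seq_len(m)) {
    r <- sum(ps <= ps[i])  # max rank of this value
    qs[i] <- min(1, min(vapply(seq_len(m), function(j) {
      rj <- sum(ps <= ps[j])
      if (ps[j] >= ps[i]) m * ps[j] / rj else Inf
    }, numeric(1))))
  }
  qs
}

# independent evaluation of the logit combination reference formula
mg_logit_oracle <- function(ps) {
  k <- length(ps)
  tt <- -sum(log(ps) - log1p(-ps))
  nu <- 5 * k + 4
  cc <- sqrt((3 * nu) / (k * pi^2 * (nu - 2)))
  stats::pt(tt * cc, df = nu, lower.tail = FALSE)
}

# small deterministic simulated bundle shared by several test files
small_sim <- function(seed = 11, ...) {
  simulate_cohort(sim_config(
    n_promoters = 80L, n_enhancers = 160L, n_genes = 80L, n_variants = 120L,
    n_planted_goi = 8L, n_planted_loi = 6L, n_planted_discordant = 4L,
    n_background_interactions = 60L,
    ase = list(n_imbalanced_genes = 3L, n_null_genes = 20L,
               snvs_per_gene = 3L, patients_per_gene = 3L),
    seed = seed, ...))
}
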