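# Allele-specific interaction imbalance: per-SNV beta-binomial test on
# interaction-read allelic counts, two-stage logit p-value combination to
# gene level, and BH FDR control.

#' QC-filter allelic count records
#'
#' Keeps heterozygous sites with genotype quality >= `min_gq`, depth >=
#' `min_dp` and at least `min_allele` reads supporting each allele (all
#' boundaries inclusive).
#'
#' @param counts data frame with columns `ref_n, alt_n, gq, dp` (plus any
#'   identifier columns).
#' @param min_gq,min_dp,min_allele inclusive thresholds (defaults 50, 10, 5).
#' @return The kept rows.
#' @export
qc_counts <- function(counts, min_gq = 50, min_dp = 10, min_allele = 5) {
  keep <- counts$gq >= min_gq & counts$dp >= min_dp &
    counts$ref_n >= min_allele & counts$alt_n >= min_allele
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# beta-binomial pmf with mean 1/2 and intra-class correlation rho;
# no d*() for this law ships with the installed stack, so it is written
# from lchoose/lbeta. rho = 0 falls back to the exact binomial.
dbetabinom_half <- function(k, n, rho) {
  if (rho == 0) return(stats::dbinom(k, n, 0.5))
  a <- (1 - rho) / (2 * rho)
  exp(lchoose(n, k) + lbeta(k + a, n - k + a) - lbeta(a, a))
}

#' Per-SNV allelic imbalance test
#'
#' Conditional on the total read count `n = ref_n + alt_n`, the alternative
#' count under the balanced null follows a beta-binomial with mean 1/2 and
#' intra-class correlation `rho` (binomial at `rho = 0`). One-tailed
#' p-values include the observed point mass; the two-tailed p doubles the
#' smaller tail, capped at 1.
#'
#' @param ref_n,alt_n non-negative read counts (vectorized).
#' @param rho overdispersion in `[0, 1)`.
#' @return Data frame `p_toward_ref, p_toward_alt, p_two, effect` where
#'   `effect = alt_n / (ref_n + alt_n)`; `p_toward_alt` is the upper tail
#'   (excess alternative allele), `p_toward_ref` the lower.
#' @examples
#' imbalance_test(0, 20)$p_toward_alt  # 2^-20
#' @export
imbalance_test <- function(ref_n, alt_n, rho = 0) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (any(ref_n < 0) || any(alt_n < 0)) stop("counts must be non-negative")
  n <- ref_n + alt_n
  res <- mapply(function(a, nn) {
    pmf <- dbetabinom_half(0:nn, nn, rho)
    c(lower = sum(pmf[seq_len(a + 1L)]), upper = sum(pmf[(a + 1L):(nn + 1L)]))
  }, alt_n, n)
  p_ref <- pmin(1, res["lower", ])
  p_alt <- pmin(1, res["upper", ])
  data.frame(p_toward_ref = p_ref, p_toward_alt = p_alt,
             p_two = pmin(1, 2 * pmin(p_ref, p_alt)),
             effect = alt_n / n)
}

#' Method-of-moments overdispersion estimate
#'
#' Estimates the global intra-class correlation `rho` from the excess
#' variance of the alternative-allele fractions across QC-passing
#' heterozygous sites relative to the binomial expectation:
#' `E[(f - 1/2)^2] = (1 + (n - 1) rho) / (4 n)` site-wise, solved for `rho`
#' by pooling over sites. Clipped to `[0, 0.5]`; with fewer than
#' `min_sites` sites returns 0 with a warning.
#'
#' @param counts data frame with columns `ref_n, alt_n` (post-QC).
#' @param min_sites minimum number of sites (default 20).
#' @return Estimated `rho`.
#' @export
estimate_overdispersion <- function(counts, min_sites = 20L) {
  n <- counts$ref_n + counts$alt_n
  if (length(n) < min_sites) {
    warning("fewer than ", min_sites, " sites; returning rho = 0")
    return(0)
  }
  f <- counts$alt_n / n
  num <- sum((f - 0.5)^2 - 1 / (4 * n))
  den <- sum((n - 1) / (4 * n))
  min(0.5, max(0, num / den))
}

#' Combine p-values with the logit method
#'
#' Mudholkar-George combination: `T = -sum(log(p/(1-p)))` referred to a
#' scaled t distribution with `5k + 4` degrees of freedom
#' (`T / C ~ t_{5k+4}` with `C = sqrt(k pi^2 (5k+2) / (3 (5k+4)))`).
#' A single p-value is returned unchanged. Values of exactly 0 or 1 are
#' clamped into the open unit interval with a warning.
#'
#' @param ps numeric vector of p-values in (0, 1).
#' @return Combined p-value.
#' @export
combine_pvalues_logit <- function(ps) {
  if (length(ps) == 0L) stop("no p-values to combine")
  eps <- .Machine$double.xmin
  if (any(ps <= 0 | ps >= 1)) {
    warning("p-values clamped into the open unit interval")
    ps <- pmin(1 - .Machine$double.eps, pmax(eps, ps))
  }
  if (length(ps) == 1L) return(ps)
  k <- length(ps)
  tstat <- -sum(log(ps / (1 - ps)))
  scale <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
  stats::pt(tstat / scale, df = 5 * k + 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment (wraps `stats::p.adjust`).
#'
#' @param ps numeric vector of p-values.
#' @return q-values in input order.
#' @export
bh_fdr <- function(ps) stats::p.adjust(ps, method = "BH")

#' Gene-level allelic imbalance
#'
#' Two-stage aggregation of per-SNV two-tailed imbalance p-values: within
#' each gene they are combined per individual with the logit method, the
#' per-individual gene-level p-values are re-combined across individuals
#' with the same method, and the cross-individual p-values are BH-adjusted
#' over the gene list. Output order is by gene ID, so results are
#' deterministic regardless of input order.
#'
#' @param results data frame with columns `variant_id, patient, p_two`
#'   (e.g. QC-passing counts augmented with [imbalance_test()] p-values).
#' @param snv2gene data frame with columns `variant_id, gene_id` (a variant
#'   may map to several genes via its interacting regions).
#' @return Data frame `gene_id, n_snvs, n_patients, p, q` sorted by
#'   `gene_id`; genes with zero tested SNVs are absent.
#' @export
gene_level_imbalance <- function(results, snv2gene) {
  m <- merge(results[, c("variant_id", "patient", "p_two")], snv2gene,
             by = "variant_id")
  if (nrow(m) == 0L)
    return(data.frame(gene_id = character(), n_snvs = integer(),
                      n_patients = integer(), p = numeric(), q = numeric()))
  genes <- sort(unique(m$gene_id))
  rows <- lapply(genes, function(g) {
    mg <- m[m$gene_id == g, , drop = FALSE]
    per_pat <- vapply(split(mg$p_two, mg$patient), combine_pvalues_logit,
                      numeric(1))
    data.frame(gene_id = g, n_snvs = length(unique(mg$variant_id)),
               n_patients = length(per_pat),
               p = combine_pvalues_logit(unname(per_pat)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Read an allelic count table
#'
#' Tab-separated with header columns
#' `variant_id, patient, ref_n, alt_n, gq, dp`.
#'
#' @param path path to the table.
#' @return Data frame with those columns.
#' @export
read_allelic_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "patient", "ref_n", "alt_n", "gq", "dp")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(df$dp < pmax(df$ref_n, df$alt_n)))
    stop("depth below the larger allele count")
  df[, need]
}

#' Write an allelic count table
#' @param counts data frame as in [read_allelic_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
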