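# PWM motif annotation of variants: exact best-hit motif p-values on the
# reference and alternative alleles, log2 p-value fold change, and
# gain-/loss-of-motif calls.

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Weights are additive log-odds scores. On construction they are snapped
#' to a fixed-point grid (`precision`, default 1e-4): both scoring and the
#' background score distribution then operate on the same discretized
#' matrix, so p-values are exact for the snapped weights and independent of
#' floating-point summation order.
#'
#' @param name motif name.
#' @param weights L x 4 numeric matrix, columns in A, C, G, T order.
#' @param background length-4 strictly positive probability vector
#'   (sums to 1).
#' @param quality optional quality grade (e.g. HOCOMOCO-style A/B/C).
#' @param precision score discretization step.
#' @return An object of class `rk_pwm`.
#' @export
pwm <- function(name, weights, background = rep(0.25, 4), quality = NA_character_,
                precision = 1e-4) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L || nrow(weights) < 1L)
    stop("weights must be an L x 4 matrix with L >= 1")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be a strictly positive probability vector of length 4")
  imat <- round(weights / precision)
  structure(list(name = name, L = nrow(weights),
                 mat = imat * precision, imat = imat,
                 background = background, quality = quality,
                 precision = precision, cache = new.env(parent = emptyenv())),
            class = "rk_pwm")
}

#' @export
print.rk_pwm <- function(x, ...) {
  cat("rk_pwm", x$name, "(L =", x$L, ")\n")
  invisible(x)
}

#' Read plain-text PWM/PCM motif files
#'
#' Parses the plain-text motif dialect: a `>` header with the motif name,
#' followed by one line per position with four whitespace-separated numbers
#' in A, C, G, T order. Several motifs per file and a mix of files /
#' directories are accepted. With `format = "pcm"` (or `"auto"` detecting
#' non-negative rows with near-constant sums > 1) counts are converted to
#' log2-odds with a background-proportional pseudocount:
#' `w = log2(((c + pseudocount * bg) / (N + pseudocount)) / bg)`.
#' A trailing dot-separated single-letter token of the name is taken as the
#' quality grade.
#'
#' @param paths files and/or directories to read.
#' @param format `"auto"`, `"pwm"` or `"pcm"`.
#' @param background,pseudocount,precision see [pwm()].
#' @return Named list of `rk_pwm` objects.
#' @export
read_pwms <- function(paths, format = c("auto", "pwm", "pcm"),
                      background = rep(0.25, 4), pseudocount = 1,
                      precision = 1e-4) {
  format <- match.arg(format)
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  }))
  out <- list()
  for (f in files) {
    lines <- trimws(readLines(f))
    lines <- lines[nzchar(lines)]
    starts <- grep("^>", lines)
    if (length(starts) == 0L) stop("no '>' motif header in ", f)
    ends <- c(starts[-1] - 1L, length(lines))
    for (k in seq_along(starts)) {
      name <- sub("^>\\s*", "", lines[starts[k]])
      name <- strsplit(name, "\\s+")[[1]][1]
      body <- lines[(starts[k] + 1L):ends[k]]
      m <- do.call(rbind, lapply(body, function(ln)
        as.numeric(strsplit(ln, "\\s+")[[1]])))
      if (ncol(m) != 4L || anyNA(m)) stop("malformed matrix for motif ", name)
      fmt <- format
      if (fmt == "auto") {
        sums <- rowSums(m)
        fmt <- if (all(m >= 0) && all(sums > 1) &&
                   max(sums) - min(sums) < 0.01 * max(sums)) "pcm" else "pwm"
      }
      if (fmt == "pcm") {
        n <- rowSums(m)
        freq <- sweep(m, 2, background * pseudocount, "+") / (n + pseudocount)
        m <- log2(sweep(freq, 2, background, "/"))
      }
      tok <- strsplit(name, ".", fixed = TRUE)[[1]]
      qual <- if (length(tok) > 1 && grepl("^[A-Z]$", tok[length(tok)]))
        tok[length(tok)] else NA_character_
      out[[name]] <- pwm(name, m, background = background, quality = qual,
                         precision = precision)
    }
  }
  out
}

#' Score a DNA word against a PWM
#'
#' Sum of per-position weights. Words containing ambiguity codes (N etc.)
#' score `NA` so that scanning callers can skip the placement.
#'
#' @param pwm an `rk_pwm`.
#' @param word DNA string of length exactly `L`.
#' @return Numeric score, or `NA` for non-ACGT content.
#' @export
pwm_score <- function(pwm, word) {
  chars <- strsplit(toupper(word), "", fixed = TRUE)[[1]]
  if (length(chars) != pwm$L) stop("word length must equal motif length ", pwm$L)
  idx <- match(chars, DNA)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$mat[cbind(seq_len(pwm$L), idx)])
}

# Exact distribution of the integer (grid-unit) score of a random background
# word: per-position convolution of the four-point weight distributions.
score_distribution <- function(pwm) {
  if (!is.null(pwm$cache$dist)) return(pwm$cache$dist)
  imat <- pwm$imat
  mins <- apply(imat, 1, min)
  off <- sweep(imat, 1, mins)  # non-negative integer offsets per position
  probs <- 1
  for (i in seq_len(pwm$L)) {
    span <- max(off[i, ])
    new <- numeric(length(probs) + span)
    for (j in 1:4) {
      o <- off[i, j]
      idx <- seq_along(probs) + o
      new[idx] <- new[idx] + probs * pwm$background[j]
    }
    probs <- new
  }
  # tail[k+1] = Pr(integer score >= base + k), k = 0..K
  tail <- rev(cumsum(rev(probs)))
  dist <- list(base = sum(mins), tail = tail, K = length(probs) - 1L)
  assign("dist", dist, envir = pwm$cache)
  dist
}

#' Exact motif p-value of a score
#'
#' `p = Pr(score of a random background word >= score)`, computed from the
#' exact discretized score distribution (dynamic programming over
#' per-position weight convolutions). `p` is in (0, 1], equals 1 at or
#' below the minimum achievable score, and is non-increasing in the score;
#' queries above the maximum achievable score clamp to the top-score
#' p-value.
#'
#' @param pwm an `rk_pwm`.
#' @param score numeric score(s) on the same scale as [pwm_score()].
#' @return Numeric p-value(s).
#' @export
pwm_pvalue <- function(pwm, score) {
  d <- score_distribution(pwm)
  # every achievable score is a grid multiple; off-grid queries take the
  # next grid point up (ceiling with a guard for float representation)
  k <- ceiling(score / pwm$precision - 1e-6) - d$base
  k <- pmax(0, pmin(d$K, k))
  unname(d$tail[k + 1L])
}

rev_comp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Best motif hit p-value in a variant-centred window
#'
#' Scans every motif placement overlapping the centre base of the window
#' (both strands by default; a window of length 2L-1 covers all L
#' placements) and returns the minimum motif p-value. Placements with
#' non-ACGT characters are skipped; if all are skipped the p-value is 1
#' with a warning.
#'
#' @param pwm an `rk_pwm`.
#' @param sequence DNA window centred on the variant base (odd length
#'   >= L recommended; centre is `ceiling(nchar/2)`).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return Best (minimum) hit p-value.
#' @export
best_hit_pvalue <- function(pwm, sequence, both_strands = TRUE) {
  n <- nchar(sequence)
  if (n < pwm$L) stop("window shorter than the motif")
  center <- ceiling(n / 2)
  seqs <- sequence
  if (both_strands) seqs <- c(seqs, rev_comp(sequence))
  best <- -Inf
  for (s in seqs) {
    for (st in max(1L, center - pwm$L + 1L):min(center, n - pwm$L + 1L)) {
      sc <- pwm_score(pwm, substr(s, st, st + pwm$L - 1L))
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  if (!is.finite(best)) {
    warning("no scannable placement (ambiguity codes); p = 1")
    return(1)
  }
  pwm_pvalue(pwm, best)
}

#' Motif impact of a variant for one PWM
#'
#' Compares the best-hit motif p-values of the reference and alternative
#' windows: `impact = log2(p_ref / p_alt)`. A gain-of-motif (GoM) is called
#' when the alternative allele is a valid hit (`p_alt <= hit_threshold`)
#' and the p-value improves at least `2^fc_min`-fold; loss-of-motif (LoM)
#' symmetrically on the reference allele. The windows must be identical
#' outside the variant footprint.
#'
#' @param pwm an `rk_pwm`.
#' @param ref_window,alt_window equal-length DNA windows centred on the
#'   variant, differing only at the variant base(s).
#' @param hit_threshold motif hit p-value threshold (default 0.0005).
#' @param fc_min minimum |log2 fold change| to call GoM/LoM (default 2).
#' @param both_strands scan both strands (default `TRUE`).
#' @return One-row data frame: `pwm, p_ref, p_alt, impact, call`.
#' @export
motif_impact <- function(pwm, ref_window, alt_window, hit_threshold = 5e-4,
                         fc_min = 2, both_strands = TRUE) {
  if (nchar(ref_window) != nchar(alt_window))
    stop("ref and alt windows must have equal length")
  rc <- strsplit(toupper(ref_window), "", fixed = TRUE)[[1]]
  ac <- strsplit(toupper(alt_window), "", fixed = TRUE)[[1]]
  diffs <- which(rc != ac)
  if (length(diffs) && diff(range(diffs)) + 1L > pwm$L)
    stop("windows differ outside a single variant footprint")
  p_ref <- best_hit_pvalue(pwm, ref_window, both_strands)
  p_alt <- best_hit_pvalue(pwm, alt_window, both_strands)
  impact <- log2(p_ref / p_alt)
  call <- "none"
  if (p_alt <= hit_threshold && impact >= fc_min) call <- "GoM"
  else if (p_ref <= hit_threshold && -impact >= fc_min) call <- "LoM"
  data.frame(pwm = pwm$name, p_ref = p_ref, p_alt = p_alt,
             impact = impact, call = call, stringsAsFactors = FALSE)
}

#' Motif impacts of many variants against many PWMs
#'
#' @param pwms list of `rk_pwm` objects.
#' @param windows data frame with columns `variant_id, ref_window,
#'   alt_window` (plus any carried-through columns, e.g. `cohort`).
#' @param ... passed to [motif_impact()].
#' @return Data frame, one row per variant x PWM, with carried-through
#'   columns prepended.
#' @export
motif_impact_table <- function(pwms, windows, ...) {
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    for (pw in pwms) {
      mi <- motif_impact(pw, windows$ref_window[i], windows$alt_window[i], ...)
      keep <- windows[i, setdiff(names(windows), c("ref_window", "alt_window")),
                      drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(keep, mi, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Per-TF-family burden of motif-altering variants across cohorts
#'
#' For each TF family, builds the 2x2 table (family GoM+LoM hits vs hits in
#' all other families, case vs control events) and reports the Fisher odds
#' ratio, p-value and BH q-value across families. Families with zero total
#' hits are absent from the output.
#'
#' @param impacts data frame with columns `pwm`, `call` and `cohort`
#'   (`"case"`/`"control"`); rows with `call == "none"` are ignored.
#' @param family_map named character vector mapping PWM name to TF family,
#'   or a data frame with columns `pwm, family`.
#' @return Data frame `family, case_hits, control_hits, odds_ratio, p, q`,
#'   ordered by `q` then family.
#' @export
tf_family_burden <- function(impacts, family_map) {
  if (is.data.frame(family_map))
    family_map <- stats::setNames(family_map$family, family_map$pwm)
  hits <- impacts[impacts$call %in% c("GoM", "LoM"), , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(family = character(), case_hits = integer(),
                      control_hits = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric()))
  hits$family <- unname(family_map[hits$pwm])
  if (anyNA(hits$family)) stop("PWM without a family assignment")
  tot_case <- sum(hits$cohort == "case")
  tot_ctrl <- sum(hits$cohort == "control")
  fams <- sort(unique(hits$family))
  rows <- lapply(fams, function(fm) {
    a <- sum(hits$family == fm & hits$cohort == "case")
    cc <- sum(hits$family == fm & hits$cohort == "control")
    ft <- fisher_two_tailed(a, tot_case - a, cc, tot_ctrl - cc)
    data.frame(family = fm, case_hits = a, control_hits = cc,
               odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
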