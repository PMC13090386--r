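# Domain types and readers/writers for the formats the pipeline touches.
# All internal coordinates are 0-based half-open; VCF input (1-based) is
# converted on read, BED-family input is native.

#' Construct a two-group patient cohort
#'
#' A cohort is the set of patients whose genotypes and interactomes are
#' integrated. Exactly two group labels are used throughout: `"case"` and
#' `"control"` (e.g. bicuspid vs tricuspid aortic valve patients).
#'
#' @param case character vector of case patient IDs.
#' @param control character vector of control patient IDs.
#' @return An object of class `rk_cohort`: a list with elements `patients`
#'   (character) and `group` (named character, values `"case"`/`"control"`).
#' @examples
#' co <- cohort(paste0("case", 1:8), paste0("ctrl", 1:8))
#' table(co$group)
#' @export
cohort <- function(case, control) {
  case <- as.character(case)
  control <- as.character(control)
  patients <- c(case, control)
  if (length(case) == 0L || length(control) == 0L)
    stop("both cohort groups must be non-empty")
  if (anyDuplicated(patients))
    stop("patient IDs must be unique across groups")
  group <- stats::setNames(rep(c("case", "control"), c(length(case), length(control))),
                           patients)
  structure(list(patients = patients, group = group), class = "rk_cohort")
}

#' @export
print.rk_cohort <- function(x, ...) {
  cat("rk_cohort:", sum(x$group == "case"), "case /",
      sum(x$group == "control"), "control patients\n")
  invisible(x)
}

#' Patients of one cohort group
#' @param cohort an [cohort()] object.
#' @param which `"case"` or `"control"`.
#' @return Character vector of patient IDs.
#' @export
cohort_group <- function(cohort, which = c("case", "control")) {
  which <- match.arg(which)
  names(cohort$group)[cohort$group == which]
}

stopifnot_cohort <- function(cohort) {
  if (!inherits(cohort, "rk_cohort")) stop("expected an rk_cohort object")
}

variant_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Read cohort variant calls from VCF or the package TSV dialect
#'
#' VCF records are converted from 1-based to 0-based half-open coordinates:
#' a SNV at POS = 100 becomes `[99, 100)`; an indel with reference allele of
#' length `k` occupies `[POS-1, POS-1+k)` (left-anchored reference
#' footprint). Multi-allelic records are handled per `multiallelic`:
#' `"reject"` (default) drops them, `"split"` emits one biallelic record per
#' alternative allele. MAF is taken from the `MAF` INFO tag when present,
#' otherwise computed from cohort genotypes as alt-allele count / 2N.
#'
#' The TSV dialect has columns `chrom, pos, end, ref, alt, maf, kind`
#' followed by one dosage column (0/1/2) per patient; coordinates are
#' already 0-based half-open.
#'
#' @param path path to a `.vcf` file or a tab-separated table.
#' @param cohort an [cohort()] object; every patient must have a sample
#'   column in the file.
#' @param multiallelic `"reject"` or `"split"`.
#' @param max_maf variants with MAF at or above this are dropped (the
#'   upstream rare-variant filter; default 0.10).
#' @return A data frame of class `rk_variants` with columns
#'   `variant_id, chrom, pos, end, ref, alt, maf, kind` plus one integer
#'   dosage column per patient. Attributes `patients`, `n_skipped_multiallelic`,
#'   `n_malformed`, `n_dropped_maf` record parsing accounting.
#' @export
read_variants <- function(path, cohort, multiallelic = c("reject", "split"),
                          max_maf = 0.10) {
  multiallelic <- match.arg(multiallelic)
  stopifnot_cohort(cohort)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    out <- read_variants_vcf(path, cohort, multiallelic)
  } else {
    out <- read_variants_tsv(path, cohort)
  }
  drop <- out$df$maf >= max_maf
  out$df <- out$df[!drop, , drop = FALSE]
  rownames(out$df) <- NULL
  structure(out$df,
            class = c("rk_variants", "data.frame"),
            patients = cohort$patients,
            n_skipped_multiallelic = out$n_multi,
            n_malformed = out$n_malformed,
            n_dropped_maf = sum(drop))
}

read_variants_vcf <- function(path, cohort, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  missing <- setdiff(cohort$patients, colnames(gt))
  if (length(missing))
    stop("cohort patients absent from VCF samples: ", paste(missing, collapse = ", "))
  gt <- gt[, cohort$patients, drop = FALSE]
  info <- fix$INFO
  multi <- grepl(",", fix$ALT)
  n_multi <- 0L
  rows <- list()
  n_malformed <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && multiallelic == "reject") {
      n_multi <- n_multi + 1L
      next
    }
    for (ai in seq_along(alts)) {
      gts <- gt[i, ]
      dos <- gt_dosage(gts, allele = ai)
      if (anyNA(dos)) { n_malformed <- n_malformed + 1L; next }
      pos <- as.integer(fix$POS[i]) - 1L
      ref <- fix$REF[i]
      maf <- info_maf(info[i])
      if (is.na(maf)) maf <- sum(dos) / (2 * length(dos))
      rows[[length(rows) + 1L]] <- c(
        list(chrom = fix$CHROM[i], pos = pos, end = pos + nchar(ref),
             ref = ref, alt = alts[ai], maf = maf,
             kind = if (nchar(ref) == 1L && nchar(alts[ai]) == 1L) "snv" else "indel"),
        as.list(dos))
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(df)) {
    df <- empty_variants_df(cohort)
  } else {
    names(df) <- c("chrom", "pos", "end", "ref", "alt", "maf", "kind", cohort$patients)
    df <- cbind(variant_id = variant_id(df$chrom, df$pos, df$ref, df$alt), df)
  }
  list(df = df, n_multi = n_multi, n_malformed = n_malformed)
}

empty_variants_df <- function(cohort) {
  df <- data.frame(variant_id = character(), chrom = character(), pos = integer(),
                   end = integer(), ref = character(), alt = character(),
                   maf = numeric(), kind = character(), stringsAsFactors = FALSE)
  for (p in cohort$patients) df[[p]] <- integer()
  df
}

# dosage of allele index `allele` from GT strings like 0/1, 1|0, .
gt_dosage <- function(gts, allele = 1L) {
  parts <- strsplit(gts, "[/|]")
  vapply(parts, function(a) {
    if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return(NA_integer_)
    if (!all(grepl("^[0-9]+$", a))) return(NA_integer_)
    sum(as.integer(a) == allele)
  }, integer(1))
}

info_maf <- function(info) {
  m <- regmatches(info, regexpr("(?:^|;)MAF=([0-9.eE+-]+)", info))
  if (length(m) == 0L) return(NA_real_)
  as.numeric(sub(".*MAF=", "", m))
}

read_variants_tsv <- function(path, cohort) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "end", "ref", "alt", "maf", "kind")
  if (!all(need %in% names(df)))
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(cohort$patients, names(df))
  if (length(missing))
    stop("cohort patients absent from variant TSV: ", paste(missing, collapse = ", "))
  df <- df[, c(need, cohort$patients)]
  bad <- rowSums(is.na(df[, cohort$patients, drop = FALSE])) > 0
  n_malformed <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  df <- cbind(variant_id = variant_id(df$chrom, df$pos, df$ref, df$alt), df)
  list(df = df, n_multi = 0L, n_malformed = n_malformed)
}

#' Write variants in the package TSV dialect
#' @param variants an `rk_variants` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  df <- as.data.frame(variants)
  df$variant_id <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Alt-allele dosage matrix of a variant table
#' @param variants an `rk_variants` data frame.
#' @return Integer matrix, variants x patients, rownames `variant_id`.
#' @export
dosage_matrix <- function(variants) {
  patients <- attr(variants, "patients")
  m <- as.matrix(as.data.frame(variants)[, patients, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- variants$variant_id
  m
}

#' Read regulatory regions (BED6+2)
#'
#' Regions are the restriction-fragment-scale promoter and
#' promoter-interacting region (PIR, "enhancer") units of the interactome.
#' The file is BED6 (`chrom, start, end, name, score, strand`) with two
#' extra columns: `role` (`promoter`/`enhancer`) and `gene_ids`
#' (comma-separated gene IDs for promoters, `.` for enhancers). Fragment
#' length is the region width `end - start`.
#'
#' @param path path to the BED6+2 file (tab-separated, no header).
#' @return Data frame of class `rk_regions` with columns
#'   `region_id, chrom, start, end, strand, role, gene_ids`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "role", "gene_ids"))
  if (any(df$start >= df$end)) stop("region with start >= end")
  if (!all(df$role %in% c("promoter", "enhancer")))
    stop("role must be 'promoter' or 'enhancer'")
  no_genes <- df$gene_ids == "." | df$gene_ids == ""
  if (any(df$role == "promoter" & no_genes))
    stop("promoter regions must carry at least one gene ID")
  if (any(df$role == "enhancer" & !no_genes))
    stop("enhancer regions carry no gene IDs at load time")
  out <- data.frame(region_id = df$name, chrom = df$chrom, start = df$start,
                    end = df$end, strand = df$strand, role = df$role,
                    gene_ids = df$gene_ids, stringsAsFactors = FALSE)
  structure(out, class = c("rk_regions", "data.frame"))
}

#' Write regulatory regions as BED6+2
#' @param regions an `rk_regions` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start, regions$end,
                   regions$region_id, 0L, regions$strand,
                   regions$role, regions$gene_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the gene annotation table
#'
#' Columns: `gene_id`, `tier` (`tier1`, `tier2` or `none`; disease-gene
#' tiers are mutually exclusive), `housekeeping` and `endothelial_specific`
#' (logical). Housekeeping genes serve as the comparison universe for tier
#' enrichment.
#'
#' @param path tab-separated file with a header.
#' @return Data frame of class `rk_genes`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tier", "housekeeping", "endothelial_specific")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$tier %in% c("tier1", "tier2", "none")))
    stop("tier must be one of tier1, tier2, none")
  df$housekeeping <- as.logical(df$housekeeping)
  df$endothelial_specific <- as.logical(df$endothelial_specific)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene IDs")
  structure(df[, need], class = c("rk_genes", "data.frame"))
}

#' Write the gene annotation table
#' @param genes an `rk_genes` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-patient promoter-anchored interactions
#'
#' BEDPE-like tab-separated table with header columns
#' `chrom1, start1, end1, chrom2, start2, end2, patient, support_pairs,
#' adj_p`; anchor 1 is the promoter fragment, anchor 2 the PIR. The `trans`
#' flag is set when the anchors are on different chromosomes; for cis pairs
#' `distance` is the absolute difference of anchor midpoints, for trans
#' pairs it is `NA`.
#'
#' @param path path to the table.
#' @param cohort an [cohort()] object; unknown patient IDs are an error.
#' @return Data frame of class `rk_interactions` with the input columns plus
#'   `trans`, `distance`, and `key` (promoter anchor x PIR anchor identity
#'   used for cross-patient uniqueness).
#' @export
read_interactions <- function(path, cohort) {
  stopifnot_cohort(cohort)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "patient", "support_pairs", "adj_p")
  if (!all(need %in% names(df)))
    stop("interaction table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  unknown <- setdiff(unique(df$patient), cohort$patients)
  if (length(unknown))
    stop("unknown patient IDs in interaction table: ", paste(unknown, collapse = ", "))
  as_interactions(df)
}

# derive trans/distance/key columns; shared by reader and simulator
as_interactions <- function(df) {
  df$trans <- df$chrom1 != df$chrom2
  mid1 <- (df$start1 + df$end1) / 2
  mid2 <- (df$start2 + df$end2) / 2
  df$distance <- ifelse(df$trans, NA_real_, abs(mid2 - mid1))
  df$key <- paste0(df$chrom1, ":", df$start1, "-", df$end1, "|",
                   df$chrom2, ":", df$start2, "-", df$end2)
  structure(df, class = c("rk_interactions", "data.frame"))
}

#' Write an interaction table
#' @param interactions an `rk_interactions` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  df <- as.data.frame(interactions)
  df <- df[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
               "patient", "support_pairs", "adj_p")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap variants with regulatory regions
#'
#' Half-open interval intersection between variant reference footprints
#' `[pos, end)` and regions `[start, end)`, per chromosome. A variant may
#' overlap both a promoter and an enhancer; each pairing is one row.
#'
#' @param variants an `rk_variants` data frame.
#' @param regions an `rk_regions` data frame.
#' @return Data frame `variant_id, region_id, role`, ordered by variant
#'   input order then region input order.
#' @export
overlap_variants_regions <- function(variants, regions) {
  if (nrow(variants) == 0L || nrow(regions) == 0L)
    return(data.frame(variant_id = character(), region_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  # GRanges is 1-based closed: [pos, end) half-open becomes [pos+1, end]
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos + 1L, variants$end))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(vg, rg)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ord <- order(qi, si)
  data.frame(variant_id = variants$variant_id[qi[ord]],
             region_id = regions$region_id[si[ord]],
             role = regions$role[si[ord]],
             stringsAsFactors = FALSE)
}
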