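## Per-marker diversity statistics and the three-rule QC filter
## (missingness, major-allele frequency, heterozygosity).

#' Per-marker diversity statistics
#'
#' Allele frequencies come from non-missing calls only (alternate frequency
#' = mean dosage / 2).  For a biallelic marker with frequencies p, q:
#' gene diversity `D = 1 - p^2 - q^2 = 2pq` and Botstein's
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2` (so `PIC <= D <= 0.5` with both maxima
#' at p = 0.5: D = 0.5, PIC = 0.375).  `het_obs` is the fraction of
#' non-missing calls equal to 1.  A marker with no non-missing call is
#' flagged undefined (`defined = FALSE`, statistics `NA`).
#'
#' @param geno a [genotype_matrix].
#' @return data.frame of class `marker_stats` with one row per marker:
#'   `marker_id`, `maf_major` (major-allele frequency, in `[0.5, 1]`),
#'   `gene_diversity`, `pic`, `het_obs`, `missing_rate`, `defined`.
#' @export
marker_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  x <- geno$calls
  n_nonmiss <- colSums(!is.na(x))
  defined <- n_nonmiss > 0
  p_alt <- colSums(x, na.rm = TRUE) / (2 * n_nonmiss)
  p_alt[!defined] <- NA_real_
  maf_major <- pmax(p_alt, 1 - p_alt)
  D <- 2 * p_alt * (1 - p_alt)
  pic <- D - 2 * p_alt^2 * (1 - p_alt)^2
  het <- colSums(x == 1L, na.rm = TRUE) / n_nonmiss
  het[!defined] <- NA_real_
  out <- data.frame(marker_id = colnames(x),
                    maf_major = unname(maf_major),
                    gene_diversity = unname(D),
                    pic = unname(pic),
                    het_obs = unname(het),
                    missing_rate = unname(colMeans(is.na(x))),
                    defined = unname(defined),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Filter markers by missingness, MAF and heterozygosity
#'
#' A marker is removed iff `missing_rate > missing` OR `maf_major > maf` OR
#' `het_obs > het` — strict inequalities, so markers sitting exactly on a
#' threshold are retained.  Monomorphic markers fail the MAF rule
#' automatically (`maf_major = 1`).  For reporting, each removed marker is
#' charged to the first rule that catches it, in the order missingness,
#' MAF, heterozygosity (the removal set itself is order-independent).
#' Undefined (all-missing) markers fall to the missingness rule.
#'
#' @param geno a [genotype_matrix].
#' @param missing,maf,het thresholds; defaults 0.10, 0.95, 0.20.
#' @return list with `geno` (filtered [genotype_matrix], marker order
#'   preserved) and `report` (class `filter_report`: `n_input`,
#'   `n_removed_missing`, `n_removed_maf`, `n_removed_het`, `n_retained`,
#'   `thresholds`).
#' @export
filter_markers <- function(geno, missing = 0.10, maf = 0.95, het = 0.20) {
  st <- marker_stats(geno)
  bad_miss <- !st$defined | st$missing_rate > missing
  bad_maf <- !bad_miss & !is.na(st$maf_major) & st$maf_major > maf
  bad_het <- !bad_miss & !bad_maf & !is.na(st$het_obs) & st$het_obs > het
  keep <- !(bad_miss | bad_maf | bad_het)
  report <- structure(list(n_input = ncol(geno$calls),
                           n_removed_missing = sum(bad_miss),
                           n_removed_maf = sum(bad_maf),
                           n_removed_het = sum(bad_het),
                           n_retained = sum(keep),
                           thresholds = c(missing = missing, maf = maf,
                                          het = het)),
                      class = "filter_report")
  out <- genotype_matrix(geno$calls[, keep, drop = FALSE],
                         geno$markers[keep, , drop = FALSE])
  list(geno = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("marker QC: %d in -> %d retained ",
                     "(removed: %d missing>%g, %d MAF>%g, %d het>%g)\n"),
              x$n_input, x$n_retained,
              x$n_removed_missing, x$thresholds["missing"],
              x$n_removed_maf, x$thresholds["maf"],
              x$n_removed_het, x$thresholds["het"]))
  invisible(x)
}

#' Summary of diversity statistics over retained markers
#'
#' @param stats a [marker_stats()] result (usually computed on a filtered
#'   matrix); undefined markers are dropped.
#' @return data.frame with rows `maf_major`, `gene_diversity`, `pic`,
#'   `het_obs` and columns `min`, `mean`, `max`.
#' @export
summarize_diversity <- function(stats) {
  stopifnot(inherits(stats, "marker_stats"))
  stats <- stats[stats$defined, , drop = FALSE]
  if (nrow(stats) == 0) stop("no defined markers to summarize")
  cols <- c("maf_major", "gene_diversity", "pic", "het_obs")
  out <- t(vapply(cols, function(cc)
    c(min = min(stats[[cc]]), mean = mean(stats[[cc]]),
      max = max(stats[[cc]])), numeric(3)))
  as.data.frame(out)
}
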