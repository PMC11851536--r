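# Two-tier quality control and kinship-based subsampling.
#
# Tier 1 (QC1) controls marker and sample missingness only and feeds the
# run/island stages; tier 2 (QC2) additionally applies the MAF filter and
# feeds Tajima's D and FST. "Minimum call rate 0.10" is interpreted in the
# PLINK --geno/--mind idiom as maximum missingness 0.10 per marker and per
# sample.

#' Filter markers and samples by missingness (QC1)
#'
#' Markers with missing-call fraction above `max_missing_marker` are removed
#' first; then samples with missing fraction (over the surviving markers)
#' above `max_missing_sample` are removed.
#'
#' @param g A [genotypes()] object.
#' @param max_missing_marker,max_missing_sample Maximum tolerated missing
#'   fraction per marker / per sample, both in `[0, 1]` (default 0.10).
#' @return A list with elements `genotypes` (the filtered object) and
#'   `report` (a one-row data.frame of in/out counts and removals).
#' @export
filter_call_rate <- function(g, max_missing_marker = 0.10,
                             max_missing_sample = 0.10) {
  stopifnot(max_missing_marker >= 0, max_missing_marker <= 1,
            max_missing_sample >= 0, max_missing_sample <= 1)
  miss_m <- colMeans(is.na(g$calls))
  keep_m <- miss_m <= max_missing_marker
  report <- data.frame(n_markers_in = ncol(g$calls),
                       n_samples_in = nrow(g$calls),
                       markers_removed_missing = sum(!keep_m))
  if (!any(keep_m)) {
    msg <- "all markers removed by the missingness filter"
    attr(msg, "report") <- report
    stop(msg)
  }
  calls <- g$calls[, keep_m, drop = FALSE]
  miss_s <- rowMeans(is.na(calls))
  keep_s <- miss_s <= max_missing_sample
  report$samples_removed_missing <- sum(!keep_s)
  report$n_markers_out <- sum(keep_m)
  report$n_samples_out <- sum(keep_s)
  out <- genotypes(g$samples[keep_s, , drop = FALSE],
                   g$map[keep_m, , drop = FALSE],
                   calls[keep_s, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Filter markers by minor allele frequency (QC2 tier)
#'
#' Removes markers whose minor-allele frequency, computed from non-missing
#' calls, is below `min_maf`. Monomorphic markers are removed at any
#' `min_maf > 0`.
#'
#' @param g A [genotypes()] object.
#' @param min_maf Minimum MAF in `[0, 0.5]` (default 0.01).
#' @return A list with elements `genotypes` and `report`.
#' @export
filter_maf <- function(g, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  p <- alt_freqs(g)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # markers with no calls
  keep <- maf >= min_maf
  report <- data.frame(n_markers_in = ncol(g$calls),
                       n_samples_in = nrow(g$calls),
                       markers_removed_maf = sum(!keep),
                       n_markers_out = sum(keep),
                       n_samples_out = nrow(g$calls))
  out <- genotypes(g$samples, g$map[keep, , drop = FALSE],
                   g$calls[, keep, drop = FALSE])
  list(genotypes = out, report = report)
}

#' Standardized-genotype kinship matrix
#'
#' Pairwise relatedness estimated as the mean over usable markers of
#' standardized genotype products:
#' `K_ij = (1/M') sum_m (g_im - 2 p_m)(g_jm - 2 p_m) / (2 p_m (1 - p_m))`,
#' where the sum runs over markers non-missing in both samples with
#' `0 < p_m < 1` and `M'` is their count. Under random mating the diagonal
#' is close to 1 and unrelated pairs are close to 0. Used only to rank
#' samples for [select_unrelated()].
#'
#' @param g A [genotypes()] object with at least two samples.
#' @return A symmetric numeric matrix with sample_id dimnames. Pairs with no
#'   usable marker are `NA` and counted in the `n_undefined_pairs`
#'   attribute.
#' @export
kinship_matrix <- function(g) {
  stopifnot(nrow(g$samples) >= 2)
  p <- alt_freqs(g)
  use <- !is.na(p) & p > 0 & p < 1
  calls <- g$calls[, use, drop = FALSE]
  p <- p[use]
  if (!length(p)) stop("no polymorphic marker available for kinship")
  z <- sweep(calls, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)
  den <- tcrossprod(obs * 1)
  k <- num / den
  k[den == 0] <- NA
  attr(k, "n_undefined_pairs") <- sum(den[upper.tri(den)] == 0)
  dimnames(k) <- list(g$samples$sample_id, g$samples$sample_id)
  k
}

#' Select up to n animals per breed by greedy kinship pruning
#'
#' Within each breed, repeatedly removes the sample with the highest mean
#' kinship to the breed's remaining members (ties broken by sample_id
#' lexical order) until `per_breed_n` remain. Breeds at or below the target
#' size are kept whole.
#'
#' @param k Kinship matrix from [kinship_matrix()].
#' @param samples data.frame with `sample_id` and `breed`.
#' @param per_breed_n Target number of animals per breed (default 20).
#' @return Character vector of kept sample_ids, in the input order.
#' @export
select_unrelated <- function(k, samples, per_breed_n = 20) {
  stopifnot(per_breed_n >= 1)
  keep <- character(0)
  for (b in unique(samples$breed)) {
    ids <- samples$sample_id[samples$breed == b]
    while (length(ids) > per_breed_n) {
      sub <- k[ids, ids, drop = FALSE]
      diag(sub) <- NA
      score <- rowMeans(sub, na.rm = TRUE)
      worst <- max(score, na.rm = TRUE)
      drop_id <- sort(ids[!is.na(score) & score == worst])[1]
      ids <- setdiff(ids, drop_id)
    }
    keep <- c(keep, ids)
  }
  samples$sample_id[samples$sample_id %in% keep]
}
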