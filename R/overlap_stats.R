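# Cross-breed accounting: hot spots of islands/signals shared by
# significantly many breeds (Z-score rule), island x signal overlap
# records, one-way ANOVA of breed factors, and pairwise Weir-Cockerham
# FST.

#' Cross-breed hot spots by sweep-line decomposition and Z-score
#'
#' The genome is decomposed into maximal intervals with a constant set of
#' supporting breeds (sweep line over all interval ends); for every region
#' with coverage >= 1, `k` is the number of distinct supporting breeds and
#' `z = (k - mean k) / sd k` over all regions. Regions with `z >= z_crit`
#' (one-sided) are significant; adjacent significant regions are merged
#' with their supporting sets unioned.
#'
#' @param features data.frame with columns `breed`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), e.g. islands or signal windows.
#' @param z_crit Z threshold (default 1.645, one-sided p < 0.05).
#' @return List with `regions` (all constant-coverage regions with `k`,
#'   `z`, `significant`, `breeds`) and `hot_spots` (merged significant
#'   regions).
#' @export
hot_spots <- function(features, z_crit = 1.645) {
  stopifnot(nrow(features) >= 1)
  regions <- list()
  for (ch in unique(features$chrom)) {
    f <- features[features$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(f$start_bp, f$end_bp + 1)))
    for (i in seq_len(length(cuts) - 1)) {
      lo <- cuts[i]
      hi <- cuts[i + 1] - 1
      sup <- sort(unique(f$breed[f$start_bp <= lo & f$end_bp >= hi]))
      if (!length(sup)) next
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = ch, start_bp = lo, end_bp = hi,
                   k = length(sup), breeds = paste(sup, collapse = ","))
    }
  }
  reg <- do.call(rbind, regions)
  # merge adjacent regions with identical supporting sets (maximal
  # constant-coverage regions)
  reg <- merge_adjacent(reg, same = function(a, b) a$breeds == b$breeds)
  if (nrow(reg) < 2 || sd(reg$k) == 0) {
    warning("hot spots undefined: fewer than two regions or zero ",
            "variance in breed counts")
    reg$z <- NA_real_
    reg$significant <- FALSE
  } else {
    reg$z <- (reg$k - mean(reg$k)) / sd(reg$k)
    reg$significant <- reg$z >= z_crit
  }
  hs <- reg[reg$significant, , drop = FALSE]
  if (nrow(hs)) {
    hs <- merge_adjacent(hs, same = function(a, b) TRUE,
                         union_breeds = TRUE)
    hs$k <- vapply(strsplit(hs$breeds, ","), length, integer(1))
  }
  rownames(reg) <- rownames(hs) <- NULL
  list(regions = reg, hot_spots = hs)
}

# Merge rows whose intervals touch (end + 1 == next start, same chrom) and
# satisfy `same`; breed sets are unioned when requested, z kept as max.
merge_adjacent <- function(df, same, union_breeds = FALSE) {
  if (nrow(df) < 2) return(df)
  df <- df[order(chrom_order(df$chrom), df$start_bp), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    if (df$chrom[i] == out$chrom[j] &&
        df$start_bp[i] == out$end_bp[j] + 1 &&
        same(out[j, ], df[i, ])) {
      out$end_bp[j] <- df$end_bp[i]
      if (union_breeds) {
        bs <- sort(unique(c(strsplit(out$breeds[j], ",")[[1]],
                            strsplit(df$breeds[i], ",")[[1]])))
        out$breeds[j] <- paste(bs, collapse = ",")
        out$k[j] <- length(bs)
      }
      if ("z" %in% names(df)) out$z[j] <- max(out$z[j], df$z[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Overlaps between islands and selection signals
#'
#' One record per (island, signal window) pair on the same chromosome with
#' at least 1 bp intersection (1-based inclusive coordinates). By default
#' only same-breed pairs are counted; `same_breed = FALSE` counts
#' cross-breed pairs too.
#'
#' @param islands data.frame from [islands_by_breed()].
#' @param signals data.frame from [threshold_signals()]; window
#'   coordinates are converted to 1-based inclusive.
#' @param same_breed Restrict to same-breed pairs (default TRUE).
#' @return data.frame with `breed`, `signal_breed`, `chrom`,
#'   `island_start`, `island_end`, `signal_start`, `signal_end`,
#'   `overlap_bp`.
#' @export
count_overlaps <- function(islands, signals, same_breed = TRUE) {
  empty <- data.frame(breed = character(0), signal_breed = character(0),
                      chrom = character(0), island_start = numeric(0),
                      island_end = numeric(0), signal_start = numeric(0),
                      signal_end = numeric(0), overlap_bp = numeric(0))
  if (!nrow(islands) || !nrow(signals)) return(empty)
  out <- list()
  for (i in seq_len(nrow(islands))) {
    cand <- signals[signals$chrom == islands$chrom[i], , drop = FALSE]
    if (same_breed)
      cand <- cand[cand$breed == islands$breed[i], , drop = FALSE]
    if (!nrow(cand)) next
    s1 <- cand$window_start + 1  # 1-based inclusive
    e1 <- cand$window_end
    ov <- pmin(e1, islands$end_bp[i]) - pmax(s1, islands$start_bp[i]) + 1
    hit <- which(ov >= 1)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        breed = islands$breed[i], signal_breed = cand$breed[hit],
        chrom = islands$chrom[i], island_start = islands$start_bp[i],
        island_end = islands$end_bp[i], signal_start = s1[hit],
        signal_end = e1[hit], overlap_bp = ov[hit])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA via [stats::aov()], reporting F,
#' its p-value and `R^2 = SS_between / SS_total`. Groups with zero
#' observations are dropped with a warning.
#'
#' @param values Numeric response.
#' @param groups Group labels, same length.
#' @param factor_name Label stored in the output row.
#' @return One-row data.frame with `factor_name`, `f`, `p`, `r_squared`,
#'   `n_groups`, `n`.
#' @export
one_way_anova <- function(values, groups, factor_name = "factor") {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  if (is.factor(groups) &&
      nlevels(droplevels(groups[ok])) < nlevels(groups))
    warning("groups with zero observations dropped")
  groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  n <- length(values)
  stopifnot(k >= 2, n > k)
  tab <- stats::anova(stats::lm(values ~ groups))
  ssb <- tab[["Sum Sq"]][1]
  sst <- sum(tab[["Sum Sq"]])
  data.frame(factor_name = factor_name, f = tab[["F value"]][1],
             p = tab[["Pr(>F)"]][1], r_squared = ssb / sst,
             n_groups = k, n = n)
}

#' ANOVA of breed factors on cross-breed sharing
#'
#' Builds the observation table from hot-spot regions: one observation per
#' (region, supporting breed) incidence with response = the region's
#' breed-sharing count `k` and group = the breed's factor level, then runs
#' [one_way_anova()] per factor. This coding is interpretive and recorded
#' in the pipeline provenance.
#'
#' @param regions `regions` element from [hot_spots()].
#' @param factors data.frame with a `breed` column and one column per
#'   factor (e.g. geographic origin, FCI group).
#' @return data.frame, one row per factor.
#' @export
breed_factor_anova <- function(regions, factors) {
  stopifnot("breed" %in% names(factors))
  obs <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    data.frame(breed = strsplit(regions$breeds[i], ",")[[1]],
               k = regions$k[i])
  }))
  res <- lapply(setdiff(names(factors), "breed"), function(fac) {
    lev <- factors[[fac]][match(obs$breed, factors$breed)]
    one_way_anova(obs$k, lev, factor_name = fac)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Weir-Cockerham variance components for one biallelic locus, two pops
#'
#' Direct evaluation of the two-population (r = 2) components `a`, `b`,
#' `c` from sample sizes, allele frequencies and heterozygote frequencies.
#' Exposed for verification; [pairwise_fst()] sums them over loci.
#'
#' @param n1,n2 Individuals with calls in each population.
#' @param p1,p2 Alternate-allele frequencies.
#' @param h1,h2 Observed heterozygote frequencies.
#' @return Named list with `n_bar`, `n_c`, `p_bar`, `s2`, `h_bar`, `a`,
#'   `b`, `c`.
#' @export
wc_fst_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - s2 / 2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c <- h_bar / 2
  list(n_bar = n_bar, n_c = n_c, p_bar = p_bar, s2 = s2, h_bar = h_bar,
       a = a, b = b, c = c)
}

#' Pairwise Weir-Cockerham FST matrix
#'
#' For each breed pair, theta-hat is the ratio of sums over loci of the
#' `a` component to `a + b + c` (multi-locus WC84). Loci are used when
#' both breeds have calls and the pooled frequency is strictly between 0
#' and 1. Negative estimates are reported, not clipped.
#'
#' @param g A [genotypes()] object (QC2 tier) with breed labels.
#' @return Symmetric numeric matrix (diagonal 0) with breed dimnames;
#'   pairs without a usable locus are `NA`.
#' @export
pairwise_fst <- function(g) {
  breeds <- unique(g$samples$breed)
  stopifnot(length(breeds) >= 2)
  stat <- lapply(breeds, function(b) {
    calls <- g$calls[g$samples$breed == b, , drop = FALSE]
    n <- colSums(!is.na(calls))
    list(n = n,
         p = ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), NA),
         h = ifelse(n > 0, colSums(calls == 1L, na.rm = TRUE) / n, NA))
  })
  names(stat) <- breeds
  fst <- matrix(NA_real_, length(breeds), length(breeds),
                dimnames = list(breeds, breeds))
  diag(fst) <- 0
  for (i in seq_along(breeds)[-length(breeds)]) {
    for (j in (i + 1):length(breeds)) {
      s1 <- stat[[i]]
      s2 <- stat[[j]]
      pbar <- (s1$n * s1$p + s2$n * s2$p) / (s1$n + s2$n)
      use <- s1$n > 0 & s2$n > 0 & !is.na(pbar) & pbar > 0 & pbar < 1
      if (!any(use)) {
        warning("no co-polymorphic locus for pair ", breeds[i], " / ",
                breeds[j])
        next
      }
      cmp <- wc_fst_components(s1$n[use], s2$n[use], s1$p[use], s2$p[use],
                               s1$h[use], s2$h[use])
      fst[i, j] <- fst[j, i] <-
        sum(cmp$a) / sum(cmp$a + cmp$b + cmp$c)
    }
  }
  fst
}
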