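# Windowed Tajima's D per breed and thresholding into
# balancing-selection signals. D contrasts nucleotide diversity (pi) with
# the scaled segregating-site count (S/a1); an excess of
# intermediate-frequency variants drives D positive.

#' Normalizing constants for Tajima's D
#'
#' Standard constants for a sample of `n` chromosomes:
#' `a1 = sum_{i<n} 1/i`, `a2 = sum_{i<n} 1/i^2`, `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Number of sampled chromosomes, at least 4.
#' @return Named list with `n`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`,
#'   `e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires at least 4 sampled chromosomes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed segregating sites, diversity and Tajima's D
#'
#' Sites are binned into non-overlapping windows of `window_bp` anchored
#' at position 0 (`floor((bp - 1) / window_bp)`). Per site, with `n_s`
#' non-missing chromosomes and alternate count `x`, the site contributes
#' `2 x (n_s - x) / (n_s (n_s - 1))` to pi and is segregating when
#' `0 < x < n_s`; sites with `n_s < 4` are ignored. D uses constants at
#' `n = round(median n_s over the window's segregating sites)` and is
#' undefined (`NA`) when `S = 0`.
#'
#' @param g A [genotypes()] object holding one breed's samples (QC2 tier).
#' @param window_bp Window length in bp (default 250000).
#' @param breed Label stored in the output; defaults to the (single) breed
#'   in `g`.
#' @return data.frame with columns `breed`, `chrom`, `window_start`
#'   (0-based, multiple of `window_bp`), `window_end`, `n_sites`, `s`,
#'   `pi`, `d`.
#' @export
window_stats <- function(g, window_bp = 250000,
                         breed = unique(g$samples$breed)[1]) {
  x <- colSums(g$calls, na.rm = TRUE)
  ns <- 2 * colSums(!is.na(g$calls))
  usable <- ns >= 4
  seg <- usable & x > 0 & x < ns
  pi_site <- ifelse(usable, 2 * x * (ns - x) / (ns * pmax(ns - 1, 1)), 0)
  win <- floor((g$map$bp - 1) / window_bp)
  key <- paste(g$map$chrom, win, sep = "\r")
  out <- lapply(unique(key), function(k) {
    mi <- which(key == k)
    mi_use <- mi[usable[mi]]
    s <- sum(seg[mi])
    pi <- sum(pi_site[mi])
    d <- NA_real_
    if (s >= 1) {
      nmed <- round(median(ns[mi[seg[mi]]]))
      if (nmed >= 4) {
        cst <- tajima_constants(nmed)
        vd <- cst$e1 * s + cst$e2 * s * (s - 1)
        if (vd > 0) d <- (pi - s / cst$a1) / sqrt(vd)
      }
    }
    data.frame(breed = breed, chrom = g$map$chrom[mi[1]],
               window_start = win[mi[1]] * window_bp,
               window_end = (win[mi[1]] + 1) * window_bp,
               n_sites = length(mi), s = s, pi = pi, d = d)
  })
  res <- do.call(rbind, out)
  res <- res[order(chrom_order(res$chrom), res$window_start), ]
  rownames(res) <- NULL
  res
}

#' Windowed statistics for every breed
#'
#' @param g A [genotypes()] object with breed labels (QC2 tier).
#' @param window_bp Window length in bp.
#' @return Row-bound [window_stats()] tables, one per breed.
#' @export
window_stats_by_breed <- function(g, window_bp = 250000) {
  out <- lapply(unique(g$samples$breed), function(b) {
    gb <- subset_genotypes(g, samples = g$samples$sample_id[
      g$samples$breed == b])
    window_stats(gb, window_bp, breed = b)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Threshold windows into balancing-selection signals
#'
#' Per breed, the threshold is the `(1 - top_fraction)` quantile (linear
#' interpolation) of the breed's defined D values, genome-wide. Signals
#' are windows with `D >= threshold` and `D > 0`; ties at the threshold
#' are all included.
#'
#' @param stats data.frame from [window_stats_by_breed()].
#' @param top_fraction Upper tail fraction (default 0.001).
#' @return data.frame of signal windows with an added `threshold_used`
#'   column.
#' @export
threshold_signals <- function(stats, top_fraction = 0.001) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  out <- list()
  for (b in unique(stats$breed)) {
    sub <- stats[stats$breed == b, , drop = FALSE]
    dv <- sub$d[!is.na(sub$d)]
    if (!length(dv)) {
      warning("no window with defined Tajima's D for breed ", b)
      next
    }
    thr <- unname(quantile(dv, 1 - top_fraction, type = 7))
    hit <- !is.na(sub$d) & sub$d >= thr & sub$d > 0
    if (any(hit)) {
      sig <- sub[hit, , drop = FALSE]
      sig$threshold_used <- thr
      out[[length(out) + 1L]] <- sig
    }
  }
  if (!length(out))
    return(cbind(stats[0, , drop = FALSE],
                 data.frame(threshold_used = numeric(0))))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
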