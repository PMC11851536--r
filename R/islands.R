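# Breed-level islands: regions where the fraction of a breed's individuals
# whose runs (HRR or ROH) cover a SNP exceeds a high genome-wide
# percentile of that breed's per-SNP sharing profile.

#' Per-SNP run-sharing frequency for one breed
#'
#' For each marker, the fraction of the breed's individuals that have at
#' least one run (of the requested type) covering the marker's position.
#' Overlapping runs in one individual count once.
#'
#' @param runs data.frame from [detect_runs()] or [hbd_segments()]
#'   (any breeds; filtered internally).
#' @param g A [genotypes()] object; its map defines the profile grid.
#' @param breed Breed label; its individuals are taken from `g$samples`.
#' @param run_type `"HRR"` or `"ROH"` (default: all rows already in
#'   `runs`).
#' @return data.frame with columns `breed`, `marker_id`, `chrom`, `bp`,
#'   `freq`.
#' @export
snp_share_frequency <- function(runs, g, breed, run_type = NULL) {
  ids <- g$samples$sample_id[g$samples$breed == breed]
  if (!length(ids)) stop("no samples for breed ", breed)
  sub <- runs[runs$sample_id %in% ids, , drop = FALSE]
  if (!is.null(run_type)) sub <- sub[sub$run_type == run_type, , drop = FALSE]
  count <- numeric(nrow(g$map))
  for (ch in unique(g$map$chrom)) {
    mi <- which(g$map$chrom == ch)
    bp <- g$map$bp[mi]
    rsub <- sub[sub$chrom == ch, , drop = FALSE]
    if (!nrow(rsub)) next
    for (sid in unique(rsub$sample_id)) {
      cov <- logical(length(mi))
      rs <- rsub[rsub$sample_id == sid, , drop = FALSE]
      for (r in seq_len(nrow(rs))) {
        lo <- findInterval(rs$start_bp[r] - 0.5, bp) + 1L
        hi <- findInterval(rs$end_bp[r] + 0.5, bp)
        if (hi >= lo) cov[lo:hi] <- TRUE
      }
      count[mi] <- count[mi] + cov
    }
  }
  data.frame(breed = breed, marker_id = g$map$marker_id,
             chrom = g$map$chrom, bp = g$map$bp,
             freq = count / length(ids), row.names = NULL)
}

#' Call islands from a sharing profile
#'
#' The threshold is the `(100 - top_percentile)`-th percentile (linear
#' interpolation between order statistics) of the breed's genome-wide
#' per-SNP sharing frequencies. Islands are maximal stretches of
#' consecutive markers within a chromosome with `freq >= threshold` and
#' `freq > 0`, kept when they contain at least `min_snp` markers.
#'
#' @param profile data.frame from [snp_share_frequency()].
#' @param top_percentile Upper tail size in percent (default 0.1, i.e. the
#'   99.9th percentile).
#' @param min_snp Minimum member SNPs per island (default 2).
#' @param island_type Label stored in the output (`"HRRI"` or `"ROHI"`).
#' @return data.frame with columns `breed`, `island_type`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snp`, `threshold_used`, `peak_frequency`.
#' @export
call_islands <- function(profile, top_percentile = 0.1, min_snp = 2,
                         island_type = "HRRI") {
  stopifnot(nrow(profile) > 0, top_percentile > 0, top_percentile < 100,
            min_snp >= 1)
  empty <- data.frame(breed = character(0), island_type = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snp = integer(0),
                      threshold_used = numeric(0),
                      peak_frequency = numeric(0))
  thr <- unname(quantile(profile$freq, 1 - top_percentile / 100, type = 7))
  if (thr <= 0) {
    warning("degenerate sharing profile for breed ",
            profile$breed[1], ": threshold is 0, no islands called")
    return(empty)
  }
  pass <- profile$freq >= thr & profile$freq > 0
  if (all(pass[profile$freq > 0]))
    warning("sharing profile for breed ", profile$breed[1],
            " is degenerate: every nonzero marker reaches the threshold")
  out <- list()
  for (ch in unique(profile$chrom)) {
    mi <- which(profile$chrom == ch)
    r <- rle(pass[mi])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_snp)) {
      seg <- mi[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        breed = profile$breed[1], island_type = island_type,
        chrom = ch, start_bp = profile$bp[seg[1]],
        end_bp = profile$bp[seg[length(seg)]],
        n_snp = length(seg), threshold_used = thr,
        peak_frequency = max(profile$freq[seg]))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call islands for every breed
#'
#' @param runs Runs table (HRR or ROH rows).
#' @param g A [genotypes()] object (QC1 tier).
#' @param run_type Which run type feeds the profile.
#' @param island_type Output label; defaults to `"HRRI"` for HRR runs and
#'   `"ROHI"` for ROH runs.
#' @param top_percentile,min_snp Passed to [call_islands()].
#' @return data.frame of islands across breeds.
#' @export
islands_by_breed <- function(runs, g, run_type = "HRR",
                             island_type = if (run_type == "HRR") "HRRI"
                                           else "ROHI",
                             top_percentile = 0.1, min_snp = 2) {
  out <- lapply(unique(g$samples$breed), function(b) {
    prof <- snp_share_frequency(runs, g, b, run_type)
    call_islands(prof, top_percentile, min_snp, island_type)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
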