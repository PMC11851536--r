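# Shared builders and independent brute-force oracles. Every oracle here
# is deliberately naive (full enumeration, all-pairs sums) so it shares no
# code path with the implementation it checks.

make_genotypes <- function(calls, bp = NULL, chrom = NULL, breed = "X",
                           sample_ids = NULL) {
  calls <- rbind(calls)
  n <- nrow(calls)
  m <- ncol(calls)
  if (is.null(bp)) bp <- seq_len(m) * 1e4
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n))
  genotypes(
    data.frame(sample_id = sample_ids, breed = rep_len(breed, n)),
    data.frame(marker_id = sprintf("m%04d", seq_len(m)),
               chrom = as.character(chrom), bp = bp),
    matrix(as.integer(calls), n, m))
}

# All inclusion-maximal feasible intervals for one individual on one
# chromosome by O(m^2) enumeration with O(m) feasibility checks.
brute_force_runs <- function(calls, bp, params) {
  m <- length(calls)
  target <- if (params$run_type == "HRR") {
    !is.na(calls) & calls == 1L
  } else {
    !is.na(calls) & calls != 1L
  }
  opposite <- !is.na(calls) & !target
  feasible <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (!target[i] || !target[j]) next
      span <- i:j
      if (sum(opposite[span]) > params$max_opposite) next
      if (sum(is.na(calls[span])) > params$max_missing) next
      if (j > i && any(diff(bp[span]) > params$max_gap_bp)) next
      if (j - i + 1 < params$min_snp) next
      if (bp[j] - bp[i] < params$min_length_bp) next
      feasible[i, j] <- TRUE
    }
  }
  keep <- which(feasible, arr.ind = TRUE)
  if (!nrow(keep)) return(data.frame(start = integer(0), end = integer(0)))
  maximal <- vapply(seq_len(nrow(keep)), function(r) {
    i <- keep[r, 1]
    j <- keep[r, 2]
    !any(keep[, 1] <= i & keep[, 2] >= j &
           !(keep[, 1] == i & keep[, 2] == j))
  }, logical(1))
  out <- data.frame(start = as.integer(keep[maximal, 1]),
                    end = as.integer(keep[maximal, 2]))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quantile-then-group island oracle on a single-chromosome profile.
brute_force_islands <- function(freq, top_percentile = 0.1, min_snp = 2) {
  thr <- unname(quantile(freq, 1 - top_percentile / 100, type = 7))
  if (thr <= 0) return(data.frame(start = integer(0), end = integer(0)))
  pass <- which(freq >= thr & freq > 0)
  if (!length(pass)) return(data.frame(start = integer(0), end = integer(0)))
  grp <- cumsum(c(1, diff(pass) != 1))
  out <- do.call(rbind, lapply(split(pass, grp), function(ix) {
    data.frame(start = min(ix), end = max(ix))
  }))
  out <- out[out$end - out$start + 1 >= min_snp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs pairwise-difference pi for one site: expand to pseudo
# haplotypes (x alt alleles among n) and count differing pairs.
pairwise_pi_site <- function(x, n) {
  hap <- c(rep(1, x), rep(0, n - x))
  diff_sum <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) diff_sum <- diff_sum + (hap[a] != hap[b])
  }
  diff_sum / choose(n, 2)
}

# Exhaustive-path log-likelihood of the HBD HMM (K^T paths).
hmm_path_oracle <- function(emis, d, rates, mix) {
  T_ <- nrow(emis)
  S <- ncol(emis)
  trans <- lapply(d, function(dd) {
    q <- exp(-rates * dd)
    diag(q) + (1 - q) %o% mix
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    pr <- mix[s[1]] * emis[1, s[1]]
    if (T_ > 1) for (t in 2:T_) pr <- pr * trans[[t - 1]][s[t - 1], s[t]] *
        emis[t, s[t]]
    tot <- tot + pr
  }
  log(tot)
}

# detect_runs on a single-individual genotype vector, returned as marker
# index pairs for comparison with brute_force_runs.
scan_one <- function(calls, bp, params) {
  g <- make_genotypes(calls, bp = bp)
  runs <- detect_runs(g, params)
  if (!nrow(runs)) return(data.frame(start = integer(0), end = integer(0)))
  out <- data.frame(start = match(runs$start_bp, bp),
                    end = match(runs$end_bp, bp))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
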