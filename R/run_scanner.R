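# Consecutive-runs detection of heterozygosity-rich regions (HRRs) and,
# as a utility, consecutive-mode runs of homozygosity (ROH).
#
# A candidate interval of consecutive markers [i..j] on one chromosome of
# one individual is *feasible* when all six clauses hold:
#   (a) markers i and j are target-state (het for HRR, hom for ROH) and
#       non-missing,
#   (b) at most max_opposite opposite-state calls inside,
#   (c) at most max_missing missing calls inside,
#   (d) every adjacent-marker gap inside is <= max_gap_bp,
#   (e) at least min_snp markers,
#   (f) bp(j) - bp(i) >= min_length_bp.
# The scanner emits exactly the inclusion-maximal feasible intervals;
# they may overlap.

#' Parameters for consecutive-runs detection
#'
#' Defaults are the standard HRR settings (20 SNPs, 50 kb minimum length,
#' 50 kb maximum gap, up to 3 homozygous and 1 missing call allowed). The
#' `"ROH"` type flips the target state to homozygous with defaults
#' `max_opposite = 1`, `max_missing = 2`.
#'
#' @param run_type `"HRR"` or `"ROH"`.
#' @param min_snp Minimum markers per run.
#' @param min_length_bp Minimum run length, `bp(last) - bp(first)`.
#' @param max_gap_bp Maximum adjacent-marker gap inside a run.
#' @param max_opposite Maximum opposite-state calls allowed inside a run.
#' @param max_missing Maximum missing calls allowed inside a run.
#' @return A list of class `run_params`.
#' @export
run_params <- function(run_type = c("HRR", "ROH"), min_snp = 20,
                       min_length_bp = 50000, max_gap_bp = 50000,
                       max_opposite = if (run_type == "HRR") 3 else 1,
                       max_missing = if (run_type == "HRR") 1 else 2) {
  run_type <- match.arg(run_type)
  stopifnot(min_snp >= 1, min_length_bp > 0, max_gap_bp > 0,
            max_opposite >= 0, max_missing >= 0)
  structure(list(run_type = run_type, min_snp = as.integer(min_snp),
                 min_length_bp = as.numeric(min_length_bp),
                 max_gap_bp = as.numeric(max_gap_bp),
                 max_opposite = as.integer(max_opposite),
                 max_missing = as.integer(max_missing)),
            class = "run_params")
}

#' Detect runs (HRR or consecutive-mode ROH) per individual
#'
#' Scans every individual and chromosome and returns all inclusion-maximal
#' feasible intervals under `params` (see the feasibility clauses in the
#' package source / vignette). Output intervals may overlap; the per-SNP
#' coverage consumed by island calling is their union.
#'
#' @param g A [genotypes()] object with a position-sorted map.
#' @param params A [run_params()] object.
#' @return data.frame with columns `sample_id`, `breed`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snp`, `n_opposite`, `n_missing`, `run_type`.
#' @export
detect_runs <- function(g, params = run_params("HRR")) {
  stopifnot(inherits(params, "run_params"))
  ord <- order(chrom_order(g$map$chrom), g$map$bp)
  if (!identical(ord, seq_len(nrow(g$map))))
    stop("marker map is not sorted by (chrom, bp)")
  chroms <- unique(g$map$chrom)
  out <- vector("list", nrow(g$samples) * length(chroms))
  idx <- 0L
  for (ch in chroms) {
    sel <- which(g$map$chrom == ch)
    bp <- g$map$bp[sel]
    # gap clause (d): blocks of markers never separated by > max_gap_bp
    block <- cumsum(c(0, diff(bp) > params$max_gap_bp))
    for (i in seq_len(nrow(g$samples))) {
      calls <- g$calls[i, sel]
      runs <- scan_chromosome(calls, bp, block, params)
      if (!is.null(runs)) {
        idx <- idx + 1L
        runs$sample_id <- g$samples$sample_id[i]
        runs$breed <- g$samples$breed[i]
        runs$chrom <- ch
        out[[idx]] <- runs
      }
    }
  }
  cols <- c("sample_id", "breed", "chrom", "start_bp", "end_bp",
            "n_snp", "n_opposite", "n_missing", "run_type")
  if (idx == 0L) {
    res <- data.frame(sample_id = character(0), breed = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snp = integer(0),
                      n_opposite = integer(0), n_missing = integer(0),
                      run_type = character(0))
    return(res)
  }
  res <- do.call(rbind, out[seq_len(idx)])
  res$run_type <- params$run_type
  rownames(res) <- NULL
  res[, cols]
}

# One individual x one chromosome. States: 2 target, 1 opposite, 0 missing.
# Two-pointer sweep per gap block: for each valid start i the farthest
# budget-feasible end e(i) is non-decreasing in i, so inclusion-maximal
# intervals are the candidates [i, e(i)] deduplicated on e.
scan_chromosome <- function(calls, bp, block, params) {
  state <- integer(length(calls))
  if (params$run_type == "HRR") {
    state[!is.na(calls) & calls == 1L] <- 2L
    state[!is.na(calls) & calls != 1L] <- 1L
  } else {
    state[!is.na(calls) & calls != 1L] <- 2L
    state[!is.na(calls) & calls == 1L] <- 1L
  }
  res <- list()
  for (b in unique(block)) {
    rng <- which(block == b)
    st <- state[rng]
    pos <- bp[rng]
    m <- length(rng)
    j <- 0L
    n_opp <- 0L
    n_mis <- 0L
    last_e <- -1L
    # last target index <= t within the block
    lt <- cummax(ifelse(st == 2L, seq_len(m), 0L))
    for (s in seq_len(m)) {
      if (s > 1L) {  # drop marker s-1 from the window
        if (j >= s - 1L) {
          if (st[s - 1L] == 1L) n_opp <- n_opp - 1L
          if (st[s - 1L] == 0L) n_mis <- n_mis - 1L
        } else {
          j <- s - 1L
          n_opp <- 0L
          n_mis <- 0L
        }
      }
      if (st[s] != 2L) next
      while (j < m) {
        nxt <- st[j + 1L]
        if (j + 1L > s) {  # markers before the start never count
          if (nxt == 1L && n_opp + 1L > params$max_opposite) break
          if (nxt == 0L && n_mis + 1L > params$max_missing) break
        }
        j <- j + 1L
        if (j > s) {
          if (nxt == 1L) n_opp <- n_opp + 1L
          if (nxt == 0L) n_mis <- n_mis + 1L
        }
      }
      e <- lt[max(j, s)]
      if (e < s) next
      if (e == last_e) next  # contained in an earlier candidate
      last_e <- e
      n_snp <- e - s + 1L
      if (n_snp < params$min_snp) next
      if (pos[e] - pos[s] < params$min_length_bp) next
      counts <- c(sum(st[s:e] == 1L), sum(st[s:e] == 0L))
      res[[length(res) + 1L]] <-
        data.frame(start_bp = pos[s], end_bp = pos[e], n_snp = n_snp,
                   n_opposite = counts[1], n_missing = counts[2])
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Per-individual run summaries and observed heterozygosity
#'
#' For every individual of `g` (including those without runs) reports the
#' run count, the union length of its runs, that union as a fraction of the
#' mapped genome (sum over chromosomes of last minus first marker
#' position), and observed heterozygosity `Ho` (heterozygous calls over
#' non-missing calls).
#'
#' @param runs data.frame from [detect_runs()].
#' @param g The [genotypes()] object the runs came from.
#' @return data.frame with columns `sample_id`, `breed`, `n_runs`,
#'   `coverage_bp`, `coverage_fraction`, `ho`.
#' @export
summarize_runs <- function(runs, g) {
  genome_bp <- sum(tapply(g$map$bp, g$map$chrom, function(x) max(x) - min(x)))
  het <- rowSums(g$calls == 1L, na.rm = TRUE)
  called <- rowSums(!is.na(g$calls))
  cov <- setNames(numeric(nrow(g$samples)), g$samples$sample_id)
  nr <- setNames(integer(nrow(g$samples)), g$samples$sample_id)
  if (nrow(runs)) {
    for (key in unique(paste(runs$sample_id, runs$chrom, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- runs[runs$sample_id == parts[1] & runs$chrom == parts[2], ]
      cov[parts[1]] <- cov[parts[1]] + union_length(sub$start_bp, sub$end_bp)
    }
    tab <- table(runs$sample_id)
    nr[names(tab)] <- as.integer(tab)
  }
  data.frame(sample_id = g$samples$sample_id, breed = g$samples$breed,
             n_runs = as.integer(nr), coverage_bp = as.numeric(cov),
             coverage_fraction = as.numeric(cov) / genome_bp,
             ho = het / called, row.names = NULL)
}

# Length of the union of [start, end] intervals under the end-minus-start
# convention: sum of (end - start) over merged components.
union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  tot <- 0
  cs <- start[1]
  ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) {
      ce <- max(ce, end[i])
    } else {
      tot <- tot + (ce - cs)
      cs <- start[i]
      ce <- end[i]
    }
  }
  tot + (ce - cs)
}

#' Merge overlapping runs per individual
#'
#' Consolidates the inclusion-maximal intervals emitted by [detect_runs()]
#' into their per-individual union: overlapping runs of one individual on
#' one chromosome become a single segment. This is the natural unit for
#' tract-level recovery scoring and per-individual coverage.
#'
#' @param runs data.frame from [detect_runs()] or [hbd_segments()].
#' @return data.frame with `sample_id`, `breed`, `chrom`, `start_bp`,
#'   `end_bp`, `n_runs_merged`, `run_type`.
#' @export
merge_runs <- function(runs) {
  if (!nrow(runs))
    return(data.frame(sample_id = character(0), breed = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_runs_merged = integer(0),
                      run_type = character(0)))
  key <- paste(runs$sample_id, runs$chrom, runs$run_type, sep = "\r")
  out <- lapply(split(runs, key), function(s) {
    s <- s[order(s$start_bp), , drop = FALSE]
    res <- data.frame(sample_id = s$sample_id[1], breed = s$breed[1],
                      chrom = s$chrom[1], start_bp = s$start_bp[1],
                      end_bp = s$end_bp[1], n_runs_merged = 1L,
                      run_type = s$run_type[1])
    for (i in seq_len(nrow(s))[-1]) {
      j <- nrow(res)
      if (s$start_bp[i] <= res$end_bp[j]) {
        res$end_bp[j] <- max(res$end_bp[j], s$end_bp[i])
        res$n_runs_merged[j] <- res$n_runs_merged[j] + 1L
      } else {
        res <- rbind(res, data.frame(sample_id = s$sample_id[i],
                                     breed = s$breed[i], chrom = s$chrom[i],
                                     start_bp = s$start_bp[i],
                                     end_bp = s$end_bp[i],
                                     n_runs_merged = 1L,
                                     run_type = s$run_type[i]))
      }
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, chrom_order(res$chrom), res$start_bp), ]
}

#' Pearson correlation with t-test
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @param pair Optional label for the variable pair.
#' @return One-row data.frame with `pair`, `r`, `r_squared`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y, pair = "x~y") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: zero variance in ", pair)
  ct <- cor.test(x, y, method = "pearson")
  data.frame(pair = pair, r = unname(ct$estimate),
             r_squared = unname(ct$estimate)^2,
             p = ct$p.value, n = length(x))
}
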