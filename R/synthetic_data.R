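# Seeded multi-breed genotype simulator. Breeds diverge from ancestral
# allele frequencies under a Balding-Nichols model; background genotypes
# are Hardy-Weinberg draws at the breed frequencies (no linkage
# disequilibrium). Three feature kinds can be planted: heterozygous
# tracts (HRR truth), autozygous tracts (ROH truth) and
# balancing-selection windows (intermediate frequencies with heterozygote
# excess, applied to every breed).

#' Simulation configuration
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param n_breeds Number of breeds (default 3).
#' @param individuals_per_breed Individuals per breed (default 20).
#' @param chrom_lengths_bp Chromosome lengths in bp (default two 25 Mb
#'   chromosomes).
#' @param snp_spacing_bp Regular marker spacing (default 15000).
#' @param breed_divergence Balding-Nichols F (default 0.10).
#' @param missing_rate Uniform missing-call rate (default 0.02).
#' @param features data.frame of planted features with columns `kind`
#'   (`"HRR_TRACT"`, `"ROH_TRACT"` or `"BALANCING_WINDOW"`), `breed`
#'   (index, ignored for balancing windows), `chrom` (index), `start_bp`,
#'   `end_bp`, `carrier_fraction`, `intensity`. `intensity` is the
#'   per-SNP heterozygote probability for HRR tracts (default 0.95) and
#'   the heterozygote inflation factor for balancing windows (default
#'   1.3).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_breeds = 3, individuals_per_breed = 20,
                       chrom_lengths_bp = c(25e6, 25e6),
                       snp_spacing_bp = 15000, breed_divergence = 0.10,
                       missing_rate = 0.02, features = NULL) {
  stopifnot(n_breeds >= 1, individuals_per_breed >= 1,
            all(chrom_lengths_bp >= snp_spacing_bp), snp_spacing_bp >= 1,
            breed_divergence >= 0, breed_divergence < 1,
            missing_rate >= 0, missing_rate <= 1)
  if (is.null(features))
    features <- data.frame(kind = character(0), breed = integer(0),
                           chrom = integer(0), start_bp = numeric(0),
                           end_bp = numeric(0),
                           carrier_fraction = numeric(0),
                           intensity = numeric(0))
  stopifnot(all(features$kind %in%
                  c("HRR_TRACT", "ROH_TRACT", "BALANCING_WINDOW")),
            all(features$chrom >= 1),
            all(features$chrom <= length(chrom_lengths_bp)),
            all(features$start_bp >= 1),
            all(features$end_bp <= chrom_lengths_bp[features$chrom]),
            all(features$start_bp <= features$end_bp),
            all(features$carrier_fraction >= 0),
            all(features$carrier_fraction <= 1))
  structure(list(seed = as.integer(seed), n_breeds = as.integer(n_breeds),
                 individuals_per_breed = as.integer(individuals_per_breed),
                 chrom_lengths_bp = as.numeric(chrom_lengths_bp),
                 snp_spacing_bp = as.numeric(snp_spacing_bp),
                 breed_divergence = as.numeric(breed_divergence),
                 missing_rate = as.numeric(missing_rate),
                 features = features),
            class = "sim_config")
}

#' Default simulation: planted heterozygous tracts
#'
#' Three breeds of 20 on two 25 Mb chromosomes with ten 600 kb
#' heterozygous tracts at carrier fraction 0.8, distributed round-robin
#' over breeds and spread along both chromosomes.
#'
#' @param seed RNG seed (default 42).
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 42) {
  k <- 10
  feats <- data.frame(
    kind = "HRR_TRACT",
    breed = rep_len(1:3, k),
    chrom = rep_len(1:2, k),
    start_bp = rep(seq(2e6, 22e6, length.out = 5), each = 2),
    carrier_fraction = 0.8,
    intensity = 0.95)
  feats$end_bp <- feats$start_bp + 6e5
  sim_config(seed, features = feats[, c("kind", "breed", "chrom",
                                        "start_bp", "end_bp",
                                        "carrier_fraction", "intensity")])
}

#' Simulate a multi-breed SNP dataset with planted features
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [genotypes()] object) and `truth`
#'   (data.frame of planted features with breed labels, intervals and
#'   comma-separated carrier ids; balancing windows carry `breed = "*"`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(config$seed)

  n_chr <- length(config$chrom_lengths_bp)
  map <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
    bp <- seq(config$snp_spacing_bp, config$chrom_lengths_bp[c],
              by = config$snp_spacing_bp)
    data.frame(marker_id = sprintf("snp_%d_%d", c, bp),
               chrom = as.character(c), bp = bp,
               allele_a = "A", allele_b = "B")
  }))
  m <- nrow(map)
  feats <- config$features
  # SNP index sets per feature; different kinds may not share SNPs
  fidx <- lapply(seq_len(nrow(feats)), function(i) {
    which(map$chrom == as.character(feats$chrom[i]) &
            map$bp >= feats$start_bp[i] & map$bp <= feats$end_bp[i])
  })
  if (nrow(feats) >= 2) {
    owner <- rep(NA_character_, m)
    for (i in seq_len(nrow(feats))) {
      clash <- !is.na(owner[fidx[[i]]]) & owner[fidx[[i]]] != feats$kind[i]
      if (any(clash))
        stop("planted features of different kinds overlap on the same SNPs")
      owner[fidx[[i]]] <- feats$kind[i]
    }
  }

  anc <- runif(m, 0.05, 0.95)
  fdiv <- config$breed_divergence
  nb <- config$n_breeds
  nind <- config$individuals_per_breed
  breed_names <- sprintf("B%02d", seq_len(nb))
  breed_p <- matrix(NA_real_, nb, m)
  for (b in seq_len(nb)) {
    breed_p[b, ] <- if (fdiv == 0) anc else
      rbeta(m, anc * (1 - fdiv) / fdiv, (1 - anc) * (1 - fdiv) / fdiv)
  }
  # keep emissions and HWE draws away from exact fixation
  breed_p <- pmin(pmax(breed_p, 1e-4), 1 - 1e-4)

  # balancing windows override frequencies in every breed
  bal <- which(feats$kind == "BALANCING_WINDOW")
  for (i in bal) {
    pw <- runif(length(fidx[[i]]), 0.4, 0.6)
    for (b in seq_len(nb)) breed_p[b, fidx[[i]]] <- pw
  }

  calls <- matrix(NA_integer_, nb * nind, m)
  samples <- data.frame(
    sample_id = as.vector(vapply(breed_names, function(b)
      sprintf("%s_I%02d", b, seq_len(nind)), character(nind))),
    breed = rep(breed_names, each = nind))
  truth <- list()

  for (b in seq_len(nb)) {
    rows <- (b - 1) * nind + seq_len(nind)
    p <- breed_p[b, ]
    gb <- matrix(rbinom(nind * m, 2, rep(p, each = nind)), nind, m)
    # heterozygote excess in balancing windows
    for (i in bal) {
      ix <- fidx[[i]]
      pr0 <- (1 - p[ix])^2
      pr1 <- 2 * p[ix] * (1 - p[ix]) * feats$intensity[i]
      pr2 <- p[ix]^2
      tot <- pr0 + pr1 + pr2
      for (j in seq_along(ix)) {
        gb[, ix[j]] <- sample(0:2, nind, replace = TRUE,
                              prob = c(pr0[j], pr1[j], pr2[j]) / tot[j])
      }
    }
    for (i in which(feats$kind != "BALANCING_WINDOW" & feats$breed == b)) {
      ix <- fidx[[i]]
      ncar <- round(feats$carrier_fraction[i] * nind)
      if (ncar == 0 || !length(ix)) next
      car <- sort(sample(seq_len(nind), ncar))
      if (feats$kind[i] == "HRR_TRACT") {
        for (ci in car) {
          het <- runif(length(ix)) < feats$intensity[i]
          hwe <- rbinom(length(ix), 2, p[ix])
          gb[ci, ix] <- ifelse(het, 1L, hwe)
        }
      } else {  # ROH_TRACT
        for (ci in car) {
          hom <- 2L * rbinom(length(ix), 1, p[ix])
          err <- runif(length(ix)) < 0.01
          hwe <- rbinom(length(ix), 2, p[ix])
          gb[ci, ix] <- ifelse(err, hwe, hom)
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        kind = feats$kind[i], breed = breed_names[b],
        chrom = as.character(feats$chrom[i]),
        start_bp = feats$start_bp[i], end_bp = feats$end_bp[i],
        carriers = paste(samples$sample_id[rows[car]], collapse = ","))
    }
    calls[rows, ] <- gb
  }
  for (i in bal) {
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "BALANCING_WINDOW", breed = "*",
      chrom = as.character(feats$chrom[i]),
      start_bp = feats$start_bp[i], end_bp = feats$end_bp[i],
      carriers = NA_character_)
  }
  if (config$missing_rate > 0) {
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(0), breed = character(0),
               chrom = character(0), start_bp = numeric(0),
               end_bp = numeric(0), carriers = character(0))
  rownames(truth) <- NULL
  list(genotypes = genotypes(samples, map, calls), truth = truth,
       breed_freqs = breed_p, ancestral_freqs = anc)
}

#' Expand truth records to per-carrier intervals
#'
#' One row per (feature, carrier) pair, for run-level recovery scoring.
#'
#' @param truth Truth table from [simulate_dataset()].
#' @param kind Feature kind to expand (default `"HRR_TRACT"`).
#' @return data.frame with `sample_id`, `chrom`, `start_bp`, `end_bp`.
#' @export
expand_truth_carriers <- function(truth, kind = "HRR_TRACT") {
  sub <- truth[truth$kind == kind & !is.na(truth$carriers), , drop = FALSE]
  out <- lapply(seq_len(nrow(sub)), function(i) {
    data.frame(sample_id = strsplit(sub$carriers[i], ",")[[1]],
               chrom = sub$chrom[i], start_bp = sub$start_bp[i],
               end_bp = sub$end_bp[i])
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0))
  res
}

#' Precision/recall/F1 of detected intervals against planted truth
#'
#' A detected interval matches a truth interval when their intersection is
#' at least `min_reciprocal_overlap` times each one's length (and, when
#' both tables carry a `sample_id` column, the individual matches too).
#' Matching is greedy one-to-one by descending overlap.
#'
#' @param detected data.frame with `chrom`, `start_bp`, `end_bp` and
#'   optionally `sample_id`.
#' @param truth data.frame in the same shape.
#' @param min_reciprocal_overlap Reciprocal-overlap threshold
#'   (default 0.5).
#' @return One-row data.frame with `n_detected`, `n_truth`, `n_matched`,
#'   `precision`, `recall`, `f1` (`NA` where undefined).
#' @export
score_recovery <- function(detected, truth, min_reciprocal_overlap = 0.5) {
  by_sample <- "sample_id" %in% names(detected) &&
    "sample_id" %in% names(truth)
  nd <- nrow(detected)
  nt <- nrow(truth)
  pairs <- NULL
  if (nd && nt) {
    cand <- list()
    for (i in seq_len(nd)) {
      sel <- truth$chrom == detected$chrom[i]
      if (by_sample) sel <- sel & truth$sample_id == detected$sample_id[i]
      tj <- which(sel)
      if (!length(tj)) next
      ov <- pmin(truth$end_bp[tj], detected$end_bp[i]) -
        pmax(truth$start_bp[tj], detected$start_bp[i]) + 1
      len_d <- detected$end_bp[i] - detected$start_bp[i] + 1
      len_t <- truth$end_bp[tj] - truth$start_bp[tj] + 1
      good <- ov >= min_reciprocal_overlap * len_d &
        ov >= min_reciprocal_overlap * len_t
      if (any(good))
        cand[[length(cand) + 1L]] <-
          data.frame(d = i, t = tj[good], ov = ov[good])
    }
    if (length(cand)) pairs <- do.call(rbind, cand)
  }
  matched <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$ov), , drop = FALSE]
    used_d <- logical(nd)
    used_t <- logical(nt)
    for (k in seq_len(nrow(pairs))) {
      if (!used_d[pairs$d[k]] && !used_t[pairs$t[k]]) {
        used_d[pairs$d[k]] <- TRUE
        used_t[pairs$t[k]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  precision <- if (nd) matched / nd else NA_real_
  recall <- if (nt) matched / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(n_detected = nd, n_truth = nt, n_matched = matched,
             precision = precision, recall = recall, f1 = f1)
}
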