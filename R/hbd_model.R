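# Model-based ROH calling: a hidden Markov model with several
# homozygous-by-descent (HBD) classes of increasing rate and one non-HBD
# class. Rates govern the exponential length scale of segments (higher
# rate, shorter and older segments); mixing proportions are estimated per
# individual by EM with the rates held fixed.

#' Specification of the HBD hidden Markov model
#'
#' @param hbd_rates Rates of the HBD classes, strictly increasing
#'   (default `c(2, 4, 8, 16, 32, 64)`).
#' @param non_hbd_rate Rate of the single non-HBD class (default 128).
#' @param mixing Mixing proportions over all `K + 1` states (HBD classes
#'   first, non-HBD last); default uniform.
#' @param error_rate Genotyping-error contamination `eps` of the HBD
#'   emission toward Hardy-Weinberg (default 0.001).
#' @param morgans_per_bp Genetic map scale (default 1e-8, i.e. 1 cM/Mb).
#' @return A list of class `hbd_model_spec`.
#' @export
hbd_model_spec <- function(hbd_rates = c(2, 4, 8, 16, 32, 64),
                           non_hbd_rate = 128, mixing = NULL,
                           error_rate = 0.001, morgans_per_bp = 1e-8) {
  stopifnot(all(hbd_rates > 0), !is.unsorted(hbd_rates, strictly = TRUE),
            non_hbd_rate > 0, error_rate >= 0, error_rate < 0.5,
            morgans_per_bp > 0)
  ns <- length(hbd_rates) + 1L
  if (is.null(mixing)) mixing <- rep(1 / ns, ns)
  stopifnot(length(mixing) == ns, all(mixing >= 0),
            abs(sum(mixing) - 1) < 1e-8)
  structure(list(hbd_rates = as.numeric(hbd_rates),
                 non_hbd_rate = as.numeric(non_hbd_rate),
                 mixing = as.numeric(mixing),
                 error_rate = as.numeric(error_rate),
                 morgans_per_bp = as.numeric(morgans_per_bp),
                 n_states = ns),
            class = "hbd_model_spec")
}

#' Per-state emission probabilities for one genotype
#'
#' HBD classes emit a homozygote for an allele drawn at the population
#' frequency, contaminated toward Hardy-Weinberg proportions with
#' probability `error_rate`; the non-HBD class emits Hardy-Weinberg
#' genotypes. A missing genotype emits 1 in every state.
#'
#' @param genotype Code 0/1/2 or `NA`.
#' @param p Alternate-allele (code-2) frequency, in `(0, 1)` for a called
#'   genotype.
#' @param spec An [hbd_model_spec()].
#' @return Numeric vector of length `n_states` (HBD classes first).
#' @export
emission_probabilities <- function(genotype, p, spec) {
  if (is.na(genotype)) return(rep(1, spec$n_states))
  if (!(p > 0 && p < 1))
    stop("allele frequency must lie in (0, 1) for a called genotype")
  eps <- spec$error_rate
  e_hbd <- switch(as.character(genotype),
    "0" = (1 - eps) * (1 - p) + eps * (1 - p)^2,
    "1" = eps * 2 * p * (1 - p),
    "2" = (1 - eps) * p + eps * p^2,
    stop("genotype code must be 0, 1, 2 or NA"))
  e_non <- switch(as.character(genotype),
    "0" = (1 - p)^2, "1" = 2 * p * (1 - p), "2" = p^2)
  c(rep(e_hbd, spec$n_states - 1L), e_non)
}

# Emission matrix for a marker sequence (rows markers, cols states).
emission_matrix <- function(genotypes, freqs, spec) {
  t(vapply(seq_along(genotypes),
           function(i) emission_probabilities(genotypes[i], freqs[i], spec),
           numeric(spec$n_states)))
}

#' Exact HBD posterior by scaled forward-backward
#'
#' Runs the forward-backward algorithm for one individual on one
#' chromosome. Transitions between adjacent markers at genetic distance
#' `d = delta_bp * morgans_per_bp` follow
#' `T(k,l) = exp(-R_k d) 1[k=l] + (1 - exp(-R_k d)) pi_l`.
#'
#' @param genotypes Integer codes 0/1/2/`NA` for consecutive markers.
#' @param freqs Population (breed) alternate-allele frequencies, in (0, 1).
#' @param positions Physical positions (bp), sorted increasing.
#' @param spec An [hbd_model_spec()].
#' @return A list of class `hbd_posterior` with `gamma` (markers x states
#'   posterior matrix), `hbd_prob` (per-marker summed HBD posterior),
#'   `loglik`, and `pi_draws` (expected per-state counts of draws from the
#'   mixing distribution, the EM sufficient statistic).
#' @export
forward_backward <- function(genotypes, freqs, positions, spec) {
  stopifnot(length(genotypes) >= 1,
            length(freqs) == length(genotypes),
            length(positions) == length(genotypes),
            !is.unsorted(positions))
  emis <- emission_matrix(genotypes, freqs, spec)
  rates <- c(spec$hbd_rates, spec$non_hbd_rate)
  if (length(genotypes) == 1L) {
    a <- spec$mixing * emis[1, ]
    ll <- log(sum(a))
    gamma <- matrix(a / sum(a), 1)
    reset <- numeric(spec$n_states)
  } else {
    d <- diff(positions) * spec$morgans_per_bp
    fb <- .hbd_forward_backward_cpp(emis, d, rates, spec$mixing)
    gamma <- fb$gamma
    ll <- fb$loglik
    reset <- fb$reset
  }
  structure(list(gamma = gamma,
                 hbd_prob = rowSums(gamma[, -spec$n_states, drop = FALSE]),
                 loglik = ll,
                 pi_draws = gamma[1, ] + reset),
            class = "hbd_posterior")
}

#' Fit per-individual mixing proportions by EM
#'
#' Starting from uniform mixing, iterates E-steps (forward-backward over
#' all chromosomes of the individual) and exact M-steps until the
#' log-likelihood improves by less than `tol` or `max_iter` is reached.
#' The transition kernel is a mixture of "stay" (probability
#' `exp(-R_k d)`) and "re-draw the state from pi", so the M-step is the
#' closed-form `pi_k proportional to` expected number of draws from `pi`
#' landing in state `k` (first marker plus re-draw transitions); the
#' log-likelihood is therefore non-decreasing. Rates are fixed.
#'
#' @param g A [genotypes()] object holding one breed (frequencies are
#'   computed from it); all its samples are fitted.
#' @param spec An [hbd_model_spec()]; its mixing is the EM start point.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200); 0 returns the
#'   starting mixing unchanged.
#' @return Named list (by sample_id) of lists with `spec` (fitted),
#'   `loglik_trace` and `hbd_mixing` (summed HBD mixing).
#' @export
fit_mixing_em <- function(g, spec = hbd_model_spec(), tol = 1e-6,
                          max_iter = 200) {
  freqs <- shrunk_alt_freqs(g)
  chroms <- unique(g$map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(g$map$chrom == ch))
  out <- list()
  for (i in seq_len(nrow(g$samples))) {
    mix <- spec$mixing
    trace <- numeric(0)
    iter <- 0L
    repeat {
      cur <- spec
      cur$mixing <- mix
      ll <- 0
      occ <- numeric(spec$n_states)
      for (ci in chrom_idx) {
        fb <- forward_backward(g$calls[i, ci], freqs[ci], g$map$bp[ci], cur)
        ll <- ll + fb$loglik
        occ <- occ + fb$pi_draws
      }
      if (!is.finite(ll)) stop("non-finite HBD likelihood for sample ",
                               g$samples$sample_id[i])
      trace <- c(trace, ll)
      if (iter >= max_iter) break
      if (length(trace) > 1 &&
          abs(trace[length(trace)] - trace[length(trace) - 1]) < tol) break
      mix <- occ / sum(occ)
      iter <- iter + 1L
    }
    fitted <- spec
    fitted$mixing <- mix
    out[[g$samples$sample_id[i]]] <-
      list(spec = fitted, loglik_trace = trace,
           hbd_mixing = sum(mix[-spec$n_states]))
  }
  out
}

# Breed allele frequencies with a half-count shrink so monomorphic markers
# keep emissions strictly inside (0, 1).
shrunk_alt_freqs <- function(g) {
  x <- colSums(g$calls, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(g$calls))
  (x + 0.5) / (n2 + 1)
}

#' Call HBD segments from a posterior
#'
#' Maximal stretches of consecutive markers whose summed HBD posterior is
#' at least `threshold` become ROH segments.
#'
#' @param posterior An `hbd_posterior` from [forward_backward()].
#' @param positions Marker positions matching the posterior rows.
#' @param threshold Posterior threshold (default 0.5).
#' @return data.frame with `start_bp`, `end_bp`, `n_snp`, `mean_hbd_prob`.
#' @export
call_hbd_segments <- function(posterior, positions, threshold = 0.5) {
  stopifnot(inherits(posterior, "hbd_posterior"),
            length(positions) == length(posterior$hbd_prob))
  hot <- posterior$hbd_prob >= threshold
  if (!any(hot))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snp = integer(0), mean_hbd_prob = numeric(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_bp = positions[starts[keep]],
             end_bp = positions[ends[keep]],
             n_snp = ends[keep] - starts[keep] + 1L,
             mean_hbd_prob = vapply(keep, function(k) {
               mean(posterior$hbd_prob[starts[k]:ends[k]])
             }, numeric(1)))
}

#' Model-based ROH segments for every individual
#'
#' Convenience wrapper: per breed, fits mixing by EM, computes posteriors
#' and extracts HBD segments in the same schema as [detect_runs()].
#'
#' @param g A [genotypes()] object (QC1 tier).
#' @param spec An [hbd_model_spec()].
#' @param threshold Posterior threshold for segment calls (default 0.5).
#' @param tol,max_iter EM controls passed to [fit_mixing_em()].
#' @return data.frame in the [detect_runs()] schema with
#'   `run_type = "ROH"` (`n_opposite` and `n_missing` are 0 by convention).
#' @export
hbd_segments <- function(g, spec = hbd_model_spec(), threshold = 0.5,
                         tol = 1e-6, max_iter = 200) {
  out <- list()
  for (b in unique(g$samples$breed)) {
    gb <- subset_genotypes(g, samples = g$samples$sample_id[
      g$samples$breed == b])
    freqs <- shrunk_alt_freqs(gb)
    fits <- fit_mixing_em(gb, spec, tol = tol, max_iter = max_iter)
    for (sid in names(fits)) {
      i <- match(sid, gb$samples$sample_id)
      for (ch in unique(gb$map$chrom)) {
        ci <- which(gb$map$chrom == ch)
        fb <- forward_backward(gb$calls[i, ci], freqs[ci], gb$map$bp[ci],
                               fits[[sid]]$spec)
        seg <- call_hbd_segments(fb, gb$map$bp[ci], threshold)
        if (nrow(seg))
          out[[length(out) + 1L]] <-
            data.frame(sample_id = sid, breed = b, chrom = ch,
                       start_bp = seg$start_bp, end_bp = seg$end_bp,
                       n_snp = seg$n_snp, n_opposite = 0L, n_missing = 0L,
                       run_type = "ROH")
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), breed = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snp = integer(0),
                      n_opposite = integer(0), n_missing = integer(0),
                      run_type = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
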