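spec3 <- hbd_model_spec(hbd_rates = c(4, 16), non_hbd_rate = 64)

test_that("emission probabilities follow the contaminated-HBD model", {
  s <- hbd_model_spec(error_rate = 0)
  expect_equal(emission_probabilities(0L, 0.5, s),
               c(rep(0.5, 6), 0.25))
  expect_equal(emission_probabilities(1L, 0.5, s)[1:6], rep(0, 6))
  s2 <- hbd_model_spec(error_rate = 0.001)
  expect_equal(emission_probabilities(1L, 0.3, s2)[1],
               0.001 * 2 * 0.3 * 0.7)  # 0.00042
  # per state, probabilities over genotypes 0/1/2 sum to 1
  for (p in c(0.1, 0.37, 0.8)) {
    tot <- emission_probabilities(0L, p, s2) +
      emission_probabilities(1L, p, s2) +
      emission_probabilities(2L, p, s2)
    expect_equal(tot, rep(1, 7))
  }
  expect_equal(emission_probabilities(NA, 0.5, s2), rep(1, 7))
  expect_error(emission_probabilities(0L, 0, s2), "frequency")
})

test_that("transition rows sum to one for any distance and rates", {
  rates <- c(2, 4, 8, 16, 32, 64, 128)
  mix <- rep(1 / 7, 7)
  for (d in c(1e-8, 1e-4, 0.01, 1, 100)) {
    q <- exp(-rates * d)
    trans <- diag(q) + (1 - q) %o% mix
    expect_equal(rowSums(trans), rep(1, 7))
  }
})

test_that("a single marker posterior is the mixing-weighted emission", {
  set.seed(51)
  p <- 0.4
  fb <- forward_backward(2L, p, 1e6, spec3)
  e <- emission_probabilities(2L, p, spec3)
  expect_equal(as.numeric(fb$gamma), spec3$mixing * e / sum(spec3$mixing * e))
  expect_equal(fb$loglik, log(sum(spec3$mixing * e)))
})

test_that("forward-backward equals exhaustive path summation", {
  set.seed(52)
  for (rep in 1:10) {
    T_ <- 6
    g <- sample(c(0L, 1L, 2L, NA), T_, replace = TRUE)
    p <- runif(T_, 0.15, 0.85)
    pos <- cumsum(sample(2e4:2e6, T_, replace = TRUE))
    fb <- forward_backward(g, p, pos, spec3)
    emis <- t(sapply(seq_len(T_), function(i)
      emission_probabilities(g[i], p[i], spec3)))
    ll <- hmm_path_oracle(emis, diff(pos) * spec3$morgans_per_bp,
                          c(4, 16, 64), spec3$mixing)
    expect_lt(abs(fb$loglik - ll), 1e-8)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-9))
  }
})

test_that("a huge gap decouples the two sides of the chromosome", {
  p <- rep(0.5, 2)
  pos <- c(1, 1e12)  # effectively infinite genetic distance
  for (g1 in c(0L, 1L, 2L)) {
    fb <- forward_backward(c(g1, 2L), p, pos, spec3)
    e2 <- emission_probabilities(2L, 0.5, spec3)
    expected <- spec3$mixing * e2 / sum(spec3$mixing * e2)
    expect_equal(as.numeric(fb$gamma[2, ]), expected, tolerance = 1e-12)
  }
})

test_that("EM is monotone, respects max_iter = 0, and finds non-HBD data", {
  set.seed(53)
  m <- 600
  p <- runif(m, 0.2, 0.8)
  calls <- t(replicate(10, rbinom(m, 2, p)))
  g <- make_genotypes(calls, bp = seq_len(m) * 2e4)
  fit0 <- fit_mixing_em(g, hbd_model_spec(), max_iter = 0)
  expect_equal(fit0[[1]]$spec$mixing, rep(1 / 7, 7))
  fits <- fit_mixing_em(g, hbd_model_spec(), max_iter = 50)
  for (f in fits) {
    expect_true(all(diff(f$loglik_trace) > -1e-9))
    expect_gte(1 - f$hbd_mixing, 0.9)
  }
})

test_that("segment extraction thresholds the summed HBD posterior", {
  fake <- structure(list(gamma = NULL,
                         hbd_prob = c(0.99, 0.99, 0.2, 0.99, 0.99),
                         loglik = -1), class = "hbd_posterior")
  pos <- c(10, 20, 30, 40, 50)
  seg <- call_hbd_segments(fake, pos, threshold = 0.5)
  expect_equal(seg$start_bp, c(10, 40))
  expect_equal(seg$end_bp, c(20, 50))
  expect_equal(seg$n_snp, c(2L, 2L))
  all_hot <- structure(list(hbd_prob = rep(0.99, 5), loglik = -1),
                       class = "hbd_posterior")
  expect_equal(nrow(call_hbd_segments(all_hot, pos)), 1)
  none <- structure(list(hbd_prob = rep(0.01, 5), loglik = -1),
                    class = "hbd_posterior")
  expect_equal(nrow(call_hbd_segments(none, pos)), 0)
})

test_that("planted autozygous tracts are recovered with high posterior", {
  feats <- data.frame(kind = "ROH_TRACT", breed = 1, chrom = 1,
                      start_bp = 10e6 + 15000,
                      end_bp = 10e6 + 200 * 15000,
                      carrier_fraction = 0.5, intensity = 1)
  sim <- simulate_dataset(sim_config(seed = 8, n_breeds = 1,
                                     chrom_lengths_bp = 25e6,
                                     features = feats))
  g <- sim$genotypes
  carriers <- strsplit(sim$truth$carriers[1], ",")[[1]]
  fits <- fit_mixing_em(g, max_iter = 30)
  freqs <- colMeans(g$calls, na.rm = TRUE) / 2
  freqs <- pmin(pmax(freqs, 1e-3), 1 - 1e-3)
  intract <- g$map$bp >= sim$truth$start_bp[1] &
    g$map$bp <= sim$truth$end_bp[1]
  post <- vapply(carriers, function(sid) {
    i <- match(sid, g$samples$sample_id)
    fb <- forward_backward(g$calls[i, ], freqs, g$map$bp,
                           fits[[sid]]$spec)
    mean(fb$hbd_prob[intract])
  }, numeric(1))
  expect_gte(mean(post), 0.9)
  # at least one overlapping segment called per carrier
  segs <- hbd_segments(g, max_iter = 30)
  for (sid in carriers) {
    s <- segs[segs$sample_id == sid, ]
    expect_true(any(s$start_bp <= sim$truth$end_bp[1] &
                      s$end_bp >= sim$truth$start_bp[1]))
  }
})

test_that("the fitted model recovers the simulated autozygous fraction", {
  # ~20% of the genome planted HBD; the recovered quantity is the mean
  # posterior HBD probability across the genome (the per-draw mixing
  # weight is much smaller because one long HBD segment competes with
  # many short non-HBD draws)
  feats <- data.frame(kind = "ROH_TRACT", breed = 1, chrom = 1,
                      start_bp = 5e6 + 15000, end_bp = 10e6,
                      carrier_fraction = 1, intensity = 1)
  sim <- simulate_dataset(sim_config(seed = 9, n_breeds = 1,
                                     individuals_per_breed = 6,
                                     chrom_lengths_bp = 25e6,
                                     features = feats))
  g <- sim$genotypes
  fits <- fit_mixing_em(g, max_iter = 40)
  freqs <- pmin(pmax(colMeans(g$calls, na.rm = TRUE) / 2, 1e-3), 1 - 1e-3)
  frac <- vapply(seq_len(nrow(g$samples)), function(i) {
    fb <- forward_backward(g$calls[i, ], freqs, g$map$bp,
                           fits[[g$samples$sample_id[i]]]$spec)
    mean(fb$hbd_prob)
  }, numeric(1))
  expect_true(all(abs(frac - 0.2) <= 0.1))
})
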