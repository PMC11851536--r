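# intervals on distinct chromosomes engineered so region r is supported
# by exactly counts[r] breeds
counts_features <- function(counts) {
  do.call(rbind, lapply(seq_along(counts), function(r) {
    data.frame(breed = sprintf("b%02d", seq_len(counts[r])),
               chrom = as.character(r), start_bp = 1e4, end_bp = 2e4)
  }))
}

test_that("the worked breed-count vector flags only the 9-breed region", {
  counts <- c(1, 1, 1, 2, 2, 2, 3, 3, 4, 9)
  hs <- hot_spots(counts_features(counts), z_crit = 1.645)
  expect_equal(sort(hs$regions$k), sort(counts))
  # brute-force z over the region set
  z_oracle <- (counts - mean(counts)) / sd(counts)
  reg <- hs$regions[order(as.numeric(hs$regions$chrom)), ]
  expect_equal(reg$z, z_oracle)
  expect_equal(reg$significant, z_oracle >= 1.645)
  expect_equal(nrow(hs$hot_spots), 1)
  expect_equal(hs$hot_spots$k, 9)
})

test_that("uniform coverage yields no hot spots", {
  expect_warning(hs <- hot_spots(counts_features(rep(2, 6))), "undefined")
  expect_false(any(hs$regions$significant))
  expect_equal(nrow(hs$hot_spots), 0)
})

test_that("identical intervals from two breeds form one k=2 region", {
  f <- data.frame(breed = c("a", "b"), chrom = "1",
                  start_bp = 100, end_bp = 500)
  expect_warning(hs <- hot_spots(f), "undefined")
  expect_equal(nrow(hs$regions), 1)
  expect_equal(hs$regions$k, 2)
  expect_equal(hs$regions$breeds, "a,b")
})

test_that("region decomposition preserves the union of input intervals", {
  set.seed(81)
  for (rep in 1:20) {
    f <- data.frame(breed = sample(letters[1:5], 12, replace = TRUE),
                    chrom = sample(c("1", "2"), 12, replace = TRUE),
                    start_bp = sample(1e5, 12))
    f$end_bp <- f$start_bp + sample(1e4, 12)
    hs <- suppressWarnings(hot_spots(f))
    for (ch in unique(f$chrom)) {
      fc <- f[f$chrom == ch, ]
      rc <- hs$regions[hs$regions$chrom == ch, ]
      # union length in inclusive-coordinate bp
      pts <- sort(unique(unlist(mapply(seq, fc$start_bp, fc$end_bp,
                                       SIMPLIFY = FALSE))))
      expect_equal(sum(rc$end_bp - rc$start_bp + 1), length(pts))
    }
  }
})

test_that("sweep-line regions have constant supporting sets", {
  f <- data.frame(breed = c("a", "b", "c"), chrom = "1",
                  start_bp = c(100, 150, 400), end_bp = c(300, 500, 450))
  hs <- suppressWarnings(hot_spots(f))
  reg <- hs$regions
  expect_equal(reg$start_bp, c(100, 150, 301, 400, 451))
  expect_equal(reg$end_bp, c(149, 300, 399, 450, 500))
  expect_equal(reg$breeds, c("a", "a,b", "b", "b,c", "b"))
})

test_that("island-signal overlaps follow the same-breed inclusive rule", {
  isl <- data.frame(breed = c("X", "Y"), island_type = "HRRI",
                    chrom = "1", start_bp = c(1000, 1000),
                    end_bp = c(2000, 2000), n_snp = 5L,
                    threshold_used = 0.5, peak_frequency = 0.9)
  sig <- data.frame(breed = "X", chrom = "1", window_start = 1499,
                    window_end = 2500, n_sites = 10L, s = 5L, pi = 1,
                    d = 3, threshold_used = 2)
  ov <- count_overlaps(isl, sig)
  expect_equal(nrow(ov), 1)  # breed Y's identical island does not count
  expect_equal(ov$breed, "X")
  expect_equal(ov$overlap_bp, 501)
  # island nested inside a signal window
  sig2 <- transform(sig, window_start = 500, window_end = 2500)
  expect_equal(count_overlaps(isl, sig2)$overlap_bp, 1001)
  # cross-breed mode counts both islands
  expect_equal(nrow(count_overlaps(isl, sig, same_breed = FALSE)), 2)
  # disjoint coordinates -> nothing
  sig3 <- transform(sig, window_start = 5000, window_end = 6000)
  expect_equal(nrow(count_overlaps(isl, sig3)), 0)
})

test_that("one-way ANOVA matches the hand-computed table", {
  # groups {1,2,3} vs {4,5,6}: SSB 13.5, MSW 1 -> F = 13.5
  a <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(a$f, 13.5)
  expect_equal(a$r_squared, 13.5 / 17.5)
  expect_equal(a$p, pf(13.5, 1, 4, lower.tail = FALSE))
  # separation with zero within-group variance (F-test degenerates)
  b <- suppressWarnings(
    one_way_anova(c(1, 1, 1, 2, 2, 2), rep(c("A", "B"), each = 3)))
  expect_equal(b$r_squared, 1)
  # identical group means
  c_ <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(c_$f, 0)
  expect_equal(c_$r_squared, 0)
})

test_that("ANOVA R-squared is invariant to affine transforms", {
  set.seed(82)
  v <- rnorm(30)
  gr <- sample(c("A", "B", "C"), 30, replace = TRUE)
  a <- one_way_anova(v, gr)
  b <- one_way_anova(3 * v - 7, gr)
  expect_equal(a$r_squared, b$r_squared)
  expect_equal(a$f, b$f)
})

test_that("WC84 components reproduce hand-evaluated cases", {
  # single locus, n1 = n2 = 10, p 0.9/0.1, h 0.18 both
  cmp <- wc_fst_components(10, 10, 0.9, 0.1, 0.18, 0.18)
  # spreadsheet-style evaluation
  n_bar <- 10
  n_c <- (20 - 200 / 20) / 1
  p_bar <- 0.5
  s2 <- (10 * 0.16 + 10 * 0.16) / 10
  h_bar <- 0.18
  a <- (n_bar / n_c) * (s2 - (1 / 9) * (0.25 - s2 / 2 - h_bar / 4))
  b <- (10 / 9) * (0.25 - s2 / 2 - (19 / 40) * h_bar)
  expect_equal(cmp$a, a)
  expect_equal(cmp$b, b)
  expect_equal(cmp$c, 0.09)
})

test_that("FST is 1 for fixed differences and <= 0 for duplicated halves", {
  n <- 10
  m <- 50
  calls <- rbind(matrix(0L, n, m), matrix(2L, n, m))
  g <- make_genotypes(calls, bp = seq_len(m) * 1e4,
                      breed = rep(c("A", "Z"), each = n))
  fst <- pairwise_fst(g)
  expect_equal(fst["A", "Z"], 1)
  expect_true(isSymmetric(fst))
  expect_equal(diag(fst), c(A = 0, Z = 0))
  set.seed(83)
  half <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.8), each = n)), n, m)
  g2 <- make_genotypes(rbind(half, half), bp = seq_len(m) * 1e4,
                       breed = rep(c("A", "Z"), each = n))
  expect_lte(pairwise_fst(g2)["A", "Z"], 1e-12)
})

test_that("FST grows with simulated Balding-Nichols divergence", {
  theta_at <- function(fdiv, seed) {
    sim <- simulate_dataset(sim_config(seed, n_breeds = 2,
                                       chrom_lengths_bp = 15e6,
                                       breed_divergence = fdiv,
                                       missing_rate = 0))
    pairwise_fst(sim$genotypes)[1, 2]
  }
  lo <- mean(sapply(1:3, function(s) theta_at(0.05, s)))
  hi <- mean(sapply(1:3, function(s) theta_at(0.20, s)))
  expect_lt(lo, hi)
  expect_gt(hi, 0.1)
})
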