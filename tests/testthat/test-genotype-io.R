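test_that("PED genotypes are coded against the first observed allele", {
  ped <- c("F1 i1 0 0 0 -9 A A A G G G",
           "F1 i2 0 0 0 -9 A A 0 0 G A")
  map <- c("1 m1 0 100", "1 m2 0 200", "1 m3 0 300")
  pp <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  writeLines(ped, pp)
  writeLines(map, mp)
  g <- read_ped_map(pp, mp)
  # at m3 the first observed allele is G, so "G G" is hom allele A
  expect_equal(unname(g$calls["i1", ]), c(0L, 1L, 0L))
  expect_true(is.na(g$calls["i2", "m2"]))  # "0 0" pair is missing
  expect_equal(unname(g$calls["i2", "m3"]), 1L)
  expect_equal(g$map$allele_a, c("A", "A", "G"))
  expect_equal(g$samples$breed, c("F1", "F1"))
})

test_that("malformed PED rows and triallelic markers are rejected", {
  mp <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 m1 0 100", "1 m2 0 200"), mp)
  pp <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 i1 0 0 0 -9 A A G G",
               "F1 i2 0 0 0 -9 A A G G T T"), pp)
  expect_error(read_ped_map(pp, mp), "line 2")
  writeLines(c("F1 i1 0 0 0 -9 A A G G",
               "F1 i2 0 0 0 -9 C T G G"), pp)
  expect_error(read_ped_map(pp, mp), "distinct alleles")
})

test_that("markers are re-sorted by position with calls permuted", {
  pp <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  writeLines("F1 i1 0 0 0 -9 A A G G C C", pp)
  writeLines(c("2 m1 0 100", "1 m2 0 900", "1 m3 0 50"), mp)
  g <- read_ped_map(pp, mp)
  expect_equal(g$map$marker_id, c("m3", "m2", "m1"))
  expect_equal(unname(g$calls[1, ]), c(0L, 0L, 0L))
  expect_equal(g$map$allele_a, c("C", "G", "A"))
})

test_that("BED 2-bit packing decodes per the SNP-major layout", {
  # byte 0xD8 = 0b11011000: sample slots LSB-first are 00, 10, 01, 11
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "x.bed")
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8)), con)
  close(con)
  writeLines("1\tm1\t0\t100\tA\tG", file.path(dir, "x.bim"))
  writeLines(sprintf("F%d\ti%d\t0\t0\t0\t-9", 1:4, 1:4),
             file.path(dir, "x.fam"))
  g <- read_bed_bim_fam(bed, file.path(dir, "x.bim"),
                        file.path(dir, "x.fam"))
  expect_equal(unname(g$calls[, 1]), c(0L, 1L, NA, 2L))
})

test_that("BED pad bits are ignored and format errors are raised", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "x.bed")
  # 5 samples, 1 marker -> 2 data bytes, 3 trailing pad pairs
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8, 0xff)), con)
  close(con)
  writeLines("1\tm1\t0\t100\tA\tG", file.path(dir, "x.bim"))
  writeLines(sprintf("F%d\ti%d\t0\t0\t0\t-9", 1:5, 1:5),
             file.path(dir, "x.fam"))
  g <- read_bed_bim_fam(bed, file.path(dir, "x.bim"),
                        file.path(dir, "x.fam"))
  expect_equal(unname(g$calls[, 1]), c(0L, 1L, NA, 2L, 2L))

  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0xd8)), con)
  close(con)
  expect_error(read_bed_bim_fam(bed, file.path(dir, "x.bim"),
                                file.path(dir, "x.fam")), "mode")
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8)), con)  # 1 byte, 2 expected
  close(con)
  expect_error(read_bed_bim_fam(bed, file.path(dir, "x.bim"),
                                file.path(dir, "x.fam")), "truncated")
})

test_that("PED/MAP and BED/BIM/FAM round trips preserve the matrix", {
  set.seed(21)
  calls <- matrix(sample(c(0:2, NA), 9 * 17, replace = TRUE), 9, 17)
  g <- make_genotypes(calls, bp = sort(sample(1e6, 17)),
                      chrom = rep(c("1", "2"), c(9, 8)),
                      breed = rep(c("A", "B", "C"), each = 3))
  dir <- withr::local_tempdir()
  write_ped_map(g, file.path(dir, "r.ped"), file.path(dir, "r.map"))
  g_txt <- read_ped_map(file.path(dir, "r.ped"), file.path(dir, "r.map"))
  write_bed_bim_fam(g, file.path(dir, "r.bed"), file.path(dir, "r.bim"),
                    file.path(dir, "r.fam"))
  g_bin <- read_bed_bim_fam(file.path(dir, "r.bed"),
                            file.path(dir, "r.bim"),
                            file.path(dir, "r.fam"))
  # text re-reading may flip allele orientation at a marker whose first
  # observed allele is B; compare het/missing structure and parity of hets
  expect_identical(g_bin$calls, g$calls)
  expect_identical(dim(g_txt$calls), dim(g$calls))
  expect_identical(is.na(g_txt$calls), is.na(g$calls))
  expect_identical(g_txt$calls == 1L, g$calls == 1L)
  expect_identical(g_txt$map$marker_id, g$map$marker_id)
  # binary and text forms of the same data agree up to orientation
  expect_identical(g_txt$calls == 1L, g_bin$calls == 1L)
})

test_that("orientation-stable matrices round trip to identical codes", {
  set.seed(22)
  calls <- matrix(sample(c(0:2, NA), 6 * 11, replace = TRUE), 6, 11)
  calls[1, ] <- rep(c(0L, 1L), length.out = 11)  # pins allele A first
  g <- make_genotypes(calls, breed = rep(c("A", "B"), each = 3))
  dir <- withr::local_tempdir()
  write_ped_map(g, file.path(dir, "s.ped"), file.path(dir, "s.map"))
  g2 <- read_ped_map(file.path(dir, "s.ped"), file.path(dir, "s.map"))
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$map$marker_id, g$map$marker_id)
  expect_identical(g2$samples, g$samples)
})

test_that("interval BED export uses 0-based half-open sorted records", {
  iv <- data.frame(chrom = c("2", "1", "1"),
                   start_bp = c(500, 1001, 10),
                   end_bp = c(600, 2000, 20),
                   label = c("c", "a", "b"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_intervals_bed(iv, path)
  lines <- readLines(path)
  expect_equal(lines[1], "1\t9\t20\tb")
  expect_equal(lines[2], "1\t1000\t2000\ta")
  expect_equal(lines[3], "2\t499\t600\tc")
  # end - start = end_bp - start_bp + 1 for every line
  f <- read.table(path)
  expect_equal(f$V3 - f$V2, c(11, 1000, 101))
  write_intervals_bed(iv[0, ], path)
  expect_length(readLines(path), 0)
})
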