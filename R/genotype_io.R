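# PLINK text/binary readers and interval/table writers.
#
# The in-memory container is a plain list of three pieces (a `genotypes`
# object): a sample table, a marker map and an integer call matrix. All
# coordinates are 1-based inclusive base pairs; the conversion to 0-based
# half-open happens only when writing BED interval files.

#' Construct a genotypes object
#'
#' Bundles a sample table, a marker map and a call matrix into the container
#' used by every stage of the package. Markers are re-sorted by
#' `(chrom, bp)` and the call matrix columns are permuted to match.
#'
#' @param samples data.frame with columns `sample_id` (unique) and `breed`.
#' @param map data.frame with columns `marker_id` (unique), `chrom`, `bp`
#'   (1-based physical position) and optionally `allele_a`, `allele_b`.
#' @param calls integer matrix, `nrow(samples)` x `nrow(map)`, with codes
#'   0 (hom A), 1 (het), 2 (hom B) and `NA` (missing).
#' @return An object of class `genotypes`: a list with elements `samples`,
#'   `map` and `calls`.
#' @export
genotypes <- function(samples, map, calls) {
  stopifnot(is.data.frame(samples), is.data.frame(map), is.matrix(calls))
  samples$sample_id <- as.character(samples$sample_id)
  samples$breed <- as.character(samples$breed)
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$bp <- as.numeric(map$bp)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker_id in map")
  if (anyDuplicated(map[, c("chrom", "bp")]))
    stop("duplicate (chrom, bp) position in map")
  if (any(map$bp < 1)) stop("map positions must be >= 1")
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(map))
    stop("call matrix dimensions do not match samples x markers")
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("call matrix contains codes outside {0, 1, 2, NA}")
  ord <- order(chrom_order(map$chrom), map$bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  rownames(samples) <- NULL
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples$sample_id, map$marker_id)
  structure(list(samples = samples, map = map, calls = calls),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d markers, %d breed(s), %d chromosome(s)\n",
              nrow(x$samples), nrow(x$map),
              length(unique(x$samples$breed)),
              length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

# Chromosome sort key: numeric labels in numeric order, then others
# lexically. Keeps dog autosomes 1..38 in natural order.
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  lab <- ifelse(is.na(num), chrom, sprintf("%015.3f", num))
  key <- paste0(ifelse(is.na(num), "z", "a"), lab)
  match(key, sort(unique(key)))
}

#' Read PLINK PED/MAP text genotypes
#'
#' Parses a PLINK 1 text fileset into a [genotypes()] object. The PED family
#' ID column is used as the breed label. For each marker, allele A (code 0)
#' is the first non-missing allele observed in file order, which makes the
#' coding deterministic; all downstream statistics are symmetric in allele
#' orientation.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [genotypes()] object.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- read.table(map_path, header = FALSE, colClasses = "character",
                        col.names = c("chrom", "marker_id", "cm", "bp"))
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != want)
      stop(sprintf(
        "PED line %d has %d fields; expected %d for %d markers in %s",
        i, length(toks[[i]]), want, m, map_path))
  }
  n <- length(toks)
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- data.frame(sample_id = tok[, 2], breed = tok[, 1],
                        stringsAsFactors = FALSE)
  calls <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- rep(NA_character_, m)
  for (k in seq_len(m)) {
    a1 <- tok[, 5L + 2L * k]
    a2 <- tok[, 6L + 2L * k]
    # observation order: ind1 allele1, ind1 allele2, ind2 allele1, ...
    seen <- as.vector(rbind(a1, a2))
    seen <- unique(seen[seen != "0"])
    if (length(seen) > 2)
      stop(sprintf("marker %s has >2 distinct alleles: %s",
                   map_raw$marker_id[k], paste(seen, collapse = ", ")))
    if (length(seen) >= 1) allele_a[k] <- seen[1]
    if (length(seen) == 2) allele_b[k] <- seen[2]
    miss <- a1 == "0" | a2 == "0"
    code <- (a1 != allele_a[k]) + (a2 != allele_a[k])
    code[miss] <- NA_integer_
    calls[, k] <- as.integer(code)
  }
  map <- data.frame(marker_id = map_raw$marker_id, chrom = map_raw$chrom,
                    bp = as.numeric(map_raw$bp),
                    allele_a = allele_a, allele_b = allele_b,
                    stringsAsFactors = FALSE)
  genotypes(samples, map, calls)
}

#' Write PLINK PED/MAP text genotypes
#'
#' Inverse of [read_ped_map()]. Alleles default to `A`/`B` symbols where the
#' map carries no allele labels. Breed is written as the family ID.
#'
#' @param g A [genotypes()] object.
#' @param ped_path,map_path Output paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  map <- g$map
  aa <- if ("allele_a" %in% names(map)) map$allele_a else rep(NA, nrow(map))
  ab <- if ("allele_b" %in% names(map)) map$allele_b else rep(NA, nrow(map))
  aa[is.na(aa)] <- "A"
  ab[is.na(ab)] <- "B"
  write.table(data.frame(map$chrom, map$marker_id, 0, format(map$bp, scientific = FALSE, trim = TRUE)),
              map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g$samples)
  m <- nrow(map)
  out <- character(n)
  for (i in seq_len(n)) {
    gi <- g$calls[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi == 2, ab, aa))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, ab, aa))
    out[i] <- paste(c(g$samples$breed[i], g$samples$sample_id[i], "0", "0",
                      "0", "-9", as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(out, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK binary BED/BIM/FAM genotypes
#'
#' Decodes a SNP-major PLINK 1 binary fileset. Per byte, four samples are
#' packed least-significant-bits first with 2-bit codes 00 = hom A1,
#' 01 = missing, 10 = het, 11 = hom A2; trailing pad bits in the last byte
#' of each marker block are ignored. A1 maps to code 0, A2 to code 2.
#'
#' @param bed_path,bim_path,fam_path Paths to the three PLINK binary files.
#' @return A [genotypes()] object.
#' @export
read_bed_bim_fam <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- read.table(bim_path, header = FALSE, colClasses = "character",
                    col.names = c("chrom", "marker_id", "cm", "bp",
                                  "allele_a", "allele_b"))
  fam <- read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("unsupported BED mode byte (only SNP-major 0x01 supported): ",
         bed_path)
  bpm <- ceiling(n / 4)  # bytes per marker
  body <- raw[-(1:3)]
  if (length(body) != bpm * m)
    stop(sprintf("BED file truncated: %d data bytes, expected %d (%d samples x %d markers)",
                 length(body), bpm * m, n, m))
  bytes <- matrix(as.integer(body), nrow = bpm, ncol = m)
  lookup <- c(0L, NA_integer_, 1L, 2L)  # 2-bit value 0..3
  calls <- matrix(NA_integer_, n, m)
  for (s in 0:3) {  # sample slot within byte, LSB first
    rows <- seq.int(s + 1L, n, by = 4L)
    if (!length(rows)) break
    pair <- (bytes[ceiling(rows / 4), , drop = FALSE] %/% 4L^s) %% 4L
    calls[rows, ] <- lookup[pair + 1L]
  }
  samples <- data.frame(sample_id = fam[, 2], breed = fam[, 1],
                        stringsAsFactors = FALSE)
  map <- data.frame(marker_id = bim$marker_id, chrom = bim$chrom,
                    bp = as.numeric(bim$bp),
                    allele_a = bim$allele_a, allele_b = bim$allele_b,
                    stringsAsFactors = FALSE)
  genotypes(samples, map, calls)
}

#' Write PLINK binary BED/BIM/FAM genotypes
#'
#' Inverse of [read_bed_bim_fam()]; writes SNP-major mode.
#'
#' @param g A [genotypes()] object.
#' @param bed_path,bim_path,fam_path Output paths.
#' @export
write_bed_bim_fam <- function(g, bed_path, bim_path, fam_path) {
  map <- g$map
  aa <- if ("allele_a" %in% names(map)) map$allele_a else rep("A", nrow(map))
  ab <- if ("allele_b" %in% names(map)) map$allele_b else rep("B", nrow(map))
  aa[is.na(aa)] <- "A"
  ab[is.na(ab)] <- "B"
  write.table(data.frame(map$chrom, map$marker_id, 0,
                         format(map$bp, scientific = FALSE, trim = TRUE), aa, ab),
              bim_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(g$samples$breed, g$samples$sample_id, 0, 0, 0, -9),
              fam_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g$samples)
  m <- nrow(g$map)
  bpm <- ceiling(n / 4)
  to2bit <- function(code) {
    v <- integer(length(code))       # 00 hom A1
    v[is.na(code)] <- 1L             # 01 missing
    v[!is.na(code) & code == 1L] <- 2L  # 10 het
    v[!is.na(code) & code == 2L] <- 3L  # 11 hom A2
    v
  }
  bytes <- matrix(0L, bpm, m)
  for (s in 0:3) {
    rows <- seq.int(s + 1L, n, by = 4L)
    if (!length(rows)) break
    v <- matrix(0L, bpm, m)
    v[ceiling(rows / 4), ] <- apply(g$calls[rows, , drop = FALSE], 2, to2bit)
    bytes <- bytes + v * 4L^s
  }
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}

#' Write genomic intervals as a BED3+ file
#'
#' Converts 1-based inclusive intervals to the 0-based half-open BED
#' convention and writes them sorted by chromosome and start.
#'
#' @param intervals data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive) and optionally `label`.
#' @param path Output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(intervals$start_bp <= intervals$end_bp))
  lab <- if ("label" %in% names(intervals)) as.character(intervals$label)
         else rep(".", nrow(intervals))
  ord <- order(chrom_order(as.character(intervals$chrom)), intervals$start_bp)
  df <- data.frame(chrom = as.character(intervals$chrom)[ord],
                   start = format(intervals$start_bp[ord] - 1,
                                  scientific = FALSE, trim = TRUE),
                   end = format(intervals$end_bp[ord],
                                scientific = FALSE, trim = TRUE),
                   label = lab[ord])
  writeLines(do.call(paste, c(df, sep = "\t")), path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; undefined values are written as `.`.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @export
write_tsv_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- ifelse(is.na(df[[j]]), NA,
                      format(df[[j]], scientific = FALSE, trim = TRUE,
                             digits = 10))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Subset a genotypes object
#'
#' @param g A [genotypes()] object.
#' @param samples Character vector of sample_ids to keep (default all).
#' @param markers Logical/integer index or character marker_ids to keep.
#' @return A [genotypes()] object.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(g$samples))
        else match(samples, g$samples$sample_id)
  if (anyNA(si)) stop("unknown sample_id in subset")
  mi <- if (is.null(markers)) seq_len(nrow(g$map))
        else if (is.character(markers)) match(markers, g$map$marker_id)
        else markers
  genotypes(g$samples[si, , drop = FALSE], g$map[mi, , drop = FALSE],
            g$calls[si, mi, drop = FALSE])
}

# Alternate ("B") allele frequency per marker from non-missing calls.
alt_freqs <- function(g) {
  colMeans(g$calls, na.rm = TRUE) / 2
}
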