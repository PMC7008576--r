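test_that("VCF reading auto-detects ploidy and counts", {
  dir <- withr::local_tempdir()
  fx2 <- make_fixture(dir, n_founders = 20, n_chrom = 2, n_snps = 100,
                      ploidy = 2, prefix = "dip", seed = 101)
  f2 <- read_founder_vcf(fx2$vcf, verbose = FALSE)
  expect_identical(f2$ploidy, 2L)
  expect_identical(f2$n_founders, 20L)
  expect_identical(nrow(f2$snps), 100L)
  expect_identical(length(unique(f2$snps$chr)), 2L)
  expect_identical(ncol(f2$haps), 40L)

  fx4 <- make_fixture(dir, n_founders = 8, n_chrom = 1, n_snps = 30,
                      ploidy = 4, prefix = "tet", seed = 102)
  f4 <- read_founder_vcf(fx4$vcf, verbose = FALSE)
  expect_identical(f4$ploidy, 4L)
  expect_identical(ncol(f4$haps), 32L)
})

test_that("ploidy detection and frequencies are sample-order invariant", {
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 10, n_chrom = 1, n_snps = 20,
                     ploidy = 4, prefix = "ord", seed = 103)
  lines <- readLines(fx$vcf)
  hdr <- grep("^#CHROM", lines)
  shuffle_cols <- function(line) {
    parts <- strsplit(line, "\t")[[1]]
    paste(c(parts[1:9], parts[9 + perm]), collapse = "\t")
  }
  set.seed(1)
  perm <- sample(10)
  out <- lines
  out[hdr:length(lines)] <- vapply(lines[hdr:length(lines)], shuffle_cols, "")
  shuf <- file.path(dir, "shuffled.vcf")
  writeLines(out, shuf)
  a <- read_founder_vcf(fx$vcf, verbose = FALSE)
  b <- read_founder_vcf(shuf, verbose = FALSE)
  expect_identical(b$ploidy, a$ploidy)
  expect_identical(b$freq, a$freq)
  expect_identical(sort(b$founder_ids), sort(a$founder_ids))
})

test_that("founder decode reproduces the input VCF dosages exactly", {
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 15, n_chrom = 2, n_snps = 40,
                     ploidy = 2, prefix = "rt", seed = 104)
  f <- read_founder_vcf(fx$vcf, verbose = FALSE)
  pop <- toy_pop(f)
  decoded <- decode_genotypes(pop)

  # independent parse of the VCF body
  lines <- grep("^#", readLines(fx$vcf), value = TRUE, invert = TRUE)
  parts <- strsplit(lines, "\t")
  raw <- t(vapply(parts, function(p) {
    vapply(p[-(1:9)], function(gt) sum(as.integer(strsplit(gt, "[|/]")[[1]])), 0)
  }, numeric(15)))
  ord <- order(match(vapply(parts, `[[`, "", 1), unique(vapply(parts, `[[`, "", 1))),
               as.numeric(vapply(parts, `[[`, "", 2)))
  expect_equal(unname(decoded), unname(t(raw[ord, , drop = FALSE])),
               ignore_attr = TRUE)
})

test_that("plink-like PED/MAP reads, recodes first-observed allele as 0", {
  ped <- withr::local_tempfile()
  map <- withr::local_tempfile()
  writeLines(c(
    "FAM1 I1 0 0 2 -9 A T A A G G",
    "FAM1 I2 0 0 1 -9 T T A T G G"
  ), ped)
  writeLines(c("1 s1 0 100", "1 s2 0 200", "2 s3 0 50"), map)
  f <- read_pedlike(ped, map, verbose = FALSE)
  expect_identical(f$ploidy, 2L)
  expect_identical(ncol(f$haps), 4L)
  # s1: A T | T T -> 0 1 1 1 (A first observed); hand-tallied frequency 3/4
  expect_identical(f$haps[1, ], c(0L, 1L, 1L, 1L))
  expect_identical(f$freq[1], 0.75)
  # s3 monomorphic G -> all zero
  expect_identical(f$haps[3, ], rep(0L, 4))

  bad_ped <- withr::local_tempfile()
  writeLines(c("F I1 0 0 2 -9 A T A A G G",
               "F I2 0 0 1 -9 T C A T G G"), bad_ped)
  expect_error(read_pedlike(bad_ped, map, verbose = FALSE), "more than two")

  short_map <- withr::local_tempfile()
  writeLines(c("1 s1 0 100"), short_map)
  expect_error(read_pedlike(ped, short_map, verbose = FALSE), "expected")
})

test_that("missing GT calls are imputed from observed frequencies", {
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 10, n_chrom = 1, n_snps = 10,
                     ploidy = 2, prefix = "miss", seed = 105)
  lines <- readLines(fx$vcf)
  body <- grep("^#", lines, invert = TRUE)
  parts <- strsplit(lines[body[1]], "\t")[[1]]
  parts[10] <- ".|."
  lines[body[1]] <- paste(parts, collapse = "\t")
  path <- file.path(dir, "missing.vcf")
  writeLines(lines, path)
  set.seed(7)
  f <- read_founder_vcf(path, verbose = FALSE)
  expect_false(anyNA(f$haps))
  expect_true(all(f$haps %in% 0:1))
  set.seed(7)
  f2 <- read_founder_vcf(path, verbose = FALSE)
  expect_identical(f$haps, f2$haps)
})

test_that("mixed ploidy is rejected", {
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 4, n_chrom = 1, n_snps = 5,
                     ploidy = 2, prefix = "mix", seed = 106)
  lines <- readLines(fx$vcf)
  body <- grep("^#", lines, invert = TRUE)
  parts <- strsplit(lines[body[1]], "\t")[[1]]
  parts[10] <- "0|1|1"
  lines[body[1]] <- paste(parts, collapse = "\t")
  path <- file.path(dir, "mixed.vcf")
  writeLines(lines, path)
  expect_error(read_founder_vcf(path, verbose = FALSE), "mixed ploidy")
})

test_that("MAF filtering matches a brute-force frequency tally", {
  set.seed(11)
  f <- rand_founders(10, 50)
  expect_identical(nrow(maf_filter(f, 0)$snps), 50L)

  filt <- maf_filter(f, 0.1)
  maf <- pmin(rowMeans(f$haps), 1 - rowMeans(f$haps))
  expect_identical(nrow(filt$snps), sum(maf >= 0.1))
  expect_equal(filt$freq, rowMeans(f$haps)[maf >= 0.1])

  # monomorphic SNPs are removed by any positive threshold
  f$haps[1, ] <- 0L
  mono <- breedsim:::new_founders(f$haps, f$snps, 2L, f$founder_ids)
  expect_false(1000 %in% maf_filter(mono, 1e-6)$snps$pos[1])
  expect_error(maf_filter(f, 0.7), "0.5")
})

test_that("dummy founders recombine real founder material only", {
  set.seed(21)
  f <- rand_founders(12, 40)
  pop <- toy_pop(f)
  expect_identical(pop_size(make_dummy_founders(pop, 0)), pop_size(pop))
  expect_error(make_dummy_founders(pop, -1), ">= 0")

  for (mode in c("random_blocks", "gene_drop")) {
    ext <- make_dummy_founders(pop, 30, mode = mode)
    expect_identical(pop_size(ext), 42L)
    expect_true(all(ext$ped$base))
    expect_identical(unique(ext$ped$generation), 0L)
    dos <- decode_genotypes(ext, ids = 13:42)
    # dummies only ever copy founder alleles: where founders are fixed, so
    # are the dummies
    fixed0 <- which(f$freq == 0)
    if (length(fixed0)) expect_true(all(dos[, fixed0] == 0))
    expect_true(all(dos >= 0 & dos <= 2))
  }
})

test_that("dummy founders preserve allele frequencies within sampling error", {
  set.seed(31)
  f <- rand_founders(20, 30)
  pop <- toy_pop(f)
  n_new <- 400
  ext <- make_dummy_founders(pop, n_new, mode = "random_blocks")
  dos <- decode_genotypes(ext, ids = 21:(20 + n_new))
  p_hat <- colMeans(dos) / 2
  se <- sqrt(f$freq * (1 - f$freq) / (2 * n_new))
  expect_true(all(abs(p_hat - f$freq) < 5 * se + 1e-9))
})
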