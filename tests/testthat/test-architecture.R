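test_that("diploid genotypic coding is -1/0/+1 with heterozygote dominance", {
  f <- dosage_founders(c(0, 1, 2), n_snp = 1)
  pop <- toy_pop(f, sexes = c("F", "M", "F"))
  g <- pop$genome

  add_only <- breedsim:::new_architecture(1L, "1", 1000, matrix(1), matrix(0), 0, 1)
  expect_equal(unname(genotypic_value(pop, add_only)[, 1]), c(-1, 0, 1))

  dom_only <- breedsim:::new_architecture(1L, "1", 1000, matrix(0), matrix(1), 0, 1)
  expect_equal(unname(genotypic_value(pop, dom_only)[, 1]), c(0, 1, 0))
})

test_that("polyploid coding uses dosage minus half ploidy and phi >= 1 copy", {
  f <- dosage_founders(0:4, n_snp = 1, ploidy = 4)
  pop <- toy_pop(f)
  add_only <- breedsim:::new_architecture(1L, "1", 1000, matrix(1), matrix(0), 0, 1)
  expect_equal(unname(genotypic_value(pop, add_only)[, 1]), c(-2, -1, 0, 1, 2))

  dom_only <- breedsim:::new_architecture(1L, "1", 1000, matrix(0), matrix(1), 0, 1)
  # every carrier of allele 1, including the complete homozygote, scores d
  expect_equal(unname(genotypic_value(pop, dom_only)[, 1]), c(0, 1, 1, 1, 1))
})

test_that("genotypic values are linear in the effects", {
  set.seed(20)
  f <- rand_founders(10, 30)
  pop <- toy_pop(f)
  arch <- random_architecture(pop, 10, h2 = 0.5)
  arch2 <- arch
  arch2$a <- 2 * arch$a
  arch2$d <- 2 * arch$d
  expect_equal(genotypic_value(pop, arch2), 2 * genotypic_value(pop, arch))
})

test_that("an empty architecture gives zero genotypic values", {
  set.seed(21)
  f <- rand_founders(5, 10)
  pop <- toy_pop(f)
  arch <- breedsim:::new_architecture(integer(0), character(0), numeric(0),
                                      matrix(0, 0, 1), matrix(0, 0, 1), 0, 0.5)
  expect_true(all(genotypic_value(pop, arch) == 0))
})

test_that("gamma effect sampling recovers shape and scale by moments", {
  set.seed(22)
  eff <- sample_gamma_effects(2e5)
  m <- abs(eff)
  shape_hat <- mean(m)^2 / stats::var(m)
  scale_hat <- stats::var(m) / mean(m)
  expect_lt(abs(shape_hat - 0.2) / 0.2, 0.05)
  expect_lt(abs(scale_hat - 5) / 5, 0.05)
  # signs are balanced
  expect_lt(abs(mean(sign(eff))), 0.02)
})

test_that("random architectures sample segregating SNPs without replacement", {
  set.seed(23)
  f <- rand_founders(10, 40)
  f$haps[1, ] <- 0L # monomorphic
  f <- breedsim:::new_founders(f$haps, f$snps, 2L, f$founder_ids)
  pop <- toy_pop(f)
  arch <- random_architecture(pop, 39, h2 = 0.5)
  expect_identical(length(unique(arch$qtn)), 39L)
  expect_false(1L %in% arch$qtn)
  expect_error(random_architecture(pop, 40, h2 = 0.5), "segregating")
})

test_that("architectures load from position and effect files", {
  set.seed(24)
  f <- rand_founders(10, 20)
  pop <- toy_pop(f)
  qfile <- withr::local_tempfile()
  writeLines(paste(f$snps$chr[c(3, 7)], f$snps$pos[c(3, 7)]), qfile)
  arch <- architecture_from_positions(pop, qfile, h2 = 0.4)
  expect_identical(arch$qtn, c(3L, 7L))

  efile <- withr::local_tempfile()
  writeLines(paste(f$snps$chr[c(2, 5)], f$snps$pos[c(2, 5)],
                   c(1.5, -0.5), c(0, 0.25), c(0, 0), c(2, 0)), efile)
  arch2 <- architecture_from_effects(pop, efile, h2 = c(0.5, 0.3))
  expect_identical(arch2$n_traits, 2L)
  expect_equal(arch2$a[, 1], c(1.5, -0.5))
  expect_equal(arch2$d[, 2], c(2, 0))

  bad <- withr::local_tempfile()
  writeLines("9 123456", bad)
  expect_error(architecture_from_positions(pop, bad, h2 = 0.5), "not in the SNP list")
})

test_that("environmental variance calibration follows the closed form", {
  expect_identical(calibrate_var_e(c(1, 2, 3), 1), 0)
  g <- stats::rnorm(100)
  var_g <- mean((g - mean(g))^2)
  expect_equal(calibrate_var_e(g, 0.5), var_g)
  g2 <- c(-1, 1) # population variance exactly 1
  expect_equal(calibrate_var_e(g2, 0.2), 4)
  expect_error(calibrate_var_e(g, 0), "in \\(0, 1\\]")
  expect_error(calibrate_var_e(rep(1, 5), 0.5), "zero")
})

test_that("phenotypes equal mu + g when Var(e) is zero", {
  set.seed(25)
  f <- rand_founders(20, 30)
  pop <- toy_pop(f)
  arch <- random_architecture(pop, 10, h2 = 1, mu = 7)
  pop <- attach_architecture(pop, arch)
  expect_identical(pop$arch$var_e, 0)
  expect_equal(pop$y[, 1], pop$g[, 1] + 7)
  ph <- phenotypes(pop)
  expect_equal(ph$y, ph$g + ph$e + 7)
})

test_that("realized heritability approaches the target in large cohorts", {
  set.seed(26)
  f <- rand_founders(2000, 40)
  pop <- toy_pop(f)
  for (h2 in c(0.2, 0.8)) {
    arch <- random_architecture(pop, 20, h2 = h2)
    pop2 <- attach_architecture(pop, arch)
    realized <- mean((pop2$g - mean(pop2$g))^2) / mean((pop2$y - mean(pop2$y))^2)
    expect_lt(abs(realized - h2), 0.05)
  }
})

test_that("multi-trait phenotypes keep environmental deviations independent", {
  set.seed(27)
  f <- rand_founders(500, 30)
  pop <- toy_pop(f)
  eff <- tibble::tibble(
    chr = f$snps$chr[1:10], pos = f$snps$pos[1:10],
    a1 = c(rep(1, 5), rep(0, 5)), d1 = 0,
    a2 = c(rep(0, 5), rep(1, 5)), d2 = 0
  )
  arch <- architecture_from_effects(pop, eff, h2 = c(0.5, 0.5))
  pop <- attach_architecture(pop, arch)
  # no pleiotropy: each trait's g depends only on its own QTN
  solo1 <- architecture_from_effects(pop, eff[1:5, 1:4], h2 = 0.5)
  expect_equal(pop$g[, 1], genotypic_value(pop, solo1)[, 1])
  expect_lt(abs(stats::cor(pop$e[, 1], pop$e[, 2])), 0.12)
})

test_that("QTN variance decomposition matches the substitution-effect formulas", {
  # alpha = a + d(1 - 2p): check the reduction cases and one hand value
  f <- dosage_founders(c(0, 1, 2, 2), n_snp = 1) # p = 5/8
  pop <- toy_pop(f)
  arch <- breedsim:::new_architecture(1L, "1", 1000, matrix(1), matrix(0.5), 0, 1)
  qv <- qtn_variance(pop, arch)
  p <- 5 / 8
  expect_equal(qv$p, p)
  expect_equal(qv$alpha, 1 + 0.5 * (1 - 2 * p))
  expect_equal(qv$var_a, 2 * p * (1 - p) * qv$alpha^2)
  expect_equal(qv$var_d, (2 * p * (1 - p) * 0.5)^2)

  # hand case: a = 1, d = 0.5, p = 0.25
  f2 <- dosage_founders(c(0, 0, 0, 2), n_snp = 1)
  pop2 <- toy_pop(f2)
  qv2 <- qtn_variance(pop2, arch)
  expect_equal(qv2$alpha, 1.25)

  # d = 0: alpha = a and dominance variance identically zero
  set.seed(28)
  f3 <- rand_founders(50, 20)
  pop3 <- toy_pop(f3)
  arch3 <- random_architecture(pop3, 10, h2 = 0.5)
  qv3 <- qtn_variance(pop3, arch3)
  expect_equal(qv3$alpha, qv3$a)
  expect_true(all(qv3$var_d == 0))
  expect_false(is.unsorted(qv3$cum_var))
})

test_that("polyploid QTN variances are empirical genotype-frequency variances", {
  f <- dosage_founders(c(0, 2, 4, 4), n_snp = 1, ploidy = 4)
  pop <- toy_pop(f)
  arch <- breedsim:::new_architecture(1L, "1", 1000, matrix(2), matrix(1), 0, 1)
  qv <- qtn_variance(pop, arch)
  dos <- c(0, 2, 4, 4)
  expect_equal(qv$var_a, 4 * mean((dos - mean(dos))^2))
  phi <- as.numeric(dos >= 1)
  expect_equal(qv$var_d, mean((phi - mean(phi))^2))
})
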