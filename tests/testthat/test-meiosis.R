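test_that("zero genetic length transmits a parental homolog unchanged", {
  map0 <- withr::local_tempfile()
  writeLines("1 100000 0.0 0.0", map0)
  set.seed(5)
  f <- rand_founders(4, 10)
  pop <- toy_pop(f, map_file = map0)
  for (rep in 1:10) {
    gam <- make_gamete(pop$inds[[1]], pop$genome)
    hom <- gam$hom[[1]][[1]]
    parental <- pop$inds[[1]]$hom[[1]]
    expect_true(identical(hom, parental[[1]]) || identical(hom, parental[[2]]))
    expect_identical(gam$n_crossovers, 0L)
  }
})

test_that("crossover counts follow the Poisson rate of the genetic length", {
  # 2-Morgan chromosome: mean crossovers per transmitted strand = 2
  map <- withr::local_tempfile()
  writeLines("1 1000000 200 200", map)
  set.seed(6)
  f <- rand_founders(2, 10)
  pop <- toy_pop(f, map_file = map)
  n <- 3000
  cx <- vapply(seq_len(n), function(i) make_gamete(pop$inds[[1]], pop$genome)$n_crossovers, 0L)
  # Poisson(2): mean within 5 standard errors
  expect_lt(abs(mean(cx) - 2), 5 * sqrt(2 / n))
})

test_that("sex chromosomes and mitochondria follow transmission rules", {
  set.seed(8)
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 10, n_chrom = 1, n_snps = 40,
                     ploidy = 2, sex_chrom = TRUE, y_chrom = TRUE, mito = TRUE,
                     seed = 107)
  f <- read_founder_vcf(fx$vcf, verbose = FALSE)
  g <- build_genome(f)
  pop <- new_population(f, g, sexes = fx$sexes)
  dam <- 1L
  sire <- 2L
  pop <- add_offspring(pop, dam, sire, n = 10, sex = "M")
  pop <- add_offspring(pop, dam, sire, n = 10, sex = "F")
  sons <- 11:20
  daughters <- 21:30
  for (s in sons) {
    expect_identical(pop$inds[[s]]$hom[["Y"]], pop$inds[[sire]]$hom[["Y"]])
    expect_identical(length(pop$inds[[s]]$hom[["X"]]), 1L)
    expect_identical(pop$inds[[s]]$sex, "M")
  }
  for (d in daughters) {
    expect_identical(length(pop$inds[[d]]$hom[["X"]]), 2L)
    expect_identical(length(pop$inds[[d]]$hom[["Y"]]), 0L)
    # exactly one X traces to the sire's single X (his haplotype column)
    sire_x <- pop$inds[[sire]]$hom[["X"]][[1]]$hap
    from_sire <- vapply(pop$inds[[d]]$hom[["X"]],
                        function(h) all(h$hap %in% sire_x), TRUE)
    expect_identical(sum(from_sire), 1L)
  }
  for (k in c(sons, daughters)) {
    expect_identical(pop$inds[[k]]$hom[["MT"]], pop$inds[[dam]]$hom[["MT"]])
  }
  expect_error(add_offspring(pop, dam, daughters[1]), "male")
})

test_that("random offspring sex is tied to the transmitted sex chromosome", {
  set.seed(9)
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 4, n_chrom = 1, n_snps = 20,
                     ploidy = 2, sex_chrom = TRUE, y_chrom = TRUE, seed = 108)
  f <- read_founder_vcf(fx$vcf, verbose = FALSE)
  pop <- new_population(f, build_genome(f), sexes = fx$sexes)
  pop <- add_offspring(pop, 1, 2, n = 60)
  kids <- 5:64
  sexes <- pop$ped$sex[kids]
  has_y <- vapply(kids, function(k) length(pop$inds[[k]]$hom[["Y"]]) == 1L, TRUE)
  expect_identical(sexes == "M", has_y)
  expect_gt(sum(sexes == "M"), 10) # both sexes occur under 1:1 sampling
  expect_gt(sum(sexes == "F"), 10)
})

test_that("dihaploids are homozygous genome-wide", {
  set.seed(10)
  f <- rand_founders(6, 50)
  pop <- toy_pop(f)
  for (rep in 1:20) {
    pop <- make_dihaploid(pop, parent_id = sample(6, 1))
  }
  di_ids <- 7:26
  dos <- decode_genotypes(pop, ids = di_ids)
  expect_true(all(dos %in% c(0L, 2L)))

  # dihaploid of a fully inbred parent is genotypically the parent
  inbred <- toy_founders(matrix(rep(c(0L, 1L), each = 5), 5, 2 * 1,
                                byrow = FALSE)[, c(1, 1)], ploidy = 2)
  ipop <- toy_pop(inbred, sexes = "F")
  ipop <- make_dihaploid(ipop, 1)
  expect_identical(unname(decode_genotypes(ipop, ids = 2)),
                   unname(decode_genotypes(ipop, ids = 1)))

  tet <- rand_founders(4, 10, ploidy = 4)
  tpop <- toy_pop(tet)
  expect_error(make_dihaploid(tpop, 1), "diploid")
})

test_that("F1 of opposite homozygotes has dosage one everywhere", {
  f <- dosage_founders(c(0, 2), n_snp = 8)
  pop <- toy_pop(f, sexes = c("F", "M"))
  pop <- add_offspring(pop, 1, 2, n = 3)
  expect_true(all(decode_genotypes(pop, ids = 3:5) == 1L))
})

test_that("block decode matches the naive allele-propagation oracle", {
  # the module's central correctness property, diploid and tetraploid,
  # with sex chromosomes and mitochondria in the diploid case
  set.seed(12)
  dir <- withr::local_tempdir()
  fx <- make_fixture(dir, n_founders = 8, n_chrom = 2, n_snps = 50,
                     ploidy = 2, sex_chrom = TRUE, y_chrom = TRUE, mito = TRUE,
                     seed = 109)
  f <- read_founder_vcf(fx$vcf, verbose = FALSE)
  pop <- new_population(f, build_genome(f), sexes = fx$sexes)
  res <- dual_sim(pop, n_per_gen = 6, n_generations = 4)
  dec <- decode_genotypes(res$pop)
  for (i in seq_len(pop_size(res$pop))) {
    expect_equal(unname(dec[i, ]), as.vector(naive_decode(res$naive[[i]], res$pop$genome)),
                 label = paste("diploid individual", i))
  }

  set.seed(13)
  tet <- rand_founders(6, 40, ploidy = 4, n_chr = 2)
  tpop <- toy_pop(tet)
  tres <- dual_sim(tpop, n_per_gen = 5, n_generations = 4)
  tdec <- decode_genotypes(tres$pop)
  for (i in seq_len(pop_size(tres$pop))) {
    expect_equal(unname(tdec[i, ]), as.vector(naive_decode(tres$naive[[i]], tres$pop$genome)),
                 label = paste("tetraploid individual", i))
  }
})

test_that("homolog structure stays valid across generations", {
  set.seed(14)
  tet <- rand_founders(6, 30, ploidy = 4)
  pop <- toy_pop(tet)
  res <- dual_sim(pop, n_per_gen = 8, n_generations = 3)
  for (ind in res$pop$inds) {
    for (ci in seq_along(res$pop$genome$chromosomes)) {
      expect_identical(length(ind$hom[[ci]]), 4L)
      for (h in ind$hom[[ci]]) {
        expect_false(is.unsorted(h$end, strictly = TRUE))
        expect_identical(h$end[length(h$end)],
                         res$pop$genome$chromosomes[[ci]]$length_bp)
        # normalized: no adjacent duplicate haplotype ids
        if (length(h$hap) > 1) expect_true(all(diff(h$hap) != 0))
        expect_true(all(h$hap >= 1 & h$hap <= ncol(tet$haps)))
      }
    }
  }
})

test_that("gene dropping follows the pedigree with no phenotype decisions", {
  set.seed(15)
  f <- rand_founders(4, 20)
  g <- build_genome(f)

  ped_f <- tibble::tibble(id = c("a", "b", "c", "d"), sire = "0", dam = "0",
                          sex = c("F", "M", "F", "M"))
  pop <- gene_drop(f, g, ped_f)
  expect_identical(pop_size(pop), 4L)
  expect_identical(unname(decode_genotypes(pop)),
                   unname(decode_genotypes(toy_pop(f))))

  ped <- tibble::tibble(
    id = c("f1", "m1", "f2", "m2", "k1", "k2", "k3", "gk1", "gk2", "gk3"),
    sire = c("0", "0", "0", "0", "m1", "m1", "m2", "k2", "k2", "k2"),
    dam = c("0", "0", "0", "0", "f1", "f2", "f1", "k1", "k3", "k3"),
    sex = c("F", "M", "F", "M", "F", "M", "F", "0", "0", "0")
  )
  pop2 <- gene_drop(f, g, ped)
  expect_identical(pop_size(pop2), 10L)
  imap <- attr(pop2, "id_map")
  k1 <- imap[["k1"]]
  expect_identical(pop2$ped$dam[k1], imap[["f1"]])
  expect_identical(pop2$ped$sire[k1], imap[["m1"]])
  expect_identical(max(pop2$ped$generation), 2L)

  # rows out of order are sorted; cycles and half-known parents are errors
  expect_identical(pop_size(gene_drop(f, g, ped[sample(10), ])), 10L)
  bad <- ped
  bad$dam[5] <- "0"
  expect_error(gene_drop(f, g, bad), "one known parent")
  cyc <- tibble::tibble(id = c("a", "b", "x", "y"), sire = c("0", "0", "b", "b"),
                        dam = c("0", "0", "y", "x"), sex = c("F", "M", "F", "F"))
  expect_error(gene_drop(f, g, cyc), "cycle")
})

test_that("neutral gene dropping preserves allele frequencies on average", {
  set.seed(16)
  f <- rand_founders(20, 25)
  pop <- toy_pop(f)
  ids <- integer(0)
  for (k in 1:200) {
    dam <- sample(seq(1, 19, by = 2), 1)
    sire <- sample(seq(2, 20, by = 2), 1)
    pop <- add_offspring(pop, dam, sire, n = 1)
    ids <- c(ids, pop_size(pop))
  }
  p_off <- colMeans(decode_genotypes(pop, ids = ids)) / 2
  se <- sqrt(f$freq * (1 - f$freq) / (2 * 200))
  # drift keeps the mean near the founder frequency (wide neutral bound)
  expect_true(all(abs(p_off - f$freq) < 6 * se + 0.05))
})

test_that("meiosis is reproducible under a fixed seed", {
  f <- rand_founders(4, 20)
  pop <- toy_pop(f)
  set.seed(77)
  a <- add_offspring(pop, 1, 2, n = 5)
  set.seed(77)
  b <- add_offspring(pop, 1, 2, n = 5)
  expect_identical(a$inds, b$inds)
  expect_identical(a$ped, b$ped)
})
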