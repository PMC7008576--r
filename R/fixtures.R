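#' Generate a synthetic founder data set
#'
#' Writes a self-contained set of input files for simulation and testing: a
#' valid VCF of phased founder genotypes with per-SNP allele frequencies drawn
#' from Uniform(0.05, 0.95), plus companion recombination-map, pedigree, QTN
#' (positions-only and with-effects) and chip files exercising every reader in
#' the package. Founders are unrelated with independent sites by default; with
#' `ld = TRUE` founder haplotypes are mosaics of a small shared haplotype
#' pool, creating block linkage disequilibrium for genomic-prediction tests.
#' Optional X, Y and MT chromosomes are written with sex-consistent GT fields
#' (males hemizygous on X, carrying the Y; mitochondria uniparental), padded
#' to uniform ploidy as placeholders where a sex carries fewer haplotypes.
#'
#' @param dir Output directory (created if needed).
#' @param n_founders Number of founder individuals (sexes alternate F, M).
#' @param n_chrom Number of autosomes.
#' @param n_snps Total SNPs, split evenly across chromosomes.
#' @param ploidy Even ploidy (2, 4, ...).
#' @param sex_chrom Add an X chromosome.
#' @param y_chrom Add a Y chromosome (requires `sex_chrom`).
#' @param mito Add a mitochondrial chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param ld Use the shared-haplotype-pool (block LD) mode.
#' @param n_pool Haplotype pool size in LD mode.
#' @param prefix File name prefix.
#' @param seed Optional RNG seed.
#' @return Invisibly, a list with the file paths (`vcf`, `map`, `pedigree`,
#'   `qtn`, `qtn_effects`, `chip`), the founder `sexes` and the generating
#'   frequency table `freq`.
#' @export
make_fixture <- function(dir, n_founders = 20, n_chrom = 2, n_snps = 100,
                         ploidy = 2, sex_chrom = FALSE, y_chrom = FALSE,
                         mito = FALSE, chrom_length = 1e6, ld = FALSE,
                         n_pool = 10, prefix = "fixture", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ploidy %% 2 != 0 || ploidy < 2) stop("ploidy must be an even number >= 2")
  if (min(n_founders, n_chrom, n_snps) < 1) stop("fixture parameters must be positive")
  if (y_chrom && !sex_chrom) stop("a Y chromosome requires sex_chrom = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  chroms <- c(as.character(seq_len(n_chrom)),
              if (sex_chrom) "X", if (y_chrom) "Y", if (mito) "MT")
  n_per <- rep(n_snps %/% length(chroms), length(chroms))
  n_per[seq_len(n_snps %% length(chroms))] <- n_per[1] + 1L
  if (any(n_per < 1)) stop("need at least one SNP per chromosome")

  sexes <- rep(c("F", "M"), length.out = n_founders)
  n_hap <- n_founders * ploidy

  snp_chr <- rep(chroms, n_per)
  snp_pos <- unlist(lapply(n_per, function(k) sort(sample.int(chrom_length - 1, k))))
  n_tot <- length(snp_chr)
  p <- stats::runif(n_tot, 0.05, 0.95)

  haps <- if (!ld) {
    matrix(stats::rbinom(n_tot * n_hap, 1, p), n_tot, n_hap)
  } else {
    ld_haplotypes(snp_chr, p, n_hap, n_pool, chrom_length, snp_pos)
  }

  # sex-consistent padding: placeholders never enter any individual's genome
  for (i in which(snp_chr == "X")) {
    for (f in which(sexes == "M")) {
      cols <- (f - 1) * ploidy + seq_len(ploidy)
      haps[i, cols[-1]] <- haps[i, cols[1]] # hemizygous male X
    }
    if (ploidy > 2) {
      for (f in which(sexes == "F")) {
        cols <- (f - 1) * ploidy + seq_len(ploidy)
        haps[i, cols[-(1:2)]] <- haps[i, cols[1]] # X carries at most 2 copies
      }
    }
  }
  for (i in which(snp_chr == "Y")) {
    for (f in seq_len(n_founders)) {
      cols <- (f - 1) * ploidy + seq_len(ploidy)
      haps[i, cols] <- if (sexes[f] == "M") haps[i, cols[2]] else 0L
    }
  }
  for (i in which(snp_chr == "MT")) {
    for (f in seq_len(n_founders)) {
      cols <- (f - 1) * ploidy + seq_len(ploidy)
      haps[i, cols] <- haps[i, cols[1]]
    }
  }

  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    map = file.path(dir, paste0(prefix, ".map")),
    pedigree = file.path(dir, paste0(prefix, ".ped")),
    qtn = file.path(dir, paste0(prefix, ".qtn")),
    qtn_effects = file.path(dir, paste0(prefix, "_qtn_effects.txt")),
    chip = file.path(dir, paste0(prefix, ".chip"))
  )

  write_fixture_vcf(paths$vcf, snp_chr, snp_pos, haps, ploidy,
                    paste0("S", seq_len(n_founders)), chroms, chrom_length)

  writeLines(
    c("chrom bp cM_female cM_male",
      unlist(lapply(chroms, function(ch) {
        sprintf("%s %d %.6f %.6f", ch, chrom_length,
                chrom_length * 1e-6, chrom_length * 1e-6)
      }))),
    paths$map
  )

  # small 3-generation pedigree over the first founders
  writeLines(
    c("id sire dam sex",
      paste(seq_len(n_founders), 0, 0, sexes),
      paste(n_founders + 1, 2, 1, "F"),
      paste(n_founders + 2, if (n_founders >= 4) 4 else 2,
            if (n_founders >= 3) 3 else 1, "M"),
      paste(n_founders + 3, n_founders + 2, n_founders + 1, "0")),
    paths$pedigree
  )

  auto <- which(snp_chr %in% as.character(seq_len(n_chrom)))
  n_qtn <- min(5L, length(auto))
  qtn_idx <- sort(auto[sample.int(length(auto), n_qtn)])
  writeLines(paste(snp_chr[qtn_idx], snp_pos[qtn_idx]), paths$qtn)
  writeLines(
    paste(snp_chr[qtn_idx], snp_pos[qtn_idx],
          signif(sample_gamma_effects(n_qtn), 6), 0),
    paths$qtn_effects
  )

  chip_idx <- sort(setdiff(auto, qtn_idx))
  chip_idx <- chip_idx[seq_len(max(1L, length(chip_idx) %/% 2L))]
  writeLines(paste(snp_chr[chip_idx], snp_pos[chip_idx]), paths$chip)

  invisible(c(paths, list(
    sexes = sexes,
    freq = tibble::tibble(chr = snp_chr, pos = snp_pos, p = p)
  )))
}

# Block-LD haplotypes: each founder haplotype is a mosaic of a small pool of
# base haplotypes, switching pool member at ~3 random breakpoints per
# chromosome.
ld_haplotypes <- function(snp_chr, p, n_hap, n_pool, chrom_length, snp_pos) {
  n_tot <- length(snp_chr)
  haps <- matrix(0L, n_tot, n_hap)
  for (ch in unique(snp_chr)) {
    rows <- which(snp_chr == ch)
    pool <- matrix(stats::rbinom(length(rows) * n_pool, 1, p[rows]),
                   length(rows), n_pool)
    for (h in seq_len(n_hap)) {
      nbk <- stats::rpois(1, 3)
      bks <- sort(stats::runif(nbk, 0, chrom_length))
      seg <- findInterval(snp_pos[rows], bks) + 1L
      src <- sample.int(n_pool, length(bks) + 1L, replace = TRUE)
      haps[rows, h] <- pool[cbind(seq_along(rows), src[seg])]
    }
  }
  haps
}

write_fixture_vcf <- function(path, chr, pos, haps, ploidy, sample_ids,
                              contigs, chrom_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=breedsim fixture generator (synthetic data)",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(chrom_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  n_sam <- length(sample_ids)
  gt <- vapply(seq_len(n_sam), function(s) {
    cols <- (s - 1) * ploidy + seq_len(ploidy)
    do.call(paste, c(lapply(cols, function(cc) haps[, cc]), list(sep = "|")))
  }, character(nrow(haps)))
  body <- paste(
    chr, as.integer(pos), paste0("snp", seq_along(chr)), "A", "T", ".",
    "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}
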