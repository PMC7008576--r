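#' @importFrom rlang .data
NULL

# Construct the founder-panel container. haps: integer 0/1 matrix, one row per
# SNP, ploidy columns per founder (founder f owns columns
# (f-1)*ploidy + 1..ploidy). snps: tibble(chr, pos) aligned with rows.
new_founders <- function(haps, snps, ploidy, founder_ids) {
  stopifnot(ncol(haps) == length(founder_ids) * ploidy, nrow(haps) == nrow(snps))
  structure(
    list(
      haps = haps,
      snps = snps,
      ploidy = as.integer(ploidy),
      n_founders = length(founder_ids),
      founder_ids = as.character(founder_ids),
      freq = rowMeans(haps)
    ),
    class = "bs_founders"
  )
}

#' @export
print.bs_founders <- function(x, ...) {
  cat("<bs_founders>", x$n_founders, "founders | ploidy", x$ploidy, "|",
      nrow(x$snps), "SNPs on", length(unique(x$snps$chr)), "chromosome(s)\n")
  invisible(x)
}

#' Read founder genotypes from a VCF file
#'
#' Loads phased founder haplotypes from a VCF (plain or gzipped). Ploidy is
#' auto-detected from the number of alleles in the GT field and must be
#' uniform across samples and sites. Multi-allelic sites are dropped (with a
#' message); unphased separators (`/`) are accepted and the within-GT allele
#' order is taken as phase. Missing allele calls are imputed by drawing allele
#' 1 with the site's observed allele frequency, so seed the RNG for
#' reproducibility.
#'
#' @param path Path to the VCF file.
#' @param seqfile Optional path; when given, a SNP-position table
#'   (chromosome, bp, index) is written there as tab-separated text.
#' @param verbose Print a load summary.
#' @return An object of class `bs_founders`: the phased 0/1 haplotype matrix
#'   (`haps`), the SNP table (`snps`), the detected `ploidy`, founder ids and
#'   per-SNP allele-1 frequencies (`freq`).
#' @export
read_founder_vcf <- function(path, seqfile = NULL, verbose = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("no GT fields found in ", path)

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (verbose) message("dropping ", sum(multi), " multi-allelic site(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (!nrow(gt)) stop("no biallelic SNPs left in ", path)

  parsed <- parse_gt_matrix(gt)
  haps <- impute_missing_haplotypes(parsed$haps)

  snps <- tibble::tibble(
    chr = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"])
  )
  ord <- order(match(snps$chr, unique(snps$chr)), snps$pos)
  snps <- snps[ord, ]
  haps <- haps[ord, , drop = FALSE]
  dup <- duplicated(paste(snps$chr, snps$pos))
  if (any(dup)) {
    if (verbose) message("dropping ", sum(dup), " duplicate position(s)")
    snps <- snps[!dup, ]
    haps <- haps[!dup, , drop = FALSE]
  }

  f <- new_founders(haps, snps, parsed$ploidy, colnames(gt))
  if (verbose) {
    message(
      "read ", f$n_founders, " founders, ploidy ", f$ploidy, ", ",
      nrow(f$snps), " SNPs on ", length(unique(f$snps$chr)), " chromosome(s)"
    )
  }
  if (!is.null(seqfile)) write_seqfile(f, seqfile)
  f
}

# Split a character GT matrix (rows SNPs x cols samples) into per-haplotype
# integer columns; enforces uniform ploidy and biallelic 0/1 codes. Missing
# alleles ('.') become NA.
parse_gt_matrix <- function(gt) {
  gtv <- as.vector(gt)
  miss_cell <- is.na(gtv) # fully missing calls (e.g. '.')
  alleles <- strsplit(gtv, "[/|]")
  ploidy <- unique(lengths(alleles[!miss_cell]))
  if (!length(ploidy)) stop("all GT calls are missing")
  if (length(ploidy) == 1 && any(miss_cell)) {
    alleles[miss_cell] <- list(rep(NA_character_, ploidy))
  }
  if (length(ploidy) != 1) {
    stop("mixed ploidy in GT fields: found ", paste(sort(ploidy), collapse = ", "),
         " alleles per call")
  }
  if (ploidy < 2 || ploidy %% 2 != 0) {
    stop("ploidy must be an even number >= 2, got ", ploidy)
  }
  flat <- suppressWarnings(as.integer(unlist(alleles)))
  if (any(stats::na.omit(flat) > 1)) stop("GT allele codes > 1 at a biallelic site")
  # unlist order: SNP varies fastest within sample column, alleles innermost
  n_snp <- nrow(gt)
  n_sam <- ncol(gt)
  arr <- array(flat, dim = c(ploidy, n_snp, n_sam))
  haps <- matrix(NA_integer_, n_snp, n_sam * ploidy)
  for (s in seq_len(n_sam)) {
    haps[, (s - 1L) * ploidy + seq_len(ploidy)] <- t(arr[, , s])
  }
  list(haps = haps, ploidy = as.integer(ploidy))
}

# Impute missing allele calls: draw allele 1 with the site's observed
# frequency (sites entirely missing fall back to 0.5).
impute_missing_haplotypes <- function(haps) {
  miss <- is.na(haps)
  if (!any(miss)) return(haps)
  p <- rowMeans(haps, na.rm = TRUE)
  p[is.nan(p)] <- 0.5
  idx <- which(miss, arr.ind = TRUE)
  haps[idx] <- as.integer(stats::runif(nrow(idx)) < p[idx[, 1]])
  haps
}

write_seqfile <- function(founders, path) {
  utils::write.table(
    data.frame(
      chrom = founders$snps$chr, bp = founders$snps$pos,
      index = seq_len(nrow(founders$snps))
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read founder genotypes from plink-like PED/MAP files
#'
#' Reads the classic 6-column PED text dialect (family, id, father, mother,
#' sex, phenotype, then two allele columns per SNP) with a 4-column MAP
#' (chromosome, snp id, cM, bp). Diploid only; alleles are recoded to 0/1 with
#' the first-observed allele per SNP as 0, and `0` allele codes treated as
#' missing (imputed as in [read_founder_vcf()]).
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param verbose Print a load summary.
#' @return A `bs_founders` object (ploidy 2).
#' @export
read_pedlike <- function(ped_path, map_path, verbose = TRUE) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) != 4) stop("MAP file must have 4 columns (chr, id, cM, bp)")
  names(map) <- c("chr", "id", "cm", "bp")

  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp) {
    stop("PED file has ", ncol(ped), " columns; expected ", 6 + 2 * n_snp,
         " for ", n_snp, " SNPs (diploid only)")
  }
  ids <- ped[[2]]
  allele_cols <- as.matrix(ped[, -(1:6), drop = FALSE])

  haps <- matrix(NA_integer_, n_snp, 2 * nrow(ped))
  for (j in seq_len(n_snp)) {
    obs <- allele_cols[, c(2 * j - 1, 2 * j)]
    in_read_order <- as.vector(t(obs)) # individual by individual
    lev <- unique(in_read_order[in_read_order != "0"])
    if (length(lev) > 2) {
      stop("SNP ", map$id[j], " has more than two alleles: ",
           paste(lev, collapse = ", "))
    }
    code <- match(obs, lev) - 1L # first observed allele -> 0
    haps[j, ] <- as.integer(t(matrix(code, nrow(ped), 2)))
  }
  haps <- impute_missing_haplotypes(haps)

  snps <- tibble::tibble(chr = as.character(map$chr), pos = as.numeric(map$bp))
  ord <- order(match(snps$chr, unique(snps$chr)), snps$pos)
  f <- new_founders(haps[ord, , drop = FALSE], snps[ord, ], 2L, ids)
  if (verbose) {
    message("read ", f$n_founders, " diploid founders, ", nrow(f$snps), " SNPs")
  }
  f
}

#' Filter founder SNPs by minimum allele frequency
#'
#' Removes SNPs whose minor allele frequency `min(p, 1-p)` is below
#' `min_maf`; frequencies are recomputed on the retained panel. Build (or
#' rebuild) the genome from the filtered panel so SNP indices stay aligned.
#'
#' @param founders A `bs_founders` panel.
#' @param min_maf Threshold in `[0, 0.5]`.
#' @return The filtered `bs_founders` panel.
#' @export
maf_filter <- function(founders, min_maf) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  maf <- pmin(founders$freq, 1 - founders$freq)
  keep <- maf >= min_maf
  new_founders(
    founders$haps[keep, , drop = FALSE],
    founders$snps[keep, ],
    founders$ploidy, founders$founder_ids
  )
}
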