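# In-code founder/population builders used across tests.

toy_founders <- function(haps, chr = NULL, pos = NULL, ploidy = 2, ids = NULL) {
  haps <- as.matrix(haps)
  n_snp <- nrow(haps)
  if (is.null(chr)) chr <- rep("1", n_snp)
  if (is.null(pos)) pos <- ave(seq_len(n_snp), chr, FUN = seq_along) * 1000
  if (is.null(ids)) ids <- paste0("F", seq_len(ncol(haps) / ploidy))
  breedsim:::new_founders(haps, tibble::tibble(chr = chr, pos = pos),
                          as.integer(ploidy), ids)
}

# Random unlinked founder panel entirely in code.
rand_founders <- function(n_f, n_snp, ploidy = 2, n_chr = 1, maf_range = c(0.1, 0.9)) {
  p <- stats::runif(n_snp, maf_range[1], maf_range[2])
  haps <- matrix(stats::rbinom(n_snp * n_f * ploidy, 1, p), n_snp, n_f * ploidy)
  chr <- as.character(rep(seq_len(n_chr), length.out = n_snp))
  chr <- sort(chr)
  toy_founders(haps, chr = chr, ploidy = ploidy)
}

# Founder panel whose founder f has a constant genotype: `dosages[f]` copies
# of allele 1 at every SNP (handy for exact genotypic-value checks).
dosage_founders <- function(dosages, n_snp = 3, ploidy = 2) {
  haps <- do.call(cbind, lapply(dosages, function(d) {
    matrix(rep(c(rep(1L, d), rep(0L, ploidy - d)), each = n_snp), n_snp, ploidy)
  }))
  toy_founders(haps, ploidy = ploidy)
}

toy_pop <- function(founders, sexes = NULL, map_file = NULL, chrom_kinds = NULL) {
  genome <- build_genome(founders, map_file = map_file, chrom_kinds = chrom_kinds)
  new_population(founders, genome, sexes = sexes)
}
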