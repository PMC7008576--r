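#' PCA of genotype dosages
#'
#' Principal components of the column-centred dosage matrix (no variance
#' standardization). Deterministic up to component sign.
#'
#' @param pop A `bs_pop` population, or a dosage matrix with ids as rownames.
#' @param n_components Number of components (truncated with a warning if it
#'   exceeds the matrix rank).
#' @param chip Optional `bs_chip` restricting the SNP set.
#' @param ids Individuals to include (default all).
#' @return A `bs_pca` object: `scores` tibble (`id`, `generation` if known,
#'   `PC1`, ...) and `var_explained` (proportion per component). `tidy()`
#'   returns the scores.
#' @export
pca_genotypes <- function(pop, n_components = 2, chip = NULL, ids = NULL) {
  if (inherits(pop, "bs_pop")) {
    if (is.null(ids)) ids <- pop$ped$id
    M <- decode_genotypes(pop, ids, if (is.null(chip)) NULL else chip$snps)
    gen <- pop$ped$generation[match(ids, pop$ped$id)]
  } else {
    M <- as.matrix(pop)
    ids <- if (is.null(rownames(M))) seq_len(nrow(M)) else rownames(M)
    gen <- NULL
  }
  if (nrow(M) < 2) stop("PCA needs at least two individuals")
  M[is.na(M)] <- 0
  keep <- apply(M, 2, function(x) stats::var(x) > 0)
  if (!any(keep)) stop("PCA needs at least one polymorphic SNP")
  M <- M[, keep, drop = FALSE]

  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    n_components <- rank
  }
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(id = ids), scores)
  if (!is.null(gen)) scores$generation <- gen
  structure(
    list(
      scores = scores,
      var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
    ),
    class = "bs_pca"
  )
}

#' @export
print.bs_pca <- function(x, ...) {
  cat("<bs_pca>", nrow(x$scores), "individuals |",
      length(x$var_explained), "components (",
      paste0(signif(100 * x$var_explained, 3), "%", collapse = ", "), ")\n")
  invisible(x)
}

#' Single-marker GWAS
#'
#' Per-SNP least-squares regression of the phenotype on allele dosage with
#' two-sided t-test p-values and Benjamini-Hochberg q-values. Optionally the
#' phenotype is first residualized on the leading genotype principal
#' components (population-structure correction). Monomorphic SNPs are reported
#' with effect 0 and p = 1.
#'
#' @param pop A phenotyped `bs_pop` population.
#' @param trait Trait index.
#' @param chip Optional `bs_chip` restricting the SNP set.
#' @param ids Individuals included (default all).
#' @param n_pcs Number of leading PCs to residualize the phenotype on (0 =
#'   none).
#' @return A tibble of class `bs_gwas`: `snp`, `chr`, `pos`, `effect`, `se`,
#'   `p`, `q`.
#' @export
gwas <- function(pop, trait = 1, chip = NULL, ids = NULL, n_pcs = 0) {
  if (is.null(pop$y)) stop("population has no phenotypes")
  if (is.null(ids)) ids <- pop$ped$id
  snps <- if (is.null(chip)) seq_len(nrow(pop$genome$snps)) else chip$snps
  M <- decode_genotypes(pop, ids, snps)
  y <- pop$y[match(ids, rownames(pop$y)), trait]
  gwas_scan(y, M, chr = pop$genome$snps$chr[snps],
            pos = pop$genome$snps$pos[snps], snp = snps, n_pcs = n_pcs)
}

#' GWAS on raw matrices
#'
#' @param y Phenotype vector.
#' @param M Dosage matrix, individuals x SNPs (rows aligned with `y`).
#' @param chr,pos,snp Optional SNP annotation vectors.
#' @param n_pcs Leading genotype PCs to residualize `y` on.
#' @return A `bs_gwas` tibble; see [gwas()].
#' @export
gwas_scan <- function(y, M, chr = NULL, pos = NULL, snp = NULL, n_pcs = 0) {
  M <- as.matrix(M)
  if (length(y) != nrow(M)) stop("phenotype and dosage rows are not aligned")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  M[is.na(M)] <- 0
  n <- length(y)

  if (n_pcs > 0) {
    sc <- pca_genotypes(M, n_components = n_pcs)$scores
    pcs <- as.matrix(sc[, grep("^PC", names(sc)), drop = FALSE])
    y <- stats::resid(stats::lm(y ~ pcs))
  }
  df <- n - 2 - n_pcs
  if (df < 1) stop("not enough residual degrees of freedom")

  xm <- colMeans(M)
  yc <- y - mean(y)
  sxx <- colSums(M^2) - n * xm^2
  sxy <- as.vector(crossprod(M, yc))
  mono <- sxx <= 1e-12
  beta <- ifelse(mono, 0, sxy / sxx)
  sse <- pmax(sum(yc^2) - beta^2 * sxx, 0)
  se <- ifelse(mono, NA_real_, sqrt(sse / df / sxx))
  tstat <- beta / se
  p <- ifelse(mono, 1, 2 * stats::pt(-abs(tstat), df))
  out <- tibble::tibble(
    snp = if (is.null(snp)) seq_len(ncol(M)) else snp,
    chr = if (is.null(chr)) rep("1", ncol(M)) else as.character(chr),
    pos = if (is.null(pos)) seq_len(ncol(M)) else pos,
    effect = beta, se = se, p = p,
    q = stats::p.adjust(p, method = "BH")
  )
  class(out) <- c("bs_gwas", class(out))
  out
}

#' Per-generation population summary
#'
#' One row per generation with counts and the mean and variance of phenotypes
#' and genotypic values, recomputed from the stored values.
#'
#' @param pop A `bs_pop` population.
#' @param trait Trait index (ignored when no phenotypes exist).
#' @return A tibble: `generation`, `n`, `n_female`, `n_male` and, when
#'   phenotyped, `mean_y`, `var_y`, `mean_g`, `var_g`.
#' @export
summarize_population <- function(pop, trait = 1) {
  base <- pop$ped |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_female = sum(.data$sex == "F"),
      n_male = sum(.data$sex == "M"),
      .groups = "drop"
    )
  if (is.null(pop$y)) return(base)
  ph <- tibble::tibble(
    generation = pop$ped$generation,
    y = pop$y[match(pop$ped$id, rownames(pop$y)), trait],
    g = pop$g[match(pop$ped$id, rownames(pop$g)), trait]
  ) |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      mean_y = mean(.data$y), var_y = stats::var(.data$y),
      mean_g = mean(.data$g), var_g = stats::var(.data$g),
      .groups = "drop"
    )
  dplyr::left_join(base, ph, by = "generation")
}
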