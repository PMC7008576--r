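#' Sample signed QTN effects from a gamma distribution
#'
#' Effect magnitudes are gamma-distributed (default shape 0.2, scale 5, so the
#' mean magnitude is 1) and signs are positive or negative with equal
#' probability, avoiding directional bias in the founder population.
#'
#' @param n Number of effects.
#' @param shape,scale Gamma parameters (scale, not rate).
#' @return Numeric vector of signed effects.
#' @export
sample_gamma_effects <- function(n, shape = 0.2, scale = 5) {
  mag <- stats::rgamma(n, shape = shape, scale = scale)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

new_architecture <- function(qtn, chr, pos, a, d, mu, h2,
                             shape = 0.2, scale = 5) {
  a <- as.matrix(a)
  d <- as.matrix(d)
  n_traits <- ncol(a)
  stopifnot(nrow(a) == length(qtn), all(dim(a) == dim(d)),
            length(mu) == n_traits, length(h2) == n_traits)
  if (any(h2 <= 0 | h2 > 1)) stop("heritabilities must be in (0, 1]")
  structure(
    list(
      qtn = as.integer(qtn), chr = chr, pos = pos,
      a = a, d = d, mu = as.numeric(mu), h2 = as.numeric(h2),
      var_e = rep(NA_real_, n_traits), n_traits = n_traits,
      shape = shape, scale = scale
    ),
    class = "bs_arch"
  )
}

#' @export
print.bs_arch <- function(x, ...) {
  cat("<bs_arch>", length(x$qtn), "QTN |", x$n_traits, "trait(s) | H2 =",
      paste(signif(x$h2, 3), collapse = ", "))
  if (!anyNA(x$var_e)) cat(" | Var(e) =", paste(signif(x$var_e, 4), collapse = ", "))
  cat("\n")
  invisible(x)
}

# match (chr, pos) pairs against the genome SNP table -> global indices
match_qtn_positions <- function(genome, chr, pos) {
  key <- paste(genome$snps$chr, genome$snps$pos)
  idx <- match(paste(as.character(chr), as.numeric(pos)), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("QTN position not in the SNP list: ", chr[miss], ":", pos[miss])
  }
  idx
}

#' Random QTN architecture
#'
#' The random option: `n_qtn` positions drawn uniformly without replacement
#' from the segregating SNPs and additive effects sampled with
#' [sample_gamma_effects()]. Single trait, additive only. QTN stay in the
#' sequence SNP set; define a chip that excludes them to remove them from
#' evaluation.
#'
#' @param pop A `bs_pop` population.
#' @param n_qtn Number of QTN (<= number of segregating SNPs).
#' @param h2 Target broad-sense heritability in (0, 1].
#' @param shape,scale Gamma parameters for effect magnitudes.
#' @param mu Trait intercept.
#' @return A `bs_arch` object (environmental variance still uncalibrated; it
#'   is set when the architecture is attached with [attach_architecture()]).
#' @export
random_architecture <- function(pop, n_qtn, h2, shape = 0.2, scale = 5, mu = 0) {
  p <- pop$founders$freq
  seg <- which(p > 0 & p < 1)
  if (n_qtn > length(seg)) {
    stop("n_qtn (", n_qtn, ") exceeds the ", length(seg), " segregating SNPs")
  }
  qtn <- sort(seg[sample.int(length(seg), n_qtn)])
  a <- sample_gamma_effects(n_qtn, shape, scale)
  new_architecture(
    qtn, pop$genome$snps$chr[qtn], pop$genome$snps$pos[qtn],
    a = matrix(a, ncol = 1), d = matrix(0, length(qtn), 1),
    mu = mu, h2 = h2, shape = shape, scale = scale
  )
}

#' QTN architecture from specified positions
#'
#' The positions-file option: QTN positions are given (file or data frame with
#' columns `chr`, `pos`) and additive effects are sampled from the gamma
#' distribution. Single trait, additive only.
#'
#' @inheritParams random_architecture
#' @param positions Path to a whitespace-delimited file (`chrom bp` per line)
#'   or a data frame with columns `chr` and `pos`.
#' @return A `bs_arch` object.
#' @export
architecture_from_positions <- function(pop, positions, h2,
                                        shape = 0.2, scale = 5, mu = 0) {
  if (is.character(positions)) positions <- read_qtn_file(positions)
  idx <- match_qtn_positions(pop$genome, positions$chr, positions$pos)
  a <- sample_gamma_effects(length(idx), shape, scale)
  new_architecture(
    idx, pop$genome$snps$chr[idx], pop$genome$snps$pos[idx],
    a = matrix(a, ncol = 1), d = matrix(0, length(idx), 1),
    mu = mu, h2 = h2, shape = shape, scale = scale
  )
}

#' QTN architecture with explicit effects (multi-trait)
#'
#' The full-file option: positions plus additive and dominance effects per
#' trait, read verbatim. To simulate no pleiotropy, give each trait's QTN zero
#' effects on all other traits; environmental correlations are always zero.
#'
#' @inheritParams random_architecture
#' @param effects Path to a whitespace-delimited file (`chrom bp a1 d1
#'   [a2 d2 ...]` per line) or a data frame with columns `chr`, `pos`, then
#'   `a`/`d` pairs per trait.
#' @param h2 Vector of target heritabilities, one per trait.
#' @param mu Vector of intercepts (recycled).
#' @return A `bs_arch` object.
#' @export
architecture_from_effects <- function(pop, effects, h2, mu = 0) {
  if (is.character(effects)) effects <- read_qtn_file(effects)
  eff <- as.data.frame(effects)
  if (ncol(eff) < 4 || (ncol(eff) - 2) %% 2 != 0) {
    stop("effects need columns chr, pos, then an a/d pair per trait")
  }
  n_traits <- (ncol(eff) - 2) %/% 2
  if (length(h2) != n_traits) {
    stop("need one h2 per trait (", n_traits, " traits in file)")
  }
  idx <- match_qtn_positions(pop$genome, eff[[1]], eff[[2]])
  a <- as.matrix(eff[, 2 + 2 * seq_len(n_traits) - 1, drop = FALSE])
  d <- as.matrix(eff[, 2 + 2 * seq_len(n_traits), drop = FALSE])
  storage.mode(a) <- storage.mode(d) <- "double"
  new_architecture(
    idx, pop$genome$snps$chr[idx], pop$genome$snps$pos[idx],
    a = a, d = d, mu = rep_len(mu, n_traits), h2 = h2
  )
}

#' Read a QTN file
#'
#' Whitespace-delimited: `chrom bp` per line (positions only) or `chrom bp`
#' followed by additive/dominance pairs per trait. Optional header detected by
#' a non-numeric second field.
#'
#' @param path File path.
#' @return A tibble with columns `chr`, `pos` and, if present, `a1`, `d1`, ...
#' @export
read_qtn_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  if (length(fields) &&
      is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1]
  }
  if (!length(fields)) stop("empty QTN file: ", path)
  nf <- unique(lengths(fields))
  if (length(nf) != 1) stop("ragged QTN file: ", path)
  out <- tibble::tibble(
    chr = vapply(fields, `[[`, "", 1L),
    pos = as.numeric(vapply(fields, `[[`, "", 2L))
  )
  if (nf > 2) {
    ex <- matrix(as.numeric(unlist(lapply(fields, `[`, -(1:2)))),
                 nrow = length(fields), byrow = TRUE)
    n_traits <- (nf - 2) %/% 2
    colnames(ex) <- paste0(rep(c("a", "d"), n_traits),
                           rep(seq_len(n_traits), each = 2))
    out <- dplyr::bind_cols(out, tibble::as_tibble(ex))
  }
  out
}

#' Genotypic values
#'
#' Computes per-individual, per-trait genotypic values from QTN dosages. For
#' diploids `g = sum gamma_j a_j + sum delta_j d_j` with `gamma` coded -1, 0,
#' 1 for the reference homozygote, heterozygote and alternative homozygote and
#' `delta = 1` only for heterozygotes. For polyploids `g = sum eta_j a_j +
#' sum phi_j d_j`, where `eta` is the '1'-allele dosage minus half the ploidy
#' and `phi = 1` for every genotype carrying at least one '1' allele (all
#' heterozygotes share the complete '1' homozygote's dominance value).
#'
#' @param pop A `bs_pop` population.
#' @param arch A `bs_arch` architecture.
#' @param ids Individual ids (default all).
#' @return Numeric matrix, individuals x traits.
#' @export
genotypic_value <- function(pop, arch, ids = NULL) {
  if (is.null(ids)) ids <- pop$ped$id
  if (!length(arch$qtn)) {
    return(matrix(0, length(ids), arch$n_traits, dimnames = list(ids, NULL)))
  }
  Q <- decode_genotypes(pop, ids, arch$qtn)
  ploidy <- pop$genome$ploidy
  if (ploidy == 2L) {
    add <- Q - 1
    dom <- (Q == 1) * 1
  } else {
    add <- Q - ploidy / 2
    dom <- (Q >= 1) * 1
  }
  add[is.na(Q)] <- 0 # structurally absent loci (e.g. Y in females)
  dom[is.na(Q)] <- 0
  g <- add %*% arch$a + dom %*% arch$d
  rownames(g) <- ids
  g
}

#' Calibrate environmental variance to a target heritability
#'
#' `Var(e) = Var(g) x (1 - H2) / H2`, with `Var(g)` the population variance
#' (divisor n) of base-population genotypic values, dominance included --
#' H2 is broad sense.
#'
#' @param g Numeric vector of founder genotypic values for one trait.
#' @param h2 Target broad-sense heritability in (0, 1].
#' @return The environmental variance.
#' @export
calibrate_var_e <- function(g, h2) {
  if (length(h2) != 1 || is.na(h2) || h2 <= 0 || h2 > 1) {
    stop("h2 must be a single value in (0, 1]")
  }
  if (length(g) < 2) stop("need at least two founders to calibrate Var(e)")
  var_g <- mean((g - mean(g))^2)
  if (h2 == 1) return(0)
  if (var_g == 0) {
    stop("founder genotypic variance is zero; cannot calibrate Var(e) for h2 < 1")
  }
  var_g * (1 - h2) / h2
}

#' Attach an architecture and phenotype the population
#'
#' Calibrates the environmental variance of each trait against the base
#' population's genotypic variance, then simulates phenotypes
#' `y = mu + g + e`, `e ~ N(0, Var(e))`, independently per individual and
#' trait (environmental correlations are zero). Individuals added later are
#' phenotyped at birth.
#'
#' @param pop A `bs_pop` population.
#' @param arch A `bs_arch` architecture.
#' @return The population with `g`, `e`, `y` matrices and `arch` set.
#' @export
attach_architecture <- function(pop, arch) {
  base_ids <- pop$ped$id[pop$ped$base]
  g_base <- genotypic_value(pop, arch, base_ids)
  arch$var_e <- vapply(
    seq_len(arch$n_traits),
    function(t) calibrate_var_e(g_base[, t], arch$h2[t]),
    0
  )
  pop$arch <- arch
  # keep the elements present-but-empty ($<- NULL would drop them and `$g`
  # would then partial-match `$genome`)
  pop["g"] <- pop["e"] <- pop["y"] <- list(NULL)
  phenotype_individuals(pop, pop$ped$id)
}

# Simulate phenotypes for the given ids and append/overwrite their rows of the
# population's g/e/y matrices.
phenotype_individuals <- function(pop, ids) {
  arch <- pop$arch
  g <- genotypic_value(pop, arch, ids)
  e <- matrix(
    stats::rnorm(length(ids) * arch$n_traits),
    length(ids), arch$n_traits
  ) %*% diag(sqrt(arch$var_e), arch$n_traits)
  y <- sweep(g + e, 2, arch$mu, "+")
  rownames(e) <- rownames(y) <- ids
  pop$g <- rbind(pop[["g"]], g)
  pop$e <- rbind(pop[["e"]], e)
  pop$y <- rbind(pop[["y"]], y)
  pop
}

#' Phenotype and pedigree table
#'
#' @param pop A phenotyped `bs_pop` population.
#' @return A tibble in long format: `id`, `sex`, `generation`, `trait`, `g`,
#'   `e`, `y`.
#' @export
phenotypes <- function(pop) {
  if (is.null(pop$arch)) stop("population has no attached architecture")
  n_traits <- pop$arch$n_traits
  purrr::map_dfr(seq_len(n_traits), function(t) {
    tibble::tibble(
      id = pop$ped$id, sex = pop$ped$sex, generation = pop$ped$generation,
      trait = t,
      g = pop$g[match(pop$ped$id, rownames(pop$g)), t],
      e = pop$e[match(pop$ped$id, rownames(pop$e)), t],
      y = pop$y[match(pop$ped$id, rownames(pop$y)), t]
    )
  })
}

#' Per-QTN variance decomposition
#'
#' For each trait and QTN, the allele substitution effect
#' `alpha = a + d(1 - 2p)` (p = '1'-allele frequency) and, for diploids, the
#' one-locus equilibrium variances `V_A = 2p(1-p)alpha^2` and
#' `V_D = (2p(1-p)d)^2`. For polyploids the per-QTN additive and dominance
#' variances are computed empirically from the genotype frequencies of the
#' evaluated individuals (`V_A = a^2 Var(dosage)`, `V_D = d^2 Var(phi)`).
#' Rows carry the MAF-sorted cumulative variance share used in diagnostic
#' plots.
#'
#' @param pop A `bs_pop` population.
#' @param arch A `bs_arch` architecture.
#' @param ids Individuals whose allele frequencies are used (default the base
#'   population).
#' @return A tibble of class `bs_qtnvar`: `trait`, `chr`, `pos`, `p`, `maf`,
#'   `a`, `d`, `alpha`, `var_a`, `var_d`, `cum_var` (cumulative total variance
#'   when QTN are sorted by MAF within trait).
#' @export
qtn_variance <- function(pop, arch, ids = NULL) {
  if (is.null(ids)) ids <- pop$ped$id[pop$ped$base]
  Q <- decode_genotypes(pop, ids, arch$qtn)
  ploidy <- pop$genome$ploidy
  p <- colMeans(Q, na.rm = TRUE) / ploidy
  pop_var <- function(x) mean((x - mean(x))^2)

  out <- purrr::map_dfr(seq_len(arch$n_traits), function(t) {
    a <- arch$a[, t]
    d <- arch$d[, t]
    alpha <- a + d * (1 - 2 * p)
    if (ploidy == 2L) {
      var_a <- 2 * p * (1 - p) * alpha^2
      var_d <- (2 * p * (1 - p) * d)^2
    } else {
      var_a <- a^2 * apply(Q, 2, pop_var)
      phi <- (Q >= 1) * 1
      var_d <- d^2 * apply(phi, 2, pop_var)
    }
    tibble::tibble(
      trait = t, chr = arch$chr, pos = arch$pos,
      p = p, maf = pmin(p, 1 - p), a = a, d = d, alpha = alpha,
      var_a = var_a, var_d = var_d
    )
  })
  out <- out |>
    dplyr::group_by(.data$trait) |>
    dplyr::arrange(.data$maf, .by_group = TRUE) |>
    dplyr::mutate(cum_var = cumsum(.data$var_a + .data$var_d)) |>
    dplyr::ungroup()
  class(out) <- c("bs_qtnvar", class(out))
  out
}
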