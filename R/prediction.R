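#' Define a SNP chip
#'
#' A chip is a named subset of genome SNPs emulating a genotyping array; it
#' may exclude the QTN so causal loci do not enter the evaluation.
#'
#' @param snps Integer vector of SNP indices into the genome SNP list.
#' @param name Chip label.
#' @param genome Optional genome for range validation.
#' @return An object of class `bs_chip`.
#' @export
chip <- function(snps, name = "chip", genome = NULL) {
  snps <- as.integer(snps)
  if (anyDuplicated(snps)) stop("chip SNP indices must be unique")
  if (any(snps < 1)) stop("chip SNP indices must be positive")
  if (!is.null(genome) && any(snps > nrow(genome$snps))) {
    stop("chip SNP index beyond the genome SNP list")
  }
  structure(list(name = name, snps = sort(snps)), class = "bs_chip")
}

#' Random SNP chip
#'
#' Samples `n` SNP indices uniformly, optionally excluding a set (typically
#' the QTN of an architecture).
#'
#' @param pop A `bs_pop` population.
#' @param n Number of chip SNPs.
#' @param exclude Integer indices to exclude (e.g. `arch$qtn`).
#' @param name Chip label.
#' @return A `bs_chip`.
#' @export
random_chip <- function(pop, n, exclude = NULL, name = "chip") {
  avail <- setdiff(seq_len(nrow(pop$genome$snps)), exclude)
  if (n > length(avail)) stop("not enough SNPs available for the chip")
  chip(sort(avail[sample.int(length(avail), n)]), name = name, genome = pop$genome)
}

#' Read a chip file
#'
#' One SNP per line: either `chrom bp` pairs or a single column of SNP
#' indices.
#'
#' @param path File path.
#' @param genome The genome used to resolve `chrom bp` pairs.
#' @param name Chip label (default the file name).
#' @return A `bs_chip`.
#' @export
read_chip_file <- function(path, genome, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  if (length(fields) &&
      is.na(suppressWarnings(as.numeric(fields[[1]][length(fields[[1]])])))) {
    fields <- fields[-1]
  }
  nf <- unique(lengths(fields))
  if (length(nf) != 1 || !nf %in% c(1, 2)) {
    stop("chip file must have 1 (index) or 2 (chrom bp) columns")
  }
  idx <- if (nf == 1) {
    as.integer(vapply(fields, `[[`, "", 1L))
  } else {
    match_qtn_positions(
      genome,
      vapply(fields, `[[`, "", 1L),
      as.numeric(vapply(fields, `[[`, "", 2L))
    )
  }
  chip(idx, name = name, genome = genome)
}

#' Genomic relationship matrix
#'
#' VanRaden's first method: `G = XX' / (k sum p_j (1 - p_j))` with dosages
#' column-centred by their mean `k p_j` (k = ploidy, 2 for diploids).
#' Diagonal elements are then multiplied by 1.05 to avoid singularity.
#'
#' @param dosages Individuals x SNPs dosage matrix (0..ploidy), rownames ids.
#' @param freq Allele frequencies `p_j`; default computed from `dosages`
#'   (i.e. from the evaluated individuals).
#' @param ploidy Ploidy of the dosage coding.
#' @param inflate_diag Diagonal safeguard factor (1.05; set 1 to disable).
#' @return Symmetric relationship matrix with the input rownames.
#' @export
compute_G <- function(dosages, freq = NULL, ploidy = 2, inflate_diag = 1.05) {
  if (is.null(freq)) freq <- colMeans(dosages, na.rm = TRUE) / ploidy
  freq[is.nan(freq)] <- 0
  den <- ploidy * sum(freq * (1 - freq))
  if (den <= 0) {
    stop("all chip SNPs are monomorphic; the G denominator is degenerate")
  }
  X <- sweep(dosages, 2, ploidy * freq)
  X[is.na(X)] <- 0 # structurally absent loci contribute no deviation
  G <- tcrossprod(X) / den
  diag(G) <- diag(G) * inflate_diag
  G
}

#' Pedigree (numerator) relationship matrix
#'
#' Standard tabular recursion; founders are taken as unrelated and
#' non-inbred. The pedigree must be sorted so parents precede offspring.
#'
#' @param ped Data frame with columns `id`, `dam`, `sire` (0 or `NA` =
#'   unknown).
#' @return Symmetric A matrix with ids as dimnames.
#' @export
compute_A <- function(ped) {
  ped <- as.data.frame(ped)
  id <- as.character(ped$id)
  n <- length(id)
  pmatch_idx <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "")] <- NA
    m <- match(x, id)
    if (any(!is.na(x) & is.na(m))) stop("pedigree references an unknown parent id")
    m
  }
  di <- pmatch_idx(ped$dam)
  si <- pmatch_idx(ped$sire)
  if (any(stats::na.omit(c(di > seq_len(n), si > seq_len(n))))) {
    stop("pedigree is not sorted parents-first")
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- A[j, i] <- aj
    }
  }
  A
}

#' Inverse of the single-step relationship matrix
#'
#' The basic single-step combination: `H^-1 = A^-1` plus the block addition of
#' `G^-1 - A22^-1` on the genotyped individuals, with `G` as produced by
#' [compute_G()] (diagonal already safeguarded). With everyone genotyped this
#' reduces to `G^-1`; with no one genotyped, to `A^-1`.
#'
#' @param A Pedigree relationship matrix (dimnames = ids).
#' @param G Genomic relationship matrix over the genotyped ids.
#' @param genotyped_ids Ids (matching dimnames of A and G) of genotyped
#'   individuals.
#' @return The H-inverse matrix, ordered as A.
#' @export
compute_H_inverse <- function(A, G, genotyped_ids = rownames(G)) {
  ids <- rownames(A)
  gidx <- match(as.character(genotyped_ids), ids)
  if (anyNA(gidx)) stop("genotyped ids must be present in A")
  Hinv <- solve_or_fail(A, "A")
  if (length(gidx)) {
    if (is.null(G) || nrow(G) != length(gidx)) {
      stop("G must cover exactly the genotyped individuals")
    }
    A22inv <- solve_or_fail(A[gidx, gidx, drop = FALSE], "A22")
    Ginv <- solve_or_fail(G, "G")
    Hinv[gidx, gidx] <- Hinv[gidx, gidx] + Ginv - A22inv
  }
  Hinv
}

solve_or_fail <- function(M, label) {
  tryCatch(solve(M), error = function(e) {
    stop("matrix ", label, " is numerically singular: ", conditionMessage(e))
  })
}

new_ebv <- function(ebv_tbl, method, h2 = NA_real_, chip = NA_character_,
                    phenotyped = character(0)) {
  structure(
    list(
      ebv = ebv_tbl, method = method, h2 = h2, chip = chip,
      phenotyped = phenotyped
    ),
    class = "bs_ebv"
  )
}

#' @export
print.bs_ebv <- function(x, ...) {
  cat("<bs_ebv>", x$method, "| n =", nrow(x$ebv),
      "| records =", length(x$phenotyped))
  if (!is.na(x$h2)) cat(" | h2 =", x$h2)
  cat("\n")
  print(utils::head(x$ebv, 5))
  invisible(x)
}

#' Solve the single-trait animal model
#'
#' Mixed-model equations with an overall mean as the only fixed effect and
#' `lambda = (1 - h2)/h2` (the heritability is supplied, not estimated). EBVs
#' are returned for every individual in the relationship matrix, phenotyped or
#' not.
#'
#' @param phen Data frame with columns `id` and `y` (the phenotyped records).
#' @param K Relationship matrix (A, G or H) with ids as dimnames; or give its
#'   inverse directly via `Kinv` (used by single-step).
#' @param h2 Heritability used in the shrinkage parameter.
#' @param Kinv Optional precision matrix replacing `solve(K)`.
#' @param method,chip Labels stored in the result.
#' @return A `bs_ebv` object; `tidy()` extracts the `(id, ebv)` tibble.
#' @export
blup_solve <- function(phen, K = NULL, h2 = 0.5, Kinv = NULL,
                       method = "blup", chip = NA_character_) {
  if (is.null(Kinv)) {
    if (is.null(K)) stop("supply K or Kinv")
    Kinv <- solve_or_fail(K, "K")
  }
  ids <- rownames(Kinv)
  if (is.null(ids) && !is.null(K)) ids <- rownames(K)
  if (is.null(ids)) stop("relationship matrix must carry ids as dimnames")
  if (length(h2) != 1 || h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  phen <- phen[!is.na(phen$y), , drop = FALSE]
  if (!nrow(phen)) stop("no phenotyped individuals")
  ridx <- match(as.character(phen$id), ids)
  if (anyNA(ridx)) stop("phenotyped id missing from the relationship matrix")

  n <- length(ids)
  lambda <- (1 - h2) / h2
  ztz <- tabulate(ridx, n)
  zty <- numeric(n)
  agg <- rowsum(phen$y, ridx)
  zty[as.integer(rownames(agg))] <- agg[, 1]
  C <- rbind(
    c(nrow(phen), ztz),
    cbind(ztz, diag(ztz, n) + lambda * Kinv)
  )
  rhs <- c(sum(phen$y), zty)
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e))
  })
  new_ebv(
    tibble::tibble(id = ids, ebv = unname(sol[-1])),
    method = method, h2 = h2, chip = chip,
    phenotyped = as.character(phen$id)
  )
}

#' Mass selection "EBVs"
#'
#' The estimated breeding value is the individual's own phenotype;
#' unphenotyped individuals are not candidates.
#'
#' @param phen Data frame with columns `id` and `y`.
#' @return A `bs_ebv` object.
#' @export
mass_selection_ebv <- function(phen) {
  phen <- phen[!is.na(phen$y), , drop = FALSE]
  new_ebv(
    tibble::tibble(id = phen$id, ebv = phen$y),
    method = "mass", phenotyped = as.character(phen$id)
  )
}

#' Estimated breeding values for a population
#'
#' Front end to the genetic-evaluation methods: own phenotype (`mass`),
#' pedigree BLUP (`blup`), GBLUP (`gblup`) over a chip, and single-step GBLUP
#' (`ssgblup`) combining the full pedigree with a genotyped subset. By default
#' the data of all individuals simulated so far enter the evaluation.
#'
#' @param pop A phenotyped `bs_pop` population.
#' @param method One of `"mass"`, `"blup"`, `"gblup"`, `"ssgblup"`.
#' @param h2 Heritability used in the mixed model; defaults to the
#'   architecture's target for the trait (it is never estimated).
#' @param chip A `bs_chip` (required for gblup/ssgblup).
#' @param ids Evaluation window: ids that receive EBVs (default all).
#'   blup/ssgblup always use the full pedigree for the relationship but
#'   report these ids.
#' @param phenotyped Ids whose phenotype records enter the evaluation
#'   (default: all of `ids`); genotyped methods still predict the rest.
#' @param genotyped For `ssgblup`: ids with chip genotypes (default the whole
#'   window).
#' @param trait Trait index.
#' @return A `bs_ebv` object covering `ids`.
#' @export
predict_ebv <- function(pop, method = c("mass", "blup", "gblup", "ssgblup"),
                        h2 = NULL, chip = NULL, ids = NULL, genotyped = NULL,
                        phenotyped = NULL, trait = 1) {
  method <- match.arg(method)
  if (is.null(pop$y)) stop("population has no phenotypes; attach an architecture")
  if (is.null(ids)) ids <- pop$ped$id
  if (is.null(h2)) h2 <- pop$arch$h2[trait]
  if (is.null(phenotyped)) phenotyped <- ids
  phen <- tibble::tibble(
    id = phenotyped, y = pop$y[match(phenotyped, rownames(pop$y)), trait]
  )

  if (method == "mass") {
    return(mass_selection_ebv(phen))
  }
  if (method == "blup") {
    A <- compute_A(pop$ped[, c("id", "dam", "sire")])
    res <- blup_solve(phen, K = A, h2 = h2, method = "blup")
  } else {
    if (is.null(chip)) stop(method, " requires a chip")
    if (method == "gblup") {
      M <- decode_genotypes(pop, ids, chip$snps)
      G <- compute_G(M, ploidy = pop$genome$ploidy)
      res <- blup_solve(phen, K = G, h2 = h2, method = "gblup", chip = chip$name)
    } else {
      if (is.null(genotyped)) genotyped <- ids
      A <- compute_A(pop$ped[, c("id", "dam", "sire")])
      M <- decode_genotypes(pop, genotyped, chip$snps)
      G <- compute_G(M, ploidy = pop$genome$ploidy)
      Hinv <- compute_H_inverse(A, G, genotyped_ids = genotyped)
      res <- blup_solve(phen, Kinv = Hinv, h2 = h2, method = "ssgblup",
                        chip = chip$name)
    }
  }
  res$ebv <- res$ebv[match(as.character(ids), res$ebv$id), ]
  res
}

#' Export chip genotypes and phenotypes for external evaluation
#'
#' Writes `<prefix>_dosages.tsv` (id plus one column per chip SNP, named
#' `chr_pos`) and `<prefix>_phenotypes.tsv` (id plus one column per trait).
#' An external evaluation's EBVs come back in via [import_ebv()].
#'
#' @param pop A phenotyped `bs_pop` population.
#' @param chip A `bs_chip`.
#' @param prefix Output path prefix.
#' @param ids Individuals to export (default all).
#' @return Invisibly, the two file paths.
#' @export
export_evaluation <- function(pop, chip, prefix, ids = NULL) {
  if (is.null(ids)) ids <- pop$ped$id
  M <- decode_genotypes(pop, ids, chip$snps)
  colnames(M) <- paste0(
    pop$genome$snps$chr[chip$snps], "_", pop$genome$snps$pos[chip$snps]
  )
  dos_path <- paste0(prefix, "_dosages.tsv")
  phe_path <- paste0(prefix, "_phenotypes.tsv")
  utils::write.table(data.frame(id = ids, M, check.names = FALSE), dos_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  y <- pop$y[match(ids, rownames(pop$y)), , drop = FALSE]
  colnames(y) <- paste0("y", seq_len(ncol(y)))
  utils::write.table(data.frame(id = ids, y, check.names = FALSE), phe_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosages = dos_path, phenotypes = phe_path))
}

#' Import externally computed EBVs
#'
#' Reads a whitespace-delimited `id value` file and attaches the EBVs to known
#' individuals; unknown ids are an error.
#'
#' @param path File path.
#' @param pop The population the ids must belong to.
#' @return A `bs_ebv` object with method `"external"`.
#' @export
import_ebv <- function(path, pop) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("EBV file needs two columns: id, value")
  ids <- as.character(df[[1]])
  header <- is.na(suppressWarnings(as.numeric(df[[2]][1])))
  if (header) {
    ids <- ids[-1]
    vals <- as.numeric(df[[2]][-1])
  } else {
    vals <- as.numeric(df[[2]])
  }
  known <- as.character(pop$ped$id)
  if (any(!ids %in% known)) {
    stop("EBV file contains unknown id(s): ",
         paste(utils::head(setdiff(ids, known)), collapse = ", "))
  }
  new_ebv(tibble::tibble(id = type.convert(ids, as.is = TRUE), ebv = vals),
          method = "external")
}
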