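# Individual genomes are block lists: per chromosome a list of homologs, each
# homolog parallel vectors end/hap where blocks are the half-open intervals
# (prev_end, end] and hap indexes a column of the founder haplotype matrix.
new_individual <- function(id, sex, dam, sire, gen, hom) {
  list(id = id, sex = sex, dam = dam, sire = sire, gen = gen, hom = hom)
}

# Founder homolog structure for founder f (1-based) given its sex.
founder_homologs <- function(genome, f, sex) {
  ploidy <- genome$ploidy
  base <- (f - 1L) * ploidy
  lapply(genome$chromosomes, function(ch) {
    cols <- switch(ch$kind,
      autosome = base + seq_len(ploidy),
      sex_x = if (sex == "F") base + 1:2 else base + 1L,
      sex_y = if (sex == "M") base + 2L else integer(0),
      mito = base + 1L
    )
    lapply(cols, function(cc) list(end = ch$length_bp, hap = cc))
  })
}

#' Create a base population from a founder panel
#'
#' Wraps a founder panel and its genome into a population object: one
#' individual per founder, each carrying intact haplotype blocks. Sexes
#' alternate female/male by default. On sex chromosomes, female founders carry
#' their first two haplotype columns as X homologs; male founders carry column
#' one as X and column two as Y (a documented convention of the VCF layout).
#'
#' @param founders A `bs_founders` panel.
#' @param genome The matching [build_genome()] object.
#' @param sexes Character vector of `"F"`/`"M"` per founder, or `NULL` for
#'   alternating.
#' @return An object of class `bs_pop`.
#' @export
new_population <- function(founders, genome, sexes = NULL) {
  n <- founders$n_founders
  if (is.null(sexes)) sexes <- rep(c("F", "M"), length.out = n)
  sexes <- normalize_sex(sexes)
  if (length(sexes) != n) stop("need one sex per founder")

  inds <- lapply(seq_len(n), function(f) {
    new_individual(f, sexes[f], 0L, 0L, 0L, founder_homologs(genome, f, sexes[f]))
  })
  structure(
    list(
      genome = genome, founders = founders, inds = inds,
      ped = tibble::tibble(
        id = seq_len(n), dam = 0L, sire = 0L,
        sex = sexes, generation = 0L, base = TRUE
      ),
      arch = NULL, g = NULL, e = NULL, y = NULL
    ),
    class = "bs_pop"
  )
}

normalize_sex <- function(x) {
  out <- toupper(as.character(x))
  out[out %in% c("FEMALE", "2")] <- "F"
  out[out %in% c("MALE", "1")] <- "M"
  if (!all(out %in% c("F", "M"))) stop("sexes must be 'F'/'M' (or female/male, 2/1)")
  out
}

#' @export
print.bs_pop <- function(x, ...) {
  cat("<bs_pop>", nrow(x$ped), "individuals over",
      length(unique(x$ped$generation)), "generation(s) | ploidy",
      x$genome$ploidy, "|", nrow(x$genome$snps), "SNPs\n")
  if (!is.null(x$arch)) {
    cat("  phenotypes:", ncol(x$y), "trait(s)\n")
  }
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `bs_pop` object.
#' @return Integer count.
#' @export
pop_size <- function(pop) nrow(pop$ped)

# Append a batch of individuals (list of new_individual) to the population,
# simulating phenotypes at birth when an architecture is attached.
pop_append <- function(pop, inds) {
  if (!length(inds)) return(pop)
  ped_new <- tibble::tibble(
    id = vapply(inds, `[[`, 0L, "id"),
    dam = vapply(inds, `[[`, 0L, "dam"),
    sire = vapply(inds, `[[`, 0L, "sire"),
    sex = vapply(inds, `[[`, "", "sex"),
    generation = vapply(inds, `[[`, 0L, "gen"),
    base = FALSE
  )
  pop$inds <- c(pop$inds, inds)
  pop$ped <- dplyr::bind_rows(pop$ped, ped_new)
  if (!is.null(pop$arch)) {
    pop <- phenotype_individuals(pop, ped_new$id)
  }
  pop
}

# Locate, for a sorted vector of positions on one chromosome, the haplotype id
# carried by one homolog at each position (blocks are (start, end]).
hap_at <- function(hom, pos) {
  hom$hap[findInterval(pos - 1e-9, hom$end) + 1L]
}

#' Decode block genomes to SNP dosages
#'
#' Converts the breakpoint-block representation back to allele dosages by
#' binary search of the covering block per homolog and summing founder
#' alleles. Dosages range 0..ploidy on autosomes; on the X males contribute
#' only their single copy, and Y-linked SNPs are `NA` in females
#' (missing by structure).
#'
#' @param pop A `bs_pop` population.
#' @param ids Individual ids to decode (default all).
#' @param snps SNP indices into `pop$genome$snps` (default all).
#' @return Integer matrix, individuals in rows (rownames = ids), SNPs in
#'   columns.
#' @export
decode_genotypes <- function(pop, ids = NULL, snps = NULL) {
  if (is.null(ids)) ids <- pop$ped$id
  if (is.null(snps)) snps <- seq_len(nrow(pop$genome$snps))
  snp_tbl <- pop$genome$snps
  if (any(snps < 1 | snps > nrow(snp_tbl))) stop("SNP index out of range")

  chr_names <- names(pop$genome$chromosomes)
  by_chr <- split(seq_along(snps), factor(snp_tbl$chr[snps], levels = chr_names))
  out <- matrix(NA_integer_, length(ids), length(snps),
                dimnames = list(ids, NULL))
  haps <- pop$founders$haps

  for (ci in seq_along(chr_names)) {
    cols <- by_chr[[ci]]
    if (!length(cols)) next
    gidx <- snps[cols]             # global SNP rows
    pos <- snp_tbl$pos[gidx]
    for (r in seq_along(ids)) {
      homs <- pop$inds[[ids[r]]]$hom[[ci]]
      if (!length(homs)) next      # e.g. Y chromosome in a female
      d <- integer(length(cols))
      for (h in homs) {
        d <- d + haps[cbind(gidx, hap_at(h, pos))]
      }
      out[r, cols] <- d
    }
  }
  out
}

#' Expand the founder pool with dummy recombinant individuals
#'
#' Creates additional base-population individuals by shuffling founder
#' genomes, either by gene-dropping each dummy down a short random pedigree
#' over real founders (`mode = "gene_drop"`, depth 2: random grandparents,
#' then parents, then the dummy), or by drawing random recombination
#' breakpoints per homolog and assigning each block a uniformly drawn founder
#' haplotype (`mode = "random_blocks"`). Dummies are flagged as base
#' population (generation 0).
#'
#' @param pop A `bs_pop` population (founders only, or any population).
#' @param n_new Number of dummies to add (>= 0).
#' @param mode `"random_blocks"` or `"gene_drop"`.
#' @param sexes Optional sexes for the dummies; alternating by default.
#' @return The extended population.
#' @export
make_dummy_founders <- function(pop, n_new,
                                mode = c("random_blocks", "gene_drop"),
                                sexes = NULL) {
  mode <- match.arg(mode)
  if (n_new < 0) stop("n_new must be >= 0")
  if (n_new == 0) return(pop)
  if (is.null(sexes)) sexes <- rep(c("F", "M"), length.out = n_new)
  sexes <- normalize_sex(sexes)

  founder_ids <- pop$ped$id[pop$ped$base]
  genome <- pop$genome
  next_id <- max(pop$ped$id)

  dummies <- vector("list", n_new)
  for (k in seq_len(n_new)) {
    id <- next_id + k
    hom <- if (mode == "random_blocks") {
      random_block_homologs(pop, sexes[k])
    } else {
      dummy_gene_drop_homologs(pop, founder_ids, sexes[k])
    }
    dummies[[k]] <- new_individual(id, sexes[k], 0L, 0L, 0L, hom)
  }
  pop2 <- pop_append(pop, dummies)
  pop2$ped$base[pop2$ped$id > next_id] <- TRUE
  pop2
}

# random_blocks mode: Poisson(genetic length) breakpoints per homolog, each
# block assigned a uniformly drawn founder haplotype column.
random_block_homologs <- function(pop, sex) {
  genome <- pop$genome
  ploidy <- genome$ploidy
  n_f <- pop$founders$n_founders
  out <- lapply(genome$chromosomes, function(ch) {
    n_hom <- switch(ch$kind,
      autosome = ploidy, sex_x = if (sex == "F") 2L else 1L,
      sex_y = if (sex == "M") 1L else 0L, mito = 1L
    )
    lapply(seq_len(n_hom), function(i) {
      # pick allowed source columns for this chromosome kind
      src_off <- switch(ch$kind,
        autosome = seq_len(ploidy),
        sex_x = 1:2, sex_y = 2L, mito = 1L
      )
      L <- genetic_length(ch, if (sex == "F") "female" else "male")
      ncx <- if (ch$kind %in% c("sex_y", "mito")) 0L else stats::rpois(1, L)
      breaks <- sort(inverse_genetic_position(ch, stats::runif(ncx, 0, L)))
      ends <- unique(c(breaks[breaks > 0 & breaks < ch$length_bp], ch$length_bp))
      f_pick <- sample.int(n_f, length(ends), replace = TRUE)
      o_pick <- sample(src_off, length(ends), replace = TRUE)
      normalize_homolog(list(end = ends, hap = (f_pick - 1L) * ploidy + o_pick))
    })
  })
  names(out) <- names(genome$chromosomes)
  out
}

# gene_drop mode: simulate a depth-2 random pedigree over real founders
# (random grandparents -> parents -> dummy) and return the dummy's homologs.
dummy_gene_drop_homologs <- function(pop, founder_ids, sex) {
  fem <- founder_ids[pop$ped$sex[founder_ids] == "F"]
  mal <- founder_ids[pop$ped$sex[founder_ids] == "M"]
  if (!length(fem) || !length(mal)) {
    stop("gene_drop dummies need both female and male founders")
  }
  pick <- function(v) v[sample.int(length(v), 1L)]
  parent_of <- function(psex) {
    mate_individuals(pop$inds[[pick(fem)]], pop$inds[[pick(mal)]],
                     pop$genome, id = -1L, gen = -1L, sex = psex)
  }
  child <- mate_individuals(parent_of("F"), parent_of("M"),
                            pop$genome, id = -1L, gen = 0L, sex = sex)
  child$hom
}
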