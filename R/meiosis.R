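# Fuse adjacent blocks carrying the same founder haplotype; decoded genotypes
# are unchanged by construction.
normalize_homolog <- function(hom) {
  n <- length(hom$end)
  if (n <= 1) return(hom)
  keep <- c(hom$hap[-n] != hom$hap[-1], TRUE)
  list(end = hom$end[keep], hap = hom$hap[keep])
}

# Build the recombinant strand that starts on h1 and switches source at each
# breakpoint. Blocks are half-open (start, end].
recombine_homologs <- function(h1, h2, breaks, length_bp) {
  breaks <- breaks[breaks > 0 & breaks < length_bp]
  if (!length(breaks)) return(h1)
  bounds <- c(sort(breaks), length_bp)
  cur <- list(h1, h2)
  si <- 1L
  lo <- 0
  end <- numeric(0)
  hap <- integer(0)
  for (hi in bounds) {
    if (hi > lo) {
      h <- cur[[si]]
      i1 <- findInterval(lo, h$end) + 1L          # first block with end > lo
      i2 <- findInterval(hi - 1e-9, h$end) + 1L   # block containing hi
      seg_end <- h$end[i1:i2]
      seg_end[length(seg_end)] <- hi
      end <- c(end, seg_end)
      hap <- c(hap, h$hap[i1:i2])
      lo <- hi
    }
    si <- 3L - si
  }
  normalize_homolog(list(end = end, hap = hap))
}

# Crossover breakpoints for one bivalent: count ~ Poisson(genetic length in
# Morgans for the parent's sex), positions uniform in genetic coordinates,
# inverse-mapped to bp.
crossover_breaks <- function(chrom, sex_map) {
  L <- genetic_length(chrom, sex_map)
  if (L <= 0) return(numeric(0))
  ncx <- stats::rpois(1L, L)
  if (ncx == 0L) return(numeric(0))
  sort(inverse_genetic_position(chrom, stats::runif(ncx, 0, L), sex_map))
}

#' Simulate one gamete
#'
#' Generates a half-genome from a parent under the block representation. Per
#' autosome, the parent's homologs are randomly partitioned into ploidy/2
#' bivalents; within each bivalent the crossover count is Poisson with rate
#' equal to the chromosome's genetic length in Morgans (sex-specific map), no
#' interference and no obligate chiasma, and one recombinant strand per
#' bivalent enters the gamete. A male transmits his X or his Y intact with
#' probability 1/2 each (the Y never recombines and the male X has no pairing
#' partner); a female recombines her two X copies as an ordinary bivalent.
#' Mitochondria are transmitted only by the mother, intact.
#'
#' @param parent An individual (element of `pop$inds`).
#' @param genome The `bs_genome`.
#' @param force_sex For a male parent, force transmission of `"X"` or `"Y"`
#'   (used to fix offspring sex); `NULL` draws 1:1.
#' @param record If `TRUE`, attach per-chromosome meiosis events (pairing and
#'   breakpoints) for external verification.
#' @return A list with `hom` (per-chromosome list of transmitted homologs),
#'   `sex_allele` (`"X"`/`"Y"` for paternal gametes, `"X"` for maternal),
#'   `n_crossovers` (total crossover events across bivalents) and, when
#'   recorded, `events`.
#' @export
make_gamete <- function(parent, genome, force_sex = NULL, record = FALSE) {
  ploidy <- genome$ploidy
  sex_map <- if (parent$sex == "F") "female" else "male"
  sex_allele <- if (parent$sex == "F") {
    "X"
  } else if (!is.null(force_sex)) {
    force_sex
  } else {
    c("X", "Y")[sample.int(2L, 1L)]
  }

  chroms <- genome$chromosomes
  hom_out <- vector("list", length(chroms))
  names(hom_out) <- names(chroms)
  events <- if (record) vector("list", length(chroms)) else NULL
  n_cx <- 0L

  for (ci in seq_along(chroms)) {
    ch <- chroms[[ci]]
    homs <- parent$hom[[ci]]
    ev <- list()
    out <- list()
    if (ch$kind == "mito") {
      if (parent$sex == "F") {
        out <- homs[1]
        ev <- list(list(pair = c(1L, 1L), breaks = numeric(0)))
      }
    } else if (ch$kind == "sex_y") {
      if (parent$sex == "M" && sex_allele == "Y" && length(homs)) {
        out <- homs[1]
        ev <- list(list(pair = c(1L, 1L), breaks = numeric(0)))
      }
    } else if (ch$kind == "sex_x") {
      if (parent$sex == "F") {
        breaks <- crossover_breaks(ch, "female")
        n_cx <- n_cx + length(breaks)
        first <- sample.int(2L, 1L)
        out <- list(recombine_homologs(homs[[first]], homs[[3L - first]],
                                       breaks, ch$length_bp))
        ev <- list(list(pair = c(first, 3L - first), breaks = breaks))
      } else if (sex_allele == "X" && length(homs)) {
        out <- homs[1] # hemizygous X: transmitted intact
        ev <- list(list(pair = c(1L, 1L), breaks = numeric(0)))
      }
    } else { # autosome
      perm <- sample.int(ploidy)
      out <- vector("list", ploidy %/% 2L)
      ev <- vector("list", ploidy %/% 2L)
      for (b in seq_len(ploidy %/% 2L)) {
        i <- perm[2L * b - 1L]
        j <- perm[2L * b]
        breaks <- crossover_breaks(ch, sex_map)
        n_cx <- n_cx + length(breaks)
        out[[b]] <- recombine_homologs(homs[[i]], homs[[j]], breaks, ch$length_bp)
        ev[[b]] <- list(pair = c(i, j), breaks = breaks)
      }
    }
    hom_out[[ci]] <- out
    if (record) events[[ci]] <- ev
  }
  res <- list(hom = hom_out, sex_allele = sex_allele, n_crossovers = n_cx)
  if (record) res$events <- events
  res
}

# Combine a maternal and a paternal gamete into an offspring individual.
combine_gametes <- function(gm, gp, genome, id, dam, sire, gen) {
  kinds <- vapply(genome$chromosomes, `[[`, "", "kind")
  has_sex <- any(kinds %in% c("sex_x", "sex_y"))
  sex <- if (gp$sex_allele == "Y") "M" else "F"
  hom <- vector("list", length(kinds))
  names(hom) <- names(genome$chromosomes)
  for (ci in seq_along(kinds)) {
    hom[[ci]] <- switch(kinds[[ci]],
      autosome = c(gm$hom[[ci]], gp$hom[[ci]]),
      sex_x = c(gm$hom[[ci]], gp$hom[[ci]]),
      sex_y = gp$hom[[ci]],
      mito = gm$hom[[ci]]
    )
  }
  new_individual(id, sex, dam, sire, gen, hom)
}

# Low-level mating: returns the offspring individual without touching a
# population object. sex: "random", "F" or "M".
mate_individuals <- function(mother, father, genome, id = 0L, gen = 0L,
                             sex = "random") {
  if (mother$sex != "F" || father$sex != "M") {
    stop("mating requires a female mother and a male father")
  }
  force_sex <- switch(sex, random = NULL, F = "X", M = "Y",
                      stop("sex must be 'random', 'F' or 'M'"))
  gm <- make_gamete(mother, genome)
  gp <- make_gamete(father, genome, force_sex = force_sex)
  off <- combine_gametes(gm, gp, genome, id, mother$id, father$id, gen)
  # without sex chromosomes the paternal gamete still carries a sex token,
  # so forced sexes are honoured either way
  off
}

#' Mate two individuals
#'
#' Adds `n` offspring of the given parents to the population: the union of one
#' maternal and one paternal gamete each. Offspring sex follows the
#' transmitted sex chromosome (male iff the paternal Y was received) and is
#' 1:1 when `sex = "random"`. Offspring are phenotyped at birth when an
#' architecture is attached.
#'
#' @param pop A `bs_pop` population.
#' @param dam,sire Parent ids; the dam must be female and the sire male.
#' @param n Number of offspring.
#' @param sex `"random"`, `"F"` or `"M"`.
#' @param generation Generation number for the offspring; defaults to
#'   `max(parent generations) + 1`.
#' @return The population with offspring appended.
#' @export
add_offspring <- function(pop, dam, sire, n = 1, sex = "random",
                          generation = NULL) {
  dsex <- pop$ped$sex[match(dam, pop$ped$id)]
  ssex <- pop$ped$sex[match(sire, pop$ped$id)]
  if (is.na(dsex) || is.na(ssex)) stop("unknown parent id")
  if (dsex != "F" || ssex != "M") {
    stop("dam must be female and sire male (got ", dsex, " x ", ssex, ")")
  }
  if (is.null(generation)) {
    generation <- max(pop$ped$generation[match(c(dam, sire), pop$ped$id)]) + 1L
  }
  next_id <- max(pop$ped$id)
  kids <- lapply(seq_len(n), function(k) {
    mate_individuals(
      pop$inds[[match(dam, pop$ped$id)]], pop$inds[[match(sire, pop$ped$id)]],
      pop$genome, id = next_id + k, gen = as.integer(generation), sex = sex
    )
  })
  pop_append(pop, kids)
}

#' Create a dihaploid offspring
#'
#' Duplicates a single gamete of a diploid parent: both homologs of every
#' autosome are identical, so the dihaploid is homozygous at every SNP.
#' Dihaploids carry a duplicated maternal-type X (sex female) when sex
#' chromosomes are modelled, and inherit the parent's mitochondria.
#'
#' @param pop A `bs_pop` population (ploidy 2).
#' @param parent_id Id of the parent.
#' @param generation Generation number (default parent's + 1).
#' @return The population with the dihaploid appended.
#' @export
make_dihaploid <- function(pop, parent_id, generation = NULL) {
  if (pop$genome$ploidy != 2L) stop("dihaploids are only supported for diploids")
  parent <- pop$inds[[match(parent_id, pop$ped$id)]]
  if (is.null(generation)) generation <- parent$gen + 1L
  gam <- make_gamete(parent, pop$genome, force_sex = "X")
  hom <- vector("list", length(pop$genome$chromosomes))
  names(hom) <- names(pop$genome$chromosomes)
  for (ci in seq_along(hom)) {
    kind <- pop$genome$chromosomes[[ci]]$kind
    hom[[ci]] <- switch(kind,
      autosome = rep(gam$hom[[ci]], 2L),
      sex_x = rep(gam$hom[[ci]], 2L),
      sex_y = list(),
      mito = parent$hom[[ci]][1]
    )
  }
  id <- max(pop$ped$id) + 1L
  di <- new_individual(id, "F", parent$id, parent$id, as.integer(generation), hom)
  pop_append(pop, list(di))
}

#' Gene dropping along a fixed pedigree
#'
#' Simulates inheritance of founder genomes down a user pedigree, with no
#' selection. Pedigree founder rows (both parents unknown) map, in order, to
#' the founder panel's individuals; later rows are simulated by mating.
#' Rows may appear in any order as long as the pedigree is acyclic; an
#' individual with exactly one known parent is an error.
#'
#' @param founders A `bs_founders` panel.
#' @param genome The matching genome.
#' @param pedigree Data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`F`/`M`, `0` or `NA` = unknown, then inferred from use as sire or
#'   dam). `0` or `NA` parent codes mean unknown.
#' @return A `bs_pop` population with one individual per pedigree row (plus
#'   any panel founders not referenced).
#' @export
gene_drop <- function(founders, genome, pedigree) {
  ped <- as.data.frame(pedigree)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) stop("pedigree needs columns id, sire, dam")
  id <- as.character(ped$id)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  unknown <- function(x) is.na(x) | x %in% c("0", "")
  sire[unknown(sire)] <- NA
  dam[unknown(dam)] <- NA
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  one_parent <- xor(is.na(sire), is.na(dam))
  if (any(one_parent)) {
    stop("individual(s) with exactly one known parent: ",
         paste(id[one_parent], collapse = ", "))
  }
  known <- !is.na(sire)
  if (any(!sire[known] %in% id) || any(!dam[known] %in% id)) {
    stop("pedigree references parents that are not rows of the pedigree")
  }

  # sexes: given, or inferred from use as sire/dam
  sex <- if ("sex" %in% names(ped)) as.character(ped$sex) else rep(NA, length(id))
  sex[sex %in% c("0", "")] <- NA
  infer_m <- id %in% sire
  infer_f <- id %in% dam
  if (any(infer_m & infer_f)) {
    stop("individual used as both sire and dam: ",
         paste(id[infer_m & infer_f], collapse = ", "))
  }
  sex[is.na(sex) & infer_m] <- "M"
  sex[is.na(sex) & infer_f] <- "F"
  sex[is.na(sex)] <- rep(c("F", "M"), length.out = sum(is.na(sex)))
  sex <- normalize_sex(sex)
  bad_use <- (id %in% sire & sex == "F") | (id %in% dam & sex == "M")
  if (any(bad_use)) {
    stop("sex inconsistent with use as parent: ", paste(id[bad_use], collapse = ", "))
  }

  # topological order (founders first); cycle -> error
  order_idx <- integer(0)
  placed <- rep(FALSE, length(id))
  repeat {
    ready <- !placed & (is.na(sire) | (sire %in% id[placed] & dam %in% id[placed]))
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle or unresolvable ordering")

  f_rows <- which(is.na(sire))
  if (length(f_rows) > founders$n_founders) {
    stop("pedigree has ", length(f_rows), " founder rows but the panel has only ",
         founders$n_founders, " founders")
  }
  sexes <- rep(c("F", "M"), length.out = founders$n_founders)
  sexes[seq_along(f_rows)] <- sex[f_rows]
  pop <- new_population(founders, genome, sexes = sexes)

  # pedigree id -> internal id
  imap <- stats::setNames(rep(NA_integer_, length(id)), id)
  imap[id[f_rows]] <- seq_along(f_rows)
  for (r in order_idx) {
    if (!is.na(sire[r]) ) {
      d <- imap[[dam[r]]]
      s <- imap[[sire[r]]]
      pop <- add_offspring(pop, d, s, n = 1, sex = sex[r])
      imap[[id[r]]] <- max(pop$ped$id)
    }
  }
  attr(pop, "id_map") <- imap
  pop
}

#' Read a pedigree file
#'
#' Whitespace-delimited columns `id sire dam [sex]`; `0` marks unknown parents
#' or sex. A header line is detected when the first token is `id`.
#'
#' @param path File path.
#' @return A tibble with columns `id`, `sire`, `dam`, `sex`.
#' @export
read_pedigree_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  if (length(fields) && tolower(fields[[1]][1]) == "id") fields <- fields[-1]
  if (!length(fields)) stop("empty pedigree file: ", path)
  n <- lengths(fields)
  if (any(n < 3 | n > 4)) stop("pedigree rows must have 3 or 4 fields")
  tibble::tibble(
    id = vapply(fields, `[[`, "", 1L),
    sire = vapply(fields, `[[`, "", 2L),
    dam = vapply(fields, `[[`, "", 3L),
    sex = vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "0", "")
  )
}
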