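# Independent oracles.
#
# 1) Naive allele-propagation simulator: individuals are full per-SNP allele
#    vectors per homolog; gametes are built by switching between the two
#    paired parental allele vectors at the recorded crossover breakpoints.
#    It shares the meiosis events (pairing + breakpoints) with the block
#    implementation but none of the block arithmetic or the decode search.
#
# 2) GLS route to BLUP: EBV = s2u K Z' V^-1 (y - X bhat), an algebraically
#    equivalent but computationally different path to the MME solution.

# Founder naive representation mirrors the documented haplotype-column
# convention (autosomes: all columns; female X: cols 1-2; male X: col 1;
# male Y: col 2; mito: col 1).
naive_founder <- function(pop, f) {
  genome <- pop$genome
  ploidy <- genome$ploidy
  sex <- pop$ped$sex[match(f, pop$ped$id)]
  base <- (f - 1L) * ploidy
  lapply(names(genome$chromosomes), function(nm) {
    ch <- genome$chromosomes[[nm]]
    rows <- which(genome$snps$chr == nm)
    cols <- switch(ch$kind,
      autosome = base + seq_len(ploidy),
      sex_x = if (sex == "F") base + 1:2 else base + 1L,
      sex_y = if (sex == "M") base + 2L else integer(0),
      mito = base + 1L
    )
    lapply(cols, function(cc) pop$founders$haps[rows, cc])
  })
}

# Build the naive gamete from recorded meiosis events.
naive_gamete <- function(naive_parent, events, genome) {
  lapply(seq_along(genome$chromosomes), function(ci) {
    nm <- names(genome$chromosomes)[ci]
    pos <- genome$snps$pos[genome$snps$chr == nm]
    lapply(events[[ci]], function(ev) {
      src1 <- naive_parent[[ci]][[ev$pair[1]]]
      src2 <- naive_parent[[ci]][[ev$pair[2]]]
      if (!length(ev$breaks)) return(src1)
      n_sw <- findInterval(pos - 1e-9, sort(ev$breaks))
      ifelse(n_sw %% 2L == 0L, src1, src2)
    })
  })
}

naive_combine <- function(gm, gp, genome) {
  lapply(seq_along(genome$chromosomes), function(ci) {
    switch(genome$chromosomes[[ci]]$kind,
      autosome = c(gm[[ci]], gp[[ci]]),
      sex_x = c(gm[[ci]], gp[[ci]]),
      sex_y = gp[[ci]],
      mito = gm[[ci]]
    )
  })
}

# Dosage vector (all genome SNPs, NA where no homolog) from a naive individual.
naive_decode <- function(naive_ind, genome) {
  out <- rep(NA_integer_, nrow(genome$snps))
  for (ci in seq_along(genome$chromosomes)) {
    nm <- names(genome$chromosomes)[ci]
    rows <- which(genome$snps$chr == nm)
    homs <- naive_ind[[ci]]
    if (!length(homs)) next
    out[rows] <- Reduce(`+`, homs)
  }
  out
}

# Run a random pedigree with both representations in lockstep. Returns the
# extended population plus the naive genomes, aligned by individual id.
dual_sim <- function(pop, n_per_gen, n_generations) {
  genome <- pop$genome
  naive <- lapply(pop$ped$id, function(f) naive_founder(pop, f))
  for (gen in seq_len(n_generations)) {
    prev <- pop$ped$id[pop$ped$generation == gen - 1L]
    dams <- prev[pop$ped$sex[match(prev, pop$ped$id)] == "F"]
    sires <- prev[pop$ped$sex[match(prev, pop$ped$id)] == "M"]
    stopifnot(length(dams) > 0, length(sires) > 0)
    kids <- list()
    for (k in seq_len(n_per_gen)) {
      dam <- dams[sample.int(length(dams), 1)]
      sire <- sires[sample.int(length(sires), 1)]
      gm <- make_gamete(pop$inds[[dam]], genome, record = TRUE)
      # keep both sexes present in every generation
      force <- if (k == 1) "X" else if (k == 2) "Y" else NULL
      gp <- make_gamete(pop$inds[[sire]], genome, force_sex = force, record = TRUE)
      id <- max(pop$ped$id) + length(kids) + 1L
      kids[[k]] <- breedsim:::combine_gametes(gm, gp, genome, id, dam, sire, gen)
      naive[[id]] <- naive_combine(
        naive_gamete(naive[[dam]], gm$events, genome),
        naive_gamete(naive[[sire]], gp$events, genome),
        genome
      )
    }
    pop <- breedsim:::pop_append(pop, kids)
  }
  list(pop = pop, naive = naive)
}

# Independent GLS/BLUP oracle (overall mean fixed effect).
blup_gls_oracle <- function(phen, K, h2) {
  ids <- rownames(K)
  n <- length(ids)
  Z <- matrix(0, nrow(phen), n)
  Z[cbind(seq_len(nrow(phen)), match(as.character(phen$id), ids))] <- 1
  X <- matrix(1, nrow(phen), 1)
  s2u <- h2
  s2e <- 1 - h2
  V <- s2u * Z %*% K %*% t(Z) + diag(s2e, nrow(phen))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% phen$y)
  drop(s2u * K %*% t(Z) %*% Vi %*% (phen$y - X %*% b))
}
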