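#' Chromosome descriptor
#'
#' Builds a single chromosome record holding its physical length, its class
#' (autosome, X, Y or mitochondrial) and its female and male recombination
#' maps. Maps are cumulative centimorgan anchor lists; between anchors the
#' genetic position is linearly interpolated, beyond the last anchor the last
#' segment's rate is extrapolated up to `length_bp`. When no map is supplied
#' the genome-wide default of 1 cM per Mb applies.
#'
#' @param name Chromosome label (as in the VCF `CHROM` column).
#' @param length_bp Physical length in base pairs; must be at least the last
#'   SNP position.
#' @param kind One of `"autosome"`, `"sex_x"`, `"sex_y"`, `"mito"`. Y and
#'   mitochondrial chromosomes never recombine regardless of map.
#' @param map_female,map_male Two-column matrices (bp, cumulative cM) with
#'   strictly increasing bp and non-decreasing cM, or `NULL` for the default
#'   1 cM/Mb map. `map_male` defaults to `map_female`.
#' @return An object of class `bs_chromosome`.
#' @export
chromosome <- function(name, length_bp,
                       kind = c("autosome", "sex_x", "sex_y", "mito"),
                       map_female = NULL, map_male = NULL) {
  kind <- match.arg(kind)
  length_bp <- as.numeric(length_bp)
  if (!is.finite(length_bp) || length_bp <= 0) {
    stop("chromosome '", name, "': length_bp must be a positive number")
  }
  if (is.null(map_male)) map_male <- map_female
  structure(
    list(
      name = as.character(name),
      length_bp = length_bp,
      kind = kind,
      map_female = prep_map(map_female, length_bp, name),
      map_male = prep_map(map_male, length_bp, name)
    ),
    class = "bs_chromosome"
  )
}

# Normalise a map to anchors spanning [0, length_bp]: prepend the (0, 0)
# origin, extrapolate the final segment's rate out to length_bp. NULL means
# the default 1 cM/Mb map.
prep_map <- function(anchors, length_bp, name = "?") {
  cm_per_bp_default <- 1e-6 # 1 cM per Mb
  if (is.null(anchors)) {
    return(cbind(bp = c(0, length_bp), cm = c(0, length_bp * cm_per_bp_default)))
  }
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 2) stop("map for '", name, "' must have two columns (bp, cM)")
  storage.mode(anchors) <- "double"
  anchors <- anchors[order(anchors[, 1]), , drop = FALSE]
  if (anyDuplicated(anchors[, 1])) {
    stop("map for '", name, "': anchor bp positions must be strictly increasing")
  }
  if (is.unsorted(anchors[, 2])) {
    stop("map for '", name, "': cumulative cM must be non-decreasing")
  }
  if (anchors[1, 1] < 0) stop("map for '", name, "': negative bp anchor")
  if (anchors[1, 1] > 0) anchors <- rbind(c(0, 0), anchors)
  n <- nrow(anchors)
  last_bp <- anchors[n, 1]
  if (last_bp > length_bp) {
    stop("map for '", name, "' extends beyond chromosome length")
  }
  if (last_bp < length_bp) {
    rate <- if (n >= 2) {
      (anchors[n, 2] - anchors[n - 1, 2]) / (anchors[n, 1] - anchors[n - 1, 1])
    } else {
      cm_per_bp_default
    }
    anchors <- rbind(anchors, c(length_bp, anchors[n, 2] + rate * (length_bp - last_bp)))
  }
  dimnames(anchors) <- list(NULL, c("bp", "cm"))
  anchors
}

#' Physical to genetic position
#'
#' Converts base-pair coordinates to Morgans by piecewise-linear interpolation
#' of the chromosome's cumulative map for the given parental sex. Y and
#' mitochondrial chromosomes are non-recombining and always map to 0.
#'
#' @param chrom A [chromosome()] object.
#' @param bp Base-pair position(s), `0 <= bp <= length_bp`.
#' @param sex `"female"` or `"male"`: which map to use.
#' @return Genetic position(s) in Morgans.
#' @seealso [inverse_genetic_position()]
#' @export
genetic_position <- function(chrom, bp, sex = c("female", "male")) {
  sex <- match.arg(sex)
  bp <- as.numeric(bp)
  if (any(bp < 0 | bp > chrom$length_bp)) {
    stop("bp outside [0, ", chrom$length_bp, "] on chromosome ", chrom$name)
  }
  if (chrom$kind %in% c("sex_y", "mito")) {
    return(rep(0, length(bp)))
  }
  map <- if (sex == "male") chrom$map_male else chrom$map_female
  stats::approx(map[, 1], map[, 2], xout = bp, ties = "ordered")$y / 100
}

#' Genetic to physical position
#'
#' Functional inverse of [genetic_position()] on the interior of each map
#' segment. Plateaus of the cumulative map (zero local recombination) map to
#' their leftmost base pair.
#'
#' @inheritParams genetic_position
#' @param morgans Genetic position(s) in Morgans.
#' @return Base-pair position(s).
#' @export
inverse_genetic_position <- function(chrom, morgans, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!length(morgans)) return(numeric(0))
  map <- if (sex == "male") chrom$map_male else chrom$map_female
  cm <- as.numeric(morgans) * 100
  if (any(cm < 0 | cm > map[nrow(map), 2] + 1e-9)) {
    stop("genetic position outside chromosome ", chrom$name)
  }
  stats::approx(map[, 2], map[, 1], xout = cm, ties = min)$y
}

# genetic length of a chromosome (Morgans) for a parent of given sex
genetic_length <- function(chrom, sex) {
  genetic_position(chrom, chrom$length_bp, sex)
}

#' Assemble a genome from founder metadata
#'
#' Collects the chromosomes observed in a founder panel into a genome object:
#' chromosome kinds are assigned by name, recombination maps attached from an
#' optional map file, and lengths default to the last observed SNP position
#' (or the last map anchor, whichever is larger). By convention a chromosome
#' named `"X"` is the sex X, `"Y"` the sex Y, and `"MT"` mitochondrial; the
#' `chrom_kinds` argument overrides or extends this.
#'
#' @param founders A founder panel from [read_founder_vcf()] or
#'   [read_pedlike()].
#' @param chrom_kinds Named character vector mapping chromosome names to kinds
#'   (`"autosome"`, `"sex_x"`, `"sex_y"`, `"mito"`), e.g.
#'   `c(X = "sex_x", MT = "mito")`. Chromosomes not named are autosomes.
#' @param map_file Optional path to a recombination-map file: whitespace
#'   columns `chrom bp cM_female [cM_male]`, cumulative cM, optional header.
#' @param auto_kinds If `TRUE` (default), names `X`, `Y`, `MT` get their
#'   conventional kinds before `chrom_kinds` is applied.
#' @return An object of class `bs_genome` with fields `ploidy`, `chromosomes`
#'   (named list of [chromosome()] objects) and `snps` (tibble of `chr`,
#'   `pos`, `index` aligned with the founder haplotype matrix rows).
#' @export
build_genome <- function(founders, chrom_kinds = NULL, map_file = NULL,
                         auto_kinds = TRUE) {
  snps <- founders$snps
  chr_names <- unique(snps$chr)

  kinds <- stats::setNames(rep("autosome", length(chr_names)), chr_names)
  if (auto_kinds) {
    for (nm in intersect(c("X", "Y", "MT"), chr_names)) {
      kinds[nm] <- c(X = "sex_x", Y = "sex_y", MT = "mito")[[nm]]
    }
  }
  if (!is.null(chrom_kinds)) {
    bad <- setdiff(names(chrom_kinds), chr_names)
    if (length(bad)) {
      stop("chrom_kinds names unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
    kinds[names(chrom_kinds)] <- chrom_kinds
  }
  for (k in c("sex_x", "sex_y", "mito")) {
    if (sum(kinds == k) > 1) stop("at most one chromosome of kind '", k, "' allowed")
  }

  maps <- if (is.null(map_file)) NULL else read_map_file(map_file)
  if (!is.null(maps)) {
    bad <- setdiff(names(maps), chr_names)
    if (length(bad)) {
      stop("map file names unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
  }

  chromosomes <- lapply(chr_names, function(nm) {
    last_snp <- max(snps$pos[snps$chr == nm])
    m <- maps[[nm]]
    len <- if (is.null(m)) last_snp else max(last_snp, max(m$bp))
    chromosome(
      name = nm, length_bp = len, kind = kinds[[nm]],
      map_female = if (is.null(m)) NULL else cbind(m$bp, m$cm_female),
      map_male = if (is.null(m)) NULL else cbind(m$bp, m$cm_male)
    )
  })
  names(chromosomes) <- chr_names

  structure(
    list(
      ploidy = founders$ploidy,
      chromosomes = chromosomes,
      snps = tibble::tibble(
        chr = snps$chr, pos = snps$pos,
        index = seq_len(nrow(snps))
      )
    ),
    class = "bs_genome"
  )
}

# Parse a map file: chrom bp cM_female [cM_male]; header detected by a
# non-numeric second field. Returns a named list of tibbles per chromosome.
read_map_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty map file: ", path)
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[[2]])))) {
    lines <- lines[-1]
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- lengths(fields)
  if (any(ncol < 3 | ncol > 4)) {
    stop("map file rows must have 3 or 4 fields (chrom bp cM_female [cM_male])")
  }
  df <- tibble::tibble(
    chr = vapply(fields, `[[`, "", 1L),
    bp = as.numeric(vapply(fields, `[[`, "", 2L)),
    cm_female = as.numeric(vapply(fields, `[[`, "", 3L))
  )
  df$cm_male <- ifelse(
    ncol == 4,
    suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""))),
    df$cm_female
  )
  if (anyNA(df$bp) || anyNA(df$cm_female) || anyNA(df$cm_male)) {
    stop("non-numeric values in map file: ", path)
  }
  split(df[-1], df$chr)
}

#' @export
print.bs_genome <- function(x, ...) {
  cat("<bs_genome> ploidy", x$ploidy, "|", length(x$chromosomes), "chromosome(s),",
      nrow(x$snps), "SNPs\n")
  for (ch in x$chromosomes) {
    n <- sum(x$snps$chr == ch$name)
    cat(sprintf(
      "  %-6s %-8s %10.0f bp  %6.2f cM (F) %6.2f cM (M)  %d SNPs\n",
      ch$name, ch$kind, ch$length_bp,
      100 * genetic_length(ch, "female"), 100 * genetic_length(ch, "male"), n
    ))
  }
  invisible(x)
}
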