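#' Define a breeding-program plan
#'
#' Collects the parameters of the three-step selection cycle (evaluate,
#' select, mate): generations to run, numbers of females and males selected by
#' truncation on EBV, family size, the evaluation method and chip, the mating
#' scheme among selected parents, and whether generations are discrete
#' (candidates come only from the newest cohort) or continuous (all non-parent
#' individuals so far are candidates).
#'
#' @param n_generations Number of selection cycles.
#' @param n_females,n_males Numbers of dams and sires selected each cycle.
#' @param offspring_per_female Family size; the next cohort has
#'   `n_females * offspring_per_female` individuals.
#' @param method Evaluation method: `"mass"`, `"blup"`, `"gblup"`,
#'   `"ssgblup"`.
#' @param chip `bs_chip` used by the genomic methods.
#' @param mating `"hierarchical"` (default: each sire gets a block of
#'   `ceiling(n_females / n_males)` dams, remainder to the top sires),
#'   `"random"` (each dam gets a uniformly drawn sire) or `"assortative"`
#'   (dams and sires rank-matched on EBV).
#' @param generations `"discrete"` or `"continuous"`.
#' @param h2 Heritability used by BLUP-type methods (default: the
#'   architecture's target).
#' @param trait Trait under selection.
#' @return A `bs_plan` object.
#' @export
selection_plan <- function(n_generations, n_females, n_males,
                           offspring_per_female,
                           method = c("mass", "blup", "gblup", "ssgblup"),
                           chip = NULL,
                           mating = c("hierarchical", "random", "assortative"),
                           generations = c("discrete", "continuous"),
                           h2 = NULL, trait = 1) {
  method <- match.arg(method)
  mating <- match.arg(mating)
  generations <- match.arg(generations)
  if (any(c(n_generations, n_females, n_males, offspring_per_female) < 1)) {
    stop("plan counts must be positive")
  }
  if (method %in% c("gblup", "ssgblup") && is.null(chip)) {
    stop(method, " selection requires a chip")
  }
  if (n_males > n_females) {
    warning("more sires than dams selected; hierarchy is degenerate ",
            "(one dam per top sire)")
  }
  structure(
    list(
      n_generations = as.integer(n_generations),
      n_females = as.integer(n_females), n_males = as.integer(n_males),
      offspring_per_female = as.integer(offspring_per_female),
      method = method, chip = chip, mating = mating,
      generations = generations, h2 = h2, trait = trait
    ),
    class = "bs_plan"
  )
}

#' Truncation selection on EBV
#'
#' Picks the top `n_f` females and top `n_m` males among the candidates by
#' EBV; ties are broken by ascending id so runs are reproducible.
#'
#' @param candidates Data frame with columns `id`, `sex` (`F`/`M`) and `ebv`.
#' @param n_f,n_m Numbers to select within each sex.
#' @return List with elements `females` and `males`, each a tibble of `id`,
#'   `ebv` in selection order.
#' @export
select_parents <- function(candidates, n_f, n_m) {
  pick <- function(s, n) {
    pool <- candidates[candidates$sex == s & !is.na(candidates$ebv), ]
    if (nrow(pool) < n) {
      stop("only ", nrow(pool), " ", if (s == "F") "female" else "male",
           " candidates for ", n, " selections")
    }
    pool <- pool[order(-pool$ebv, pool$id), ]
    tibble::as_tibble(pool[seq_len(n), c("id", "ebv")])
  }
  list(females = pick("F", n_f), males = pick("M", n_m))
}

#' Build the mating list for one cycle
#'
#' Assigns selected dams to selected sires under the plan's scheme:
#' hierarchical blocks (default), uniform random sires, or assortative
#' rank-matching on EBV.
#'
#' @param selected List from [select_parents()].
#' @param mating `"hierarchical"`, `"random"` or `"assortative"`.
#' @return A tibble of `(dam, sire)` pairs, one row per selected dam.
#' @export
return_new_ped <- function(selected,
                           mating = c("hierarchical", "random", "assortative")) {
  mating <- match.arg(mating)
  dams <- selected$females
  sires <- selected$males
  nf <- nrow(dams)
  nm <- nrow(sires)
  sire_for_dam <- switch(mating,
    hierarchical = {
      per <- ceiling(nf / nm)
      rep(sires$id, each = per, length.out = nf)
    },
    random = sires$id[sample.int(nm, nf, replace = TRUE)],
    assortative = {
      per <- ceiling(nf / nm)
      # both lists are already in descending EBV order
      rep(sires$id, each = per, length.out = nf)
    }
  )
  if (mating == "random") {
    dam_order <- dams$id
  } else if (mating == "hierarchical") {
    dam_order <- dams$id[order(dams$id)] # block structure, not merit-matched
  } else {
    dam_order <- dams$id # merit order: top dam with top sire
  }
  tibble::tibble(dam = dam_order, sire = sire_for_dam)
}

#' Run a multi-generation breeding program
#'
#' Repeats the three-step cycle for `plan$n_generations`: (1) EBVs are
#' computed with the chosen method, by default from all individuals simulated
#' so far; (2) the top females and males among the candidates are selected by
#' truncation; (3) offspring are generated under the mating scheme and
#' phenotyped at birth. Per-generation means/variances of phenotype and
#' genotypic value and the realized accuracy `cor(EBV, g)` among candidates
#' are recorded.
#'
#' @param pop A phenotyped `bs_pop` population.
#' @param plan A [selection_plan()].
#' @return An object of class `bs_selection`: list with `population` (the
#'   extended population) and `summary` (per-generation tibble). `tidy()`
#'   returns the summary.
#' @export
run_cycles <- function(pop, plan) {
  if (is.null(pop$arch)) stop("attach an architecture before running selection")
  trait <- plan$trait
  used_parents <- integer(0)
  summaries <- list()

  for (cycle in seq_len(plan$n_generations)) {
    current_gen <- max(pop$ped$generation)
    window <- pop$ped$id
    ev <- predict_ebv(pop, method = plan$method, h2 = plan$h2,
                      chip = plan$chip, ids = window, trait = trait)
    ebv_map <- stats::setNames(ev$ebv$ebv, ev$ebv$id)

    cand_ids <- if (plan$generations == "discrete") {
      pop$ped$id[pop$ped$generation == current_gen]
    } else {
      setdiff(pop$ped$id, used_parents)
    }
    candidates <- tibble::tibble(
      id = cand_ids,
      sex = pop$ped$sex[match(cand_ids, pop$ped$id)],
      ebv = unname(ebv_map[as.character(cand_ids)])
    )
    sel <- select_parents(candidates, plan$n_females, plan$n_males)
    matings <- return_new_ped(sel, plan$mating)
    used_parents <- union(used_parents, c(sel$females$id, sel$males$id))

    g_cand <- pop$g[match(candidates$id, rownames(pop$g)), trait]
    acc <- suppressWarnings(stats::cor(candidates$ebv, g_cand))
    summaries[[cycle]] <- tibble::tibble(
      generation = current_gen,
      n_candidates = nrow(candidates),
      accuracy = acc
    )

    for (r in seq_len(nrow(matings))) {
      pop <- add_offspring(pop, matings$dam[r], matings$sire[r],
                           n = plan$offspring_per_female,
                           generation = current_gen + 1L)
    }
  }

  acc_tbl <- dplyr::bind_rows(summaries)
  summary <- summarize_population(pop, trait = trait) |>
    dplyr::left_join(acc_tbl, by = "generation")
  structure(
    list(population = pop, summary = summary, plan = plan),
    class = "bs_selection"
  )
}

#' @export
print.bs_selection <- function(x, ...) {
  cat("<bs_selection>", x$plan$method, "selection,", x$plan$n_generations,
      "cycle(s)\n")
  print(x$summary)
  invisible(x)
}
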