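#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy bs_ebv
#' @export
tidy.bs_ebv <- function(x, ...) x$ebv

#' @method glance bs_ebv
#' @export
glance.bs_ebv <- function(x, ...) {
  tibble::tibble(
    method = x$method, chip = x$chip, h2 = x$h2,
    n = nrow(x$ebv), n_phenotyped = length(x$phenotyped)
  )
}

#' @method tidy bs_pca
#' @export
tidy.bs_pca <- function(x, ...) x$scores

#' @method glance bs_pca
#' @export
glance.bs_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_components = length(x$var_explained),
    var_explained_total = sum(x$var_explained)
  )
}

#' @method tidy bs_selection
#' @export
tidy.bs_selection <- function(x, ...) x$summary

#' @method glance bs_selection
#' @export
glance.bs_selection <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    method = x$plan$method,
    n_generations = x$plan$n_generations,
    n_individuals = nrow(x$population$ped),
    response_g = s$mean_g[nrow(s)] - s$mean_g[1]
  )
}

#' Manhattan-style GWAS plot
#'
#' @param object A `bs_gwas` tibble.
#' @param fdr Plot `-log10(q)` instead of `-log10(p)`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_gwas
#' @export
autoplot.bs_gwas <- function(object, fdr = FALSE, ...) {
  val <- if (fdr) object$q else object$p
  df <- tibble::tibble(
    chr = factor(object$chr, levels = unique(object$chr)),
    pos = object$pos, neglog = -log10(pmax(val, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$neglog,
                                   colour = .data$chr)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(~chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = if (fdr) expression(-log[10](q)) else expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' PCA scatter plot
#'
#' @param object A `bs_pca` object.
#' @param ... Unused.
#' @return A ggplot of the first two components, coloured by generation when
#'   available.
#' @method autoplot bs_pca
#' @export
autoplot.bs_pca <- function(object, ...) {
  df <- object$scores
  pct <- signif(100 * object$var_explained[1:2], 3)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if ("generation" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$generation))) +
      ggplot2::labs(colour = "generation")
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                    y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Selection-response plot
#'
#' @param object A `bs_selection` result.
#' @param ... Unused.
#' @return A ggplot of mean genotypic and phenotypic value by generation.
#' @method autoplot bs_selection
#' @export
autoplot.bs_selection <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("mean_g", "mean_y"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation", y = "mean value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' QTN variance diagnostic plots
#'
#' Three stacked panels per trait: per-QTN variance against MAF, the histogram
#' of QTN variances, and the cumulative variance with QTN sorted by MAF.
#' Additive and dominance components are overlaid.
#'
#' @param object A `bs_qtnvar` tibble from [qtn_variance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_qtnvar
#' @export
autoplot.bs_qtnvar <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("var_a", "var_d"),
                        names_to = "component", values_to = "variance") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            var_a = "additive",
                                            var_d = "dominance"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$maf, y = .data$variance,
                                     colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "MAF", y = "per-QTN variance", colour = NULL) +
    ggplot2::theme_minimal()
}
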