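#' Fold-change area statistic
#'
#' The per-group repression readout: mean background M minus mean target M.
#' Positive values mean the target genes are, on average, more inhibited
#' than background. The statistic equals the signed area between the target
#' and background empirical cumulative M-value distributions, hence the
#' "area" reading of the cumulative plots.
#'
#' @param target_m Numeric vector of M values for the target group.
#' @param background_m Numeric vector of M values for the group's background.
#' @return A single numeric statistic.
#' @examples
#' fold_change_area(c(-1, -1), c(0, 0)) # 1
#' @export
fold_change_area <- function(target_m, background_m) {
  if (length(target_m) == 0 || length(background_m) == 0) {
    stop("fold-change area undefined for empty samples", call. = FALSE)
  }
  mean(background_m) - mean(target_m)
}

#' Wilcoxon rank-sum test of target vs background M values
#'
#' Tests whether the target-group M distribution differs from background.
#' The default alternative `"less"` asks whether targets sit lower
#' (more repressed) than background. For small pooled samples
#' (`n + m <= 12`) the p-value is computed by exact enumeration of all
#' `choose(n + m, n)` group labelings of the pooled ranks, which stays exact
#' under ties; larger samples use the normal approximation with continuity
#' and tie correction.
#'
#' @param target_m,background_m Numeric M-value vectors.
#' @param alternative `"less"` (targets lower; default), `"greater"`, or
#'   `"two.sided"`.
#' @return List with `p_value`, `statistic` (rank sum of the target sample),
#'   `method` (`"exact"` or `"normal"`), and `alternative`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value # 0.05 by enumeration
#' @export
rank_sum_test <- function(target_m, background_m,
                          alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(target_m); m <- length(background_m)
  if (n == 0 || m == 0) stop("rank-sum test undefined for empty samples", call. = FALSE)
  pooled <- c(target_m, background_m)
  if (length(unique(pooled)) == 1) {
    warning("constant pooled data: rank-sum test degenerate, p = 1", call. = FALSE)
    return(list(p_value = 1, statistic = sum(rank(pooled)[seq_len(n)]),
                method = "degenerate", alternative = alternative))
  }
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  if (n + m <= 12) {
    combs <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[combs], nrow = n))
    p_less <- mean(w_all <= w_obs)
    p_greater <- mean(w_all >= w_obs)
    p <- switch(alternative,
                less = p_less,
                greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    return(list(p_value = p, statistic = w_obs, method = "exact",
                alternative = alternative))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(target_m, background_m, alternative = alternative,
                       exact = FALSE, correct = TRUE)
  )
  list(p_value = unname(ht$p.value), statistic = w_obs, method = "normal",
       alternative = alternative)
}

#' Empirical cumulative distribution of M values
#'
#' The cumulative-curve representation of a group's M values: sorted unique
#' M with the cumulative fraction of genes at or below each value
#' (right-continuous ECDF). Duplicated values collapse into a single step.
#'
#' @param m_values Numeric vector (non-empty).
#' @return Tibble with `M` (sorted unique values) and `fraction`.
#' @export
cumulative_curve <- function(m_values) {
  if (length(m_values) == 0) stop("cumulative curve of empty sample", call. = FALSE)
  x <- sort(unique(m_values))
  tibble::tibble(M = x, fraction = stats::ecdf(m_values)(x))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation with validation; used to relate measured
#' seed-duplex melting temperatures to silencing readouts (microarray
#' fold-changes, or user-supplied reporter measurements).
#'
#' @param xs,ys Equal-length numeric vectors, length >= 3, non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("inputs must have equal length", call. = FALSE)
  if (length(xs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(xs, ys, method = "pearson")
}

#' qRT-PCR relative expression (delta-delta-Ct)
#'
#' Double normalization of quantification cycles: first to a reference gene
#' (e.g. LDHA), then to the mock transfection control. Relative expression
#' is `2^-ddCt`.
#'
#' @param ct_target,ct_reference Ct values in the treated sample.
#' @param ct_target_mock,ct_reference_mock Ct values in the mock sample.
#' @return Fold expression relative to mock (1 = unchanged).
#' @examples
#' qpcr_relative_expression(21, 20, 20, 20) # 0.5
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_mock, ct_reference_mock) {
  vals <- c(ct_target, ct_reference, ct_target_mock, ct_reference_mock)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target - ct_reference) - (ct_target_mock - ct_reference_mock)
  2^(-ddct)
}

#' Per-group repression statistics for one contrast
#'
#' Joins a per-gene M table with target-group assignments and computes, for
#' each of the four groups, the fold-change area statistic and rank-sum
#' p-value of target vs background M values.
#'
#' @param ma M/A tibble for a single contrast (columns `gene_id`, `M`).
#' @param tg A `target_groups` object ([assign_target_groups()]).
#' @param alternative Sidedness passed to [rank_sum_test()].
#' @param alpha Significance threshold (default `1e-2`).
#' @return A `group_comparison` tibble: one row per group with `group`,
#'   `n_target`, `n_background`, `fold_change`, `p_value`, `significant`,
#'   and list-columns `target_M`, `background_M` holding the underlying
#'   samples (dropped by [tidy.group_comparison()]).
#' @export
compare_groups <- function(ma, tg, alternative = c("less", "greater", "two.sided"),
                           alpha = 1e-2) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(tg, "target_groups"))
  mvals <- stats::setNames(ma$M, ma$gene_id)
  rows <- lapply(c("A", "C", "G", "U"), function(g) {
    tm <- mvals[intersect(group_members(tg, g), names(mvals))]
    bm <- mvals[intersect(group_background(tg, g), names(mvals))]
    if (length(tm) == 0 || length(bm) == 0) {
      return(tibble::tibble(group = g, n_target = length(tm),
                            n_background = length(bm),
                            fold_change = NA_real_, p_value = NA_real_,
                            significant = NA,
                            target_M = list(unname(tm)),
                            background_M = list(unname(bm))))
    }
    fc <- fold_change_area(tm, bm)
    p <- rank_sum_test(tm, bm, alternative)$p_value
    tibble::tibble(group = g, n_target = length(tm), n_background = length(bm),
                   fold_change = fc, p_value = p, significant = p < alpha,
                   target_M = list(unname(tm)), background_M = list(unname(bm)))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("group_comparison", class(out)),
            alternative = alternative, alpha = alpha)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> alternative=", attr(x, "alternative"),
      ", alpha=", format(attr(x, "alpha")), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-group repression statistics
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble without the sample list-columns.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(x)[c("group", "n_target", "n_background",
                         "fold_change", "p_value", "significant")]
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble with the number of groups tested, the most repressed
#'   (largest fold-change) group and its statistics.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  td <- tidy(x)
  ok <- which(!is.na(td$fold_change))
  best <- if (length(ok)) ok[which.max(td$fold_change[ok])] else NA_integer_
  tibble::tibble(
    n_groups = nrow(td),
    n_significant = sum(td$significant, na.rm = TRUE),
    top_group = if (is.na(best)) NA_character_ else td$group[best],
    top_fold_change = if (is.na(best)) NA_real_ else td$fold_change[best],
    top_p_value = if (is.na(best)) NA_real_ else td$p_value[best],
    alpha = attr(x, "alpha")
  )
}

#' Cumulative-distribution plot of target vs background M values
#'
#' Reconstructs the cumulative-fraction view: one panel per group, target
#' curve in red, background in black; the horizontal gap between the curves
#' is the fold-change area statistic.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  dat <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    dplyr::bind_rows(
      if (length(object$target_M[[i]]))
        dplyr::mutate(cumulative_curve(object$target_M[[i]]),
                      group = object$group[i], set = "target"),
      if (length(object$background_M[[i]]))
        dplyr::mutate(cumulative_curve(object$background_M[[i]]),
                      group = object$group[i], set = "background")
    )
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$M, y = .data$fraction,
                                    colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(target = "red", background = "black")) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "M (log2 vs mock)", y = "cumulative fraction of mRNAs",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
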