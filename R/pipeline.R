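#' Read 3'-UTR sequences from FASTA
#'
#' Multi-line FASTA, case-insensitive, DNA or RNA alphabet; `T` is
#' normalized to `U` and the record id (first whitespace-delimited token)
#' becomes `gene_id`.
#'
#' @param path FASTA file path.
#' @return UTR tibble ([as_utr_table()]).
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  as_utr_table(tibble::tibble(gene_id = ids,
                              sequence = unname(as.character(set))))
}

#' Write 3'-UTR sequences to FASTA
#'
#' @param utrs UTR tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  utrs <- as_utr_table(utrs)
  set <- Biostrings::RNAStringSet(stats::setNames(utrs$sequence, utrs$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write a probe-level expression matrix as TSV
#'
#' Columns: `probe_id`, `gene_id`, then `<sample>.intensity` (numeric) and
#' `<sample>.detected` (logical) per sample.
#'
#' @param path TSV file path.
#' @return Probe-level tibble.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expression_samples(x) # validates schema
  x
}

#' @rdname read_expression_tsv
#' @param probes Probe-level tibble.
#' @export
write_expression_tsv <- function(probes, path) {
  readr::write_tsv(probes, path, progress = FALSE)
  invisible(path)
}

#' Read a UV melting curve from two-column CSV
#'
#' Expects columns `temperature` (degrees C) and `absorbance` (A260), or an
#' unnamed two-column file in that order.
#'
#' @param path CSV file path.
#' @return Validated melting-curve tibble.
#' @export
read_melting_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("temperature", "absorbance") %in% names(x)) && ncol(x) == 2) {
    names(x) <- c("temperature", "absorbance")
  }
  as_melting_curve(x)
}

#' Read a miRNA duplex definition from a YAML config
#'
#' Keys: `name`, `edited_strand`, `opposite_strand` (sequences 5'->3'),
#' `edit_position` (1-based), optional `opposite_name`.
#'
#' @param path YAML file path.
#' @return A [mirna_duplex()].
#' @export
read_duplex_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "edited_strand", "opposite_strand", "edit_position")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("duplex config missing keys: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  mirna_duplex(
    mirna_strand(cfg$name, cfg$edited_strand,
                 edit_position = cfg$edit_position),
    mirna_strand(cfg$opposite_name %||% paste0(cfg$name, "-opposite"),
                 cfg$opposite_strand)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted Tm of the 5'-terminal 5-bp duplex (miTm 1-5)
#'
#' Nearest-neighbor prediction for the duplex formed by positions 1-5 of the
#' edited strand and the pairing bases of the opposite strand (canonical
#' 2-nt 3' overhang register). 5-bp duplexes are too unstable to melt
#' reliably in vitro, so this quantity is predicted rather than measured;
#' when the 5-bp window is not fully Watson-Crick the result is `NA`.
#'
#' @param duplex A [mirna_duplex()].
#' @param params,conc Passed to [predict_tm_nn()].
#' @param overhang 3' overhang length assumed for the pairing register.
#' @return Tm in degrees Celsius, or `NA_real_`.
#' @export
mitm_1_5 <- function(duplex, params = nn_parameters(), conc = 5e-6,
                     overhang = 2L) {
  stopifnot(inherits(duplex, "mirna_duplex"))
  g <- duplex$edited_strand$sequence
  p <- duplex$opposite_strand$sequence
  jj <- (nchar(p) - overhang) - (1:5) + 1L
  if (any(jj < 1 | jj > nchar(p))) return(NA_real_)
  opp <- paste(rev(strsplit(p, "")[[1]][jj]), collapse = "") # 5'->3'
  tryCatch(predict_tm_nn(substr(g, 1, 5), opp, conc = conc, params = params),
           error = function(e) NA_real_)
}

#' Run the full silencing analysis for one miRNA duplex
#'
#' End-to-end orchestration of the analysis workflow: derive the editing
#' variant seeds and the four target motifs plus the dead seed; preprocess
#' the probe matrix (detection filter, quantile normalization, probe
#' averaging, M/A contrasts vs mock); restrict the universe to genes present
#' in both the UTR set and the filtered expression table; assign target
#' groups; compute per-(variant, group) fold-change area statistics and
#' rank-sum p-values; attach seed-duplex Tm values (measured calibration
#' first, optional nearest-neighbor fallback) and miScore; and correlate Tm
#' with fold-change across duplex types. Deterministic given its inputs.
#'
#' @param utrs UTR tibble (e.g. [read_utr_fasta()]).
#' @param probes Probe-level expression tibble.
#' @param duplex A [mirna_duplex()]; its editing variants are taken from
#'   `variants`.
#' @param mock Mock sample name (default `"mock"`).
#' @param variants miRNA variants analyzed; must match non-mock sample
#'   names in `probes`.
#' @param alternative Rank-sum sidedness (default `"less"`: targets more
#'   repressed).
#' @param alpha Significance threshold (default `1e-2`).
#' @param calibration Measured-Tm table (default [calibration_table()]).
#' @param nn_params NN parameters (default [nn_parameters()]).
#' @param conc Strand concentration for predictions (mol/L).
#' @param fallback_nn Predict Tm when a calibration key is absent?
#' @return A `silencing_report` list: `groups` (the `target_groups`),
#'   `comparisons` (tibble: variant x group statistics), `thermo` (tibble:
#'   variant, group, seed, target, tm, provenance, miScore), `correlation`
#'   (list `r`, `n`), `mitm_1_5`, and `params` (the thresholds used).
#' @export
run_silencing_analysis <- function(utrs, probes, duplex = mir376a2_duplex(),
                                   mock = "mock", variants = c("A", "I", "G"),
                                   alternative = c("less", "greater", "two.sided"),
                                   alpha = 1e-2,
                                   calibration = calibration_table(),
                                   nn_params = nn_parameters(), conc = 5e-6,
                                   fallback_nn = FALSE) {
  alternative <- match.arg(alternative)
  st <- duplex_seed_table(duplex, variants)

  prep <- prepare_expression(probes, mock)
  missing_samples <- setdiff(variants, unique(prep$ma$sample))
  if (length(missing_samples)) {
    stop("expression matrix lacks samples for variants: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }

  utrs <- as_utr_table(utrs)
  universe <- intersect(utrs$gene_id, prep$gene_expr$gene_id)
  utrs_u <- restrict_ids(utrs, universe)
  tg <- assign_target_groups(utrs_u, st$motifs, st$dead)

  comparisons <- dplyr::bind_rows(lapply(variants, function(v) {
    ma_v <- prep$ma[prep$ma$sample == v & prep$ma$gene_id %in% universe, ]
    cmp <- compare_groups(ma_v, tg, alternative = alternative, alpha = alpha)
    dplyr::mutate(tidy(cmp), variant = v, .before = 1)
  }))

  mitm <- mitm_1_5(duplex, params = nn_params, conc = conc)
  thermo <- dplyr::bind_rows(lapply(variants, function(v) {
    seed_v <- st$seeds$seed[st$seeds$variant == v]
    dplyr::bind_rows(lapply(seq_len(nrow(st$motifs)), function(i) {
      res <- seed_duplex_tm(seed_v, st$motifs$motif[i], method = "lookup",
                            table = calibration, params = nn_params,
                            conc = conc, fallback_nn = fallback_nn)
      tibble::tibble(variant = v, group = st$motifs$group[i], seed = seed_v,
                     target = st$motifs$motif[i], tm_C = res$tm,
                     provenance = res$provenance,
                     miscore = if (is.finite(res$tm) && is.finite(mitm))
                       miscore(res$tm, mitm) else NA_real_)
    }))
  }))

  paired <- dplyr::inner_join(
    thermo[c("variant", "group", "tm_C")],
    comparisons[c("variant", "group", "fold_change")],
    by = c("variant", "group")
  )
  paired <- paired[is.finite(paired$tm_C) & is.finite(paired$fold_change), ]
  correlation <- if (nrow(paired) >= 3) {
    list(r = pearson_r(paired$tm_C, paired$fold_change), n = nrow(paired))
  } else {
    list(r = NA_real_, n = nrow(paired))
  }

  structure(
    list(groups = tg, comparisons = comparisons, thermo = thermo,
         correlation = correlation, mitm_1_5 = mitm,
         params = list(mock = mock, variants = variants,
                       alternative = alternative, alpha = alpha,
                       conc = conc, fallback_nn = fallback_nn,
                       n_universe = length(universe))),
    class = "silencing_report"
  )
}

#' @export
print.silencing_report <- function(x, ...) {
  cat("<silencing_report> ", x$params$n_universe, " genes | variants ",
      paste(x$params$variants, collapse = "/"), "\n", sep = "")
  print(tidy(x))
  if (is.finite(x$correlation$r)) {
    cat(sprintf("Tm vs fold-change Pearson r = %.2f (n = %d)\n",
                x$correlation$r, x$correlation$n))
  }
  invisible(x)
}

#' Tidy per-(variant, group) report rows
#'
#' @param x A `silencing_report`.
#' @param ... Unused.
#' @return Tibble joining repression statistics with Tm and miScore.
#' @method tidy silencing_report
#' @export
tidy.silencing_report <- function(x, ...) {
  dplyr::left_join(x$comparisons,
                   x$thermo[c("variant", "group", "tm_C", "provenance", "miscore")],
                   by = c("variant", "group"))
}

#' One-row study summary
#'
#' @param x A `silencing_report`.
#' @param ... Unused.
#' @return Tibble with universe size, significant combinations, and the
#'   Tm/fold-change correlation.
#' @method glance silencing_report
#' @export
glance.silencing_report <- function(x, ...) {
  tibble::tibble(
    n_universe = x$params$n_universe,
    n_combinations = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant, na.rm = TRUE),
    tm_foldchange_r = x$correlation$r,
    n_tm_pairs = x$correlation$n,
    alpha = x$params$alpha
  )
}

#' Fold-change heat view of a silencing report
#'
#' Variant-by-group tile plot of the fold-change area statistic, with
#' significant combinations outlined.
#'
#' @param object A `silencing_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot silencing_report
#' @export
autoplot.silencing_report <- function(object, ...) {
  d <- object$comparisons
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$variant,
                                  fill = .data$fold_change)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$fold_change), "",
                     sprintf("%.3f%s", .data$fold_change,
                             ifelse(!is.na(.data$significant) & .data$significant,
                                    "*", ""))))) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "target group", y = "miRNA variant",
                  fill = "fold-change\n(area)") +
    ggplot2::theme_minimal()
}

#' Write the per-group report to TSV
#'
#' @param report A `silencing_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(tidy(report), path, progress = FALSE)
  invisible(path)
}

#' Scatter plot of Tm versus silencing fold-change
#'
#' @param data Tibble with `tm_C` and a readout column (default
#'   [mir376a2_reference()]).
#' @param readout Readout column name.
#' @return A ggplot object annotated with the Pearson r.
#' @export
plot_tm_correlation <- function(data = mir376a2_reference(),
                                readout = "fold_change") {
  res <- correlate_tm_silencing(data, readout)
  ggplot2::ggplot(res$data,
                  ggplot2::aes(x = .data$tm_C, y = .data[[readout]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::labs(x = "seed-duplex Tm (°C)", y = readout,
                  subtitle = sprintf("Pearson r = %.2f (n = %d)", res$r, res$n)) +
    ggplot2::theme_bw()
}
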