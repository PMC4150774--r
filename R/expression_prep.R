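#' Probe-level expression table schema
#'
#' The probe matrix is a tibble with one row per probe: `probe_id`,
#' `gene_id`, one numeric intensity column per sample named
#' `<sample>.intensity`, and one logical column per sample named
#' `<sample>.detected` (the "detected with certainty" flag of the array
#' platform). Helpers below discover the sample names from the columns.
#'
#' @param x A data frame in the above schema.
#' @return Character vector of sample names.
#' @export
expression_samples <- function(x) {
  ints <- grep("\\.intensity$", names(x), value = TRUE)
  dets <- grep("\\.detected$", names(x), value = TRUE)
  samples <- sub("\\.intensity$", "", ints)
  if (!setequal(samples, sub("\\.detected$", "", dets))) {
    stop("every sample needs both <sample>.intensity and <sample>.detected columns",
         call. = FALSE)
  }
  if (length(samples) == 0) stop("no sample columns found", call. = FALSE)
  samples
}

int_cols <- function(samples) paste0(samples, ".intensity")
det_cols <- function(samples) paste0(samples, ".detected")

#' Keep only probes detected with certainty in every sample
#'
#' Spots must carry a TRUE detection flag in all samples to survive; this
#' also keeps signals inside the linear range, which later justifies
#' averaging probe intensities per gene on the linear scale.
#'
#' @param probes Probe-level tibble (see [expression_samples()]).
#' @return Filtered tibble.
#' @export
filter_detected <- function(probes) {
  probes <- tibble::as_tibble(probes)
  samples <- expression_samples(probes)
  flags <- as.matrix(probes[det_cols(samples)])
  if (anyNA(flags)) stop("detection flags contain NA", call. = FALSE)
  probes[rowSums(flags) == length(samples), , drop = FALSE]
}

#' Quantile-normalize intensities across samples
#'
#' Forces every sample's intensity distribution to the common distribution
#' given by the across-sample mean of sorted values; ties receive the mean
#' of their tied ranks' values. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param probes Probe-level tibble with positive intensities.
#' @return Tibble with normalized `<sample>.intensity` columns.
#' @export
quantile_normalize <- function(probes) {
  probes <- tibble::as_tibble(probes)
  samples <- expression_samples(probes)
  m <- as.matrix(probes[int_cols(samples)])
  if (nrow(m) < 1) return(probes)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("intensities must be positive and finite for normalization", call. = FALSE)
  }
  if (length(samples) < 2) {
    warning("single sample: quantile normalization is a no-op", call. = FALSE)
    return(probes)
  }
  probes[int_cols(samples)] <- as.data.frame(limma::normalizeQuantiles(m, ties = TRUE))
  probes
}

#' Average plural probes per gene
#'
#' Arithmetic mean on the linear intensity scale, per gene and sample.
#' Genes left with zero probes (e.g. after the detection filter) are simply
#' absent from the output.
#'
#' @param probes Probe-level tibble (normally after [quantile_normalize()]).
#' @return Gene-level tibble: `gene_id` plus one `<sample>` intensity column
#'   per sample.
#' @export
aggregate_probes <- function(probes) {
  probes <- tibble::as_tibble(probes)
  samples <- expression_samples(probes)
  out <- probes |>
    dplyr::select("gene_id", dplyr::all_of(int_cols(samples))) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  names(out) <- c("gene_id", samples)
  out
}

#' Per-gene M and A values of a miRNA-vs-mock contrast
#'
#' M is the log2 ratio of the miRNA-transfected sample over mock;
#' A is the average of the log10 intensities of the two samples (the mixed
#' log bases are deliberate and follow the original analysis). Negative M
#' means the gene is repressed relative to mock.
#'
#' @param gene_expr Gene-level tibble from [aggregate_probes()].
#' @param sample Name of the miRNA-transfected sample column.
#' @param mock Name of the mock sample column.
#' @return Tibble `gene_id`, `M`, `A`, `contrast`.
#' @examples
#' ge <- tibble::tibble(gene_id = "g", s = 4, mock = 1)
#' compute_ma(ge, "s", "mock") # M = 2
#' @export
compute_ma <- function(gene_expr, sample, mock) {
  gene_expr <- tibble::as_tibble(gene_expr)
  for (col in c(sample, mock)) {
    if (!col %in% names(gene_expr)) stop("sample column not found: ", col, call. = FALSE)
  }
  s <- gene_expr[[sample]]
  m <- gene_expr[[mock]]
  if (any(s <= 0 | m <= 0)) {
    stop("intensities must be strictly positive to form log ratios", call. = FALSE)
  }
  tibble::tibble(
    gene_id = gene_expr$gene_id,
    M = log2(s / m),
    A = (log10(s) + log10(m)) / 2,
    contrast = paste0(sample, "_vs_", mock)
  )
}

#' Probe matrix to M/A tables for every non-mock sample
#'
#' Runs the fixed preprocessing order — detection filter, quantile
#' normalization, probe averaging — and computes M/A contrasts of every
#' remaining sample against the designated mock.
#'
#' @param probes Probe-level tibble.
#' @param mock Mock (control transfection) sample name.
#' @return List with `gene_expr` (gene-level intensities) and `ma`
#'   (row-bound M/A tibble with a `sample` column).
#' @export
prepare_expression <- function(probes, mock) {
  samples <- expression_samples(probes)
  if (!mock %in% samples) stop("mock sample not in matrix: ", mock, call. = FALSE)
  ge <- probes |> filter_detected() |> quantile_normalize() |> aggregate_probes()
  ma <- dplyr::bind_rows(lapply(setdiff(samples, mock), function(s) {
    dplyr::mutate(compute_ma(ge, s, mock), sample = s, .before = 1)
  }))
  list(gene_expr = ge, ma = ma)
}
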