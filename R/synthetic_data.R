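#' Simulation configuration for a synthetic transfection study
#'
#' Describes a synthetic version of the study design: a mock transfection
#' plus one sample per miRNA variant (A-, I-, G-type), 3'-UTR sets with
#' planted seed-complementary motifs, and probe-level single-channel
#' intensities with seed-group-dependent repression.
#'
#' Default effect sizes emulate the qualitative outcome of the transfection
#' experiments: the wild-type (A-type) miRNA represses U-target genes, the
#' G-type represses C-target genes, and the I-type represses C-target genes
#' more weakly than the G-type (inosine pairing cytidine, but less stably
#' than guanosine); all other variant x group combinations are null.
#'
#' @param n_per_group Genes planted per target group (A, C, G, U).
#' @param n_background Background genes (no motif occurrences at all).
#' @param n_dead Genes carrying the dead-seed motif.
#' @param n_multi Genes carrying motifs of two different groups.
#' @param utr_length Length-2 integer range of UTR lengths (nt).
#' @param base_composition Named sampling probabilities for `A`,`C`,`G`,`U`.
#' @param effects Tibble with `variant` (`A`,`I`,`G`), `group`
#'   (`A`,`C`,`G`,`U`) and `delta` (log2 repression, >= 0); combinations not
#'   listed are null.
#' @param noise_sd Per-probe log2 noise sd in the miRNA samples.
#' @param baseline_mean_log2,baseline_sd_log2 Log2-normal parameters of the
#'   mock probe intensities.
#' @param detection_dropout Probability a probe is flagged undetected in a
#'   sample.
#' @param probes_per_gene Integer vector sampled uniformly for the number of
#'   probes per gene.
#' @param seed Integer seed from which all randomness flows.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 200, n_background = 5000,
                       n_dead = 50, n_multi = 50,
                       utr_length = c(100L, 300L),
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       effects = tibble::tribble(
                         ~variant, ~group, ~delta,
                         "A", "U", 0.5,
                         "G", "C", 0.5,
                         "I", "C", 0.3
                       ),
                       noise_sd = 0.5,
                       baseline_mean_log2 = 8, baseline_sd_log2 = 2,
                       detection_dropout = 0.05,
                       probes_per_gene = 1:3,
                       seed = 20260101L) {
  stopifnot(length(utr_length) == 2, utr_length[1] >= 7,
            utr_length[1] <= utr_length[2],
            all(effects$delta >= 0), all(is.finite(effects$delta)),
            detection_dropout >= 0, detection_dropout <= 1,
            abs(sum(base_composition) - 1) < 1e-8)
  structure(
    list(n_per_group = n_per_group, n_background = n_background,
         n_dead = n_dead, n_multi = n_multi, utr_length = as.integer(utr_length),
         base_composition = base_composition, effects = effects,
         noise_sd = noise_sd, baseline_mean_log2 = baseline_mean_log2,
         baseline_sd_log2 = baseline_sd_log2,
         detection_dropout = detection_dropout,
         probes_per_gene = probes_per_gene, seed = as.integer(seed)),
    class = "sim_config"
  )
}

random_utr <- function(len, comp) {
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

#' Simulate 3'-UTR sets with planted seed-match motifs
#'
#' Generates random-composition UTRs and plants the configured numbers of
#' group-specific motifs, multi-group genes and dead-seed genes. Background
#' genes are rejection-sampled to contain none of the five motifs, and every
#' planted gene is re-checked to match exactly its intended motif set
#' (planting near a junction can create chance occurrences; such draws are
#' retried), so group membership in the emitted truth table is exact by
#' construction.
#'
#' @param config A [sim_config()].
#' @param motifs Tibble with `group`, `motif` (from [variant_motifs()]).
#' @param dead Dead-seed 7-mer.
#' @param seed Integer seed (default `config$seed`).
#' @return List with `utrs` (UTR tibble) and `truth` (tibble: `gene_id`,
#'   `group` in `{A,C,G,U,dead,multi,background}`, `planted_positions`
#'   list-column).
#' @export
simulate_utrs <- function(config, motifs, dead, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  mot <- stats::setNames(as_rna(motifs$motif), motifs$group)
  dead <- as_rna(dead)
  all5 <- c(mot, dead = dead)
  if (config$utr_length[1] < 7) stop("UTRs shorter than the motif", call. = FALSE)
  set.seed(seed)

  gen_seqs <- function(k) {
    span <- config$utr_length[2] - config$utr_length[1] + 1L
    lens <- sample.int(span, k, replace = TRUE) + config$utr_length[1] - 1L
    vapply(lens, random_utr, character(1), comp = config$base_composition)
  }
  count_matrix <- function(seqs) {
    set <- Biostrings::RNAStringSet(seqs)
    vapply(all5, function(m) Biostrings::vcountPattern(m, set),
           integer(length(seqs)))
  }
  # batched rejection sampling: draw, plant, re-check the full motif
  # constraint, retry offenders
  draw_genes <- function(k, want) {
    seqs <- character(k)
    poss <- rep(list(integer(0)), k)
    todo <- seq_len(k)
    while (length(todo)) {
      cand <- gen_seqs(length(todo))
      pos <- matrix(0L, length(todo), length(want))
      for (j in seq_along(want)) {
        p <- vapply(nchar(cand) - 6L, sample.int, integer(1), size = 1)
        substr(cand, p, p + 6L) <- rep(all5[[want[j]]], length(cand))
        pos[, j] <- p
      }
      counts <- matrix(count_matrix(cand), ncol = length(all5))
      forbid <- !(names(all5) %in% want)
      ok <- rowSums(counts[, forbid, drop = FALSE] > 0) == 0
      if (length(want)) {
        ok <- ok & rowSums(counts[, !forbid, drop = FALSE] >= 1) == length(want)
      }
      hit <- todo[ok]
      seqs[hit] <- cand[ok]
      poss[hit] <- lapply(which(ok), function(i) pos[i, ])
      todo <- todo[!ok]
    }
    list(sequences = seqs, positions = poss)
  }

  blocks <- list(
    list(group = "A", want = "A", n = config$n_per_group),
    list(group = "C", want = "C", n = config$n_per_group),
    list(group = "G", want = "G", n = config$n_per_group),
    list(group = "U", want = "U", n = config$n_per_group),
    list(group = "dead", want = "dead", n = config$n_dead),
    list(group = "multi", want = c("U", "C"), n = config$n_multi),
    list(group = "background", want = character(0), n = config$n_background)
  )
  drawn <- lapply(blocks, function(b) draw_genes(b$n, b$want))
  group <- unlist(lapply(blocks, function(b) rep(b$group, b$n)))
  truth <- tibble::tibble(
    gene_id = sprintf("gene%05d", seq_along(group)),
    group = group,
    planted_positions = unlist(lapply(drawn, `[[`, "positions"),
                               recursive = FALSE)
  )
  utrs <- tibble::tibble(
    gene_id = truth$gene_id,
    sequence = unlist(lapply(drawn, `[[`, "sequences"))
  )
  list(utrs = utrs, truth = truth)
}

#' Simulate a probe-level expression matrix from planted truth
#'
#' Emits the four-sample (mock, A, I, G) probe matrix: mock intensities are
#' log2-normal per probe; each miRNA sample multiplies the mock probe
#' intensity by `2^(-delta + noise)`, where `delta` is the configured
#' repression for that (variant, gene-group) combination (zero off-target)
#' and `noise` is Gaussian on the log2 scale. Detection flags drop out
#' independently per probe and sample.
#'
#' @param truth Truth tibble from [simulate_utrs()] (columns `gene_id`,
#'   `group`), or any tibble with those columns.
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed + 1`).
#' @return Probe-level tibble in the [expression_samples()] schema with
#'   samples `mock`, `A`, `I`, `G`.
#' @export
simulate_expression <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_probes <- sample(config$probes_per_gene, nrow(truth), replace = TRUE)
  gene_id <- rep(truth$gene_id, n_probes)
  group <- rep(truth$group, n_probes)
  np <- length(gene_id)
  mock <- 2^stats::rnorm(np, config$baseline_mean_log2, config$baseline_sd_log2)

  delta_for <- function(variant) {
    eff <- config$effects[config$effects$variant == variant, , drop = FALSE]
    d <- stats::setNames(rep(0, length(unique(group))), unique(group))
    d[eff$group[eff$group %in% names(d)]] <-
      eff$delta[eff$group %in% names(d)]
    unname(d[group])
  }

  out <- tibble::tibble(
    probe_id = sprintf("%s_p%d", gene_id, unlist(lapply(n_probes, seq_len))),
    gene_id = gene_id,
    mock.intensity = mock,
    mock.detected = stats::runif(np) >= config$detection_dropout
  )
  for (v in c("A", "I", "G")) {
    noise <- stats::rnorm(np, 0, config$noise_sd)
    out[[paste0(v, ".intensity")]] <- mock * 2^(-delta_for(v) + noise)
    out[[paste0(v, ".detected")]] <- stats::runif(np) >= config$detection_dropout
  }
  out
}

#' Simulate a two-state UV melting curve
#'
#' Two-state absorbance model on a temperature grid:
#' `A(T) = lower(T) + (upper(T) - lower(T)) * logistic((T - tm)/width)` plus
#' Gaussian noise, with linear baselines of common slope. Mimics the
#' hyperchromic transition monitored at 260 nm from 4 to 95 degrees C.
#'
#' @param tm True melting temperature (degrees C), inside the grid.
#' @param width Transition width (degrees C, > 0).
#' @param lower,upper Baseline absorbances at 0 degrees C.
#' @param baseline_slope Common linear slope of both baselines (A260 per
#'   degree C).
#' @param noise_sd Gaussian absorbance noise sd.
#' @param temperatures Temperature grid (default 4-95 in 0.5 steps).
#' @param seed Optional integer seed.
#' @return Melting-curve tibble (`temperature`, `absorbance`).
#' @export
simulate_melting_curve <- function(tm, width = 3, lower = 0.60, upper = 0.75,
                                   baseline_slope = 0, noise_sd = 0,
                                   temperatures = seq(4, 95, by = 0.5),
                                   seed = NULL) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (tm < min(temperatures) || tm > max(temperatures)) {
    stop("tm lies outside the temperature grid", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  frac <- stats::plogis((temperatures - tm) / width)
  lo <- lower + baseline_slope * temperatures
  hi <- upper + baseline_slope * temperatures
  ab <- lo + (hi - lo) * frac +
    if (noise_sd > 0) stats::rnorm(length(temperatures), 0, noise_sd) else 0
  tibble::tibble(temperature = temperatures, absorbance = ab)
}

#' Simulate a full synthetic study bundle
#'
#' Convenience wrapper producing UTRs, truth and the probe matrix for a
#' duplex's motif set in one call.
#'
#' @param config A [sim_config()].
#' @param duplex A [mirna_duplex()] (default [mir376a2_duplex()]).
#' @return List with `utrs`, `truth`, `probes`, `motifs`, `dead`.
#' @export
simulate_study <- function(config = sim_config(), duplex = mir376a2_duplex()) {
  st <- duplex_seed_table(duplex)
  sim <- simulate_utrs(config, st$motifs, st$dead)
  probes <- simulate_expression(sim$truth, config)
  list(utrs = sim$utrs, truth = sim$truth, probes = probes,
       motifs = st$motifs, dead = st$dead)
}
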