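#' Watson-Crick RNA nearest-neighbor parameters (1 M NaCl)
#'
#' The standard published RNA nearest-neighbor enthalpy/entropy set for
#' Watson-Crick dinucleotide stacks in 1 M NaCl, expanded to all 16 stack
#' keys, plus duplex initiation and the per-terminal-AU penalty. A stack key
#' is written `"XY/ZW"`: top strand dinucleotide 5'->3' over the aligned
#' bottom strand dinucleotide written 3'->5'. Parameters for stacks
#' involving inosine or G:U wobbles are not part of the published set;
#' supply extra rows to extend the model, otherwise [predict_tm_nn()]
#' reports such duplexes as unavailable.
#'
#' @return Tibble with `stack`, `dH_kcal` (kcal/mol), `dS_cal` (cal/(mol K)).
#'   The rows `init` and `termAU` hold the initiation and terminal-AU terms.
#' @export
nn_parameters <- function() {
  base <- c(
    AA = 1, UU = 1, AU = 2, UA = 3, CU = 4, AG = 4, CA = 5, UG = 5,
    GU = 6, AC = 6, GA = 7, UC = 7, CG = 8, GG = 9, CC = 9, GC = 10
  )
  dh <- c(-6.82, -9.38, -7.69, -10.48, -10.44, -11.40, -12.44, -10.64,
          -13.39, -14.88)
  ds <- c(-19.0, -26.7, -20.5, -27.1, -26.9, -29.5, -32.5, -26.7,
          -32.7, -36.9)
  tops <- names(base)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  bottoms <- vapply(strsplit(tops, ""), function(x)
    paste(wc[x], collapse = ""), character(1))
  tibble::tibble(
    stack = c(paste0(tops, "/", bottoms), "init", "termAU"),
    dH_kcal = c(dh[base], 3.61, 3.72),
    dS_cal = c(ds[base], -1.5, 10.5)
  )
}

#' Melting temperature from aggregate duplex energies
#'
#' Two-state melting temperature of a non-self-complementary duplex:
#' `Tm(K) = dH * 1000 / (dS + R * ln(Ct / 4))` with
#' `R = 1.987 cal/(mol K)`, converted to degrees Celsius.
#'
#' @param dH_kcal Aggregate enthalpy (kcal/mol, negative for favorable).
#' @param dS_cal Aggregate entropy (cal/(mol K)).
#' @param conc Total strand concentration in mol/L (default 5 uM, the
#'   concentration used for UV melting in 1 M NaCl).
#' @return Tm in degrees Celsius.
#' @examples
#' tm_from_energies(-50, -140) # 26.2
#' @export
tm_from_energies <- function(dH_kcal, dS_cal, conc = 5e-6) {
  if (conc <= 0) stop("strand concentration must be positive", call. = FALSE)
  R <- 1.987
  denom <- dS_cal + R * log(conc / 4)
  if (denom >= 0) {
    stop("non-physical duplex: dS + R*ln(Ct/4) must be negative", call. = FALSE)
  }
  dH_kcal * 1000 / denom - 273.15
}

wc_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG")
}

#' Nearest-neighbor Tm prediction for a short fully paired duplex
#'
#' Sums stack enthalpies/entropies over the antiparallel alignment of two
#' equal-length strands (position `i` of `strand_a` pairs position
#' `L - i + 1` of `strand_b`), adds initiation and terminal-AU terms, and
#' converts to Tm with [tm_from_energies()]. When any stack of the duplex is
#' absent from `params` — e.g. stacks involving inosine, whose pairing
#' thermodynamics are not published — the prediction is unavailable and
#' `NA_real_` is returned (not an error).
#'
#' @param strand_a,strand_b RNA strings 5'->3', equal length >= 2.
#' @param conc Total strand concentration (mol/L).
#' @param params Parameter tibble as [nn_parameters()], user-extendable.
#' @return Tm in degrees Celsius, or `NA_real_` when parameters are missing.
#' @examples
#' predict_tm_nn("UCAUAGA", "UCUAUGA") # Watson-Crick seed/target duplex
#' predict_tm_nn("UCAUIGA", "UCCAUGA") # NA: no inosine parameters
#' @export
predict_tm_nn <- function(strand_a, strand_b, conc = 5e-6,
                          params = nn_parameters()) {
  a <- strsplit(as_rna(strand_a), "")[[1]]
  b <- strsplit(as_rna(strand_b), "")[[1]]
  if (length(a) != length(b)) {
    stop("strands must have equal length for a fully paired duplex", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) stop("duplex too short", call. = FALSE)
  b_aligned <- rev(b) # b_aligned[i] pairs a[i]; written 3'->5' under a
  keys <- paste0(a[-n], a[-1], "/", b_aligned[-n], b_aligned[-1])
  idx <- match(keys, params$stack)
  if (anyNA(idx)) return(NA_real_)
  dH <- sum(params$dH_kcal[idx])
  dS <- sum(params$dS_cal[idx])
  init <- match("init", params$stack)
  if (!is.na(init)) {
    dH <- dH + params$dH_kcal[init]
    dS <- dS + params$dS_cal[init]
  }
  term <- match("termAU", params$stack)
  if (!is.na(term)) {
    n_au <- sum(paste0(a[c(1, n)], b_aligned[c(1, n)]) %in% c("AU", "UA"))
    dH <- dH + n_au * params$dH_kcal[term]
    dS <- dS + n_au * params$dS_cal[term]
  }
  tm_from_energies(dH, dS, conc)
}

#' Measured seed-duplex melting temperatures (miR-376a-3p context)
#'
#' Calibration table of UV-measured Tm values for the 7-bp duplexes formed
#' between the miR-376a-3p seed variants (A/I/G at the editing site) and the
#' U-/C-target 7-mers, at 5 uM strand concentration in 1 M NaCl. The A:C
#' duplex could not be melted and is stored as not determined (`NA`).
#' The stored values reproduce the stability ranking
#' G:C > A:U > I:C > G:U > I:U.
#'
#' @return Tibble with `seed`, `target` (both 5'->3' 7-mers), `pair` (the
#'   base pair formed at the editing position) and `tm_C` (`NA` = not
#'   determined).
#' @export
calibration_table <- function() {
  tibble::tibble(
    seed   = c("UCAUAGA", "UCAUGGA", "UCAUIGA", "UCAUGGA", "UCAUIGA", "UCAUAGA"),
    target = c("UCUAUGA", "UCCAUGA", "UCCAUGA", "UCUAUGA", "UCUAUGA", "UCCAUGA"),
    pair   = c("A:U", "G:C", "I:C", "G:U", "I:U", "A:C"),
    tm_C   = c(26.6, 39.0, 23.3, 19.3, 9.3, NA_real_)
  )
}

#' Look up a measured seed-duplex Tm
#'
#' Exact-key lookup in a calibration table. A present key whose Tm could not
#' be measured returns `NA_real_` ("not determined" is a value, not an
#' error); an absent key raises a `inoseed_missing_entry` error.
#'
#' @param table Calibration tibble ([calibration_table()]).
#' @param seed,target 7-mer key pair.
#' @return Tm in degrees Celsius, or `NA_real_` for a not-determined entry.
#' @examples
#' lookup_tm(calibration_table(), "UCAUIGA", "UCCAUGA") # 23.3
#' @export
lookup_tm <- function(table, seed, target) {
  seed <- as_rna(seed); target <- as_rna(target)
  if (nchar(seed) != 7 || nchar(target) != 7) {
    stop("seed and target must be 7-mers", call. = FALSE)
  }
  i <- which(table$seed == seed & table$target == target)
  if (length(i) == 0) {
    stop(structure(
      class = c("inoseed_missing_entry", "error", "condition"),
      list(message = paste0("no calibration entry for (", seed, ", ", target, ")"),
           call = NULL)))
  }
  table$tm_C[i[1]]
}

#' Validate a melting curve table
#'
#' @param curve Data frame with numeric `temperature` (degrees C, strictly
#'   increasing) and `absorbance` (A260) columns.
#' @return The curve as a tibble (invisibly validated).
#' @export
as_melting_curve <- function(curve) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("temperature", "absorbance") %in% names(curve))) {
    stop("melting curve needs `temperature` and `absorbance` columns", call. = FALSE)
  }
  if (nrow(curve) < 10) stop("melting curve needs >= 10 points", call. = FALSE)
  if (any(diff(curve$temperature) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  curve
}

#' Tm from a UV melting curve by the Two Point Average method
#'
#' Reads the melting temperature off a two-state absorbance curve: the lower
#' baseline is the mean absorbance over the first `baseline_fraction` of
#' points, the upper baseline the mean over the last, and Tm is the
#' temperature at which the (optionally smoothed) curve first crosses the
#' midpoint of the two baselines, located by linear interpolation between
#' the bracketing samples. Invariant to constant offsets and to affine
#' rescaling of the absorbance axis.
#'
#' @param curve Melting curve ([as_melting_curve()]).
#' @param baseline_fraction Fraction of points averaged into each baseline,
#'   in `(0, 0.4]` (default 0.15).
#' @param smooth Odd window width for a running-mean smooth of the
#'   absorbance before the crossing search; `0` (default) disables it.
#' @return Tm in degrees Celsius.
#' @export
tm_two_point_average <- function(curve, baseline_fraction = 0.15, smooth = 0) {
  curve <- as_melting_curve(curve)
  if (baseline_fraction <= 0 || baseline_fraction > 0.4) {
    stop("baseline_fraction must lie in (0, 0.4]", call. = FALSE)
  }
  tt <- curve$temperature
  aa <- curve$absorbance
  n <- length(aa)
  k <- max(1L, floor(baseline_fraction * n))
  lower <- mean(aa[seq_len(k)])
  upper <- mean(aa[seq.int(n - k + 1L, n)])
  mid <- (lower + upper) / 2
  if (smooth > 1) {
    aa <- as.numeric(stats::filter(aa, rep(1 / smooth, smooth), sides = 2))
    keep <- !is.na(aa)
    tt <- tt[keep]; aa <- aa[keep]
  }
  d <- aa - mid
  cross <- which(d[-length(d)] * d[-1] <= 0 & (d[-length(d)] != 0 | d[-1] != 0))
  if (length(cross) == 0) {
    if (any(d == 0)) return(tt[which(d == 0)[1]])
    stop("curve never crosses the baseline midpoint within the scanned range",
         call. = FALSE)
  }
  i <- cross[1]
  if (d[i] == 0) return(tt[i])
  tt[i] + (tt[i + 1] - tt[i]) * (0 - d[i]) / (d[i + 1] - d[i])
}

#' miScore: thermodynamic predictor of miRNA silencing efficiency
#'
#' `miScore = Tm_2-8 - 0.5 * miTm_1-5`, where `Tm_2-8` is the melting
#' temperature of the 7-bp seed-target duplex (strong pairing favors
#' silencing) and `miTm_1-5` that of the 5-bp 5'-terminal duplex of the
#' miRNA (weak pairing favors loading of the strand into the RISC). The 0.5
#' coefficient halves the 5'-terminal contribution relative to the seed.
#'
#' @param tm_2_8 Seed-target duplex Tm (degrees C).
#' @param mitm_1_5 5'-terminal 5-bp duplex Tm (degrees C).
#' @return The score (same units as Tm).
#' @examples
#' miscore(26.6, 10) # 21.6
#' @export
miscore <- function(tm_2_8, mitm_1_5) {
  if (any(!is.finite(c(tm_2_8, mitm_1_5)))) {
    stop("miScore requires finite Tm values", call. = FALSE)
  }
  tm_2_8 - 0.5 * mitm_1_5
}

#' Seed-target duplex Tm with provenance
#'
#' Resolves the Tm of a 7-bp seed-target duplex from the measured
#' calibration table (primary path) or nearest-neighbor prediction. Lookup
#' mode falls back to prediction only when `fallback_nn = TRUE` and the key
#' is absent; the provenance of the returned value is always recorded.
#'
#' @param seed,target 7-mer pair (seed 5'->3', target mRNA-side 5'->3').
#' @param method `"lookup"` (default) or `"nn"`.
#' @param table Calibration table for lookup mode.
#' @param params NN parameters for prediction mode.
#' @param conc Total strand concentration (mol/L).
#' @param fallback_nn In lookup mode, predict when the key is absent?
#' @return List with `tm` (`NA_real_` when unavailable or not determined)
#'   and `provenance` (`"measured"`, `"not_determined"`, `"predicted"`, or
#'   `"unavailable"`).
#' @export
seed_duplex_tm <- function(seed, target, method = c("lookup", "nn"),
                           table = calibration_table(),
                           params = nn_parameters(), conc = 5e-6,
                           fallback_nn = FALSE) {
  method <- match.arg(method)
  if (method == "lookup") {
    tm <- tryCatch(lookup_tm(table, seed, target),
                   inoseed_missing_entry = function(e) "absent")
    if (!identical(tm, "absent")) {
      if (is.na(tm)) return(list(tm = NA_real_, provenance = "not_determined"))
      return(list(tm = tm, provenance = "measured"))
    }
    if (!fallback_nn) return(list(tm = NA_real_, provenance = "unavailable"))
  }
  tm <- predict_tm_nn(seed, target, conc = conc, params = params)
  if (is.na(tm)) return(list(tm = NA_real_, provenance = "unavailable"))
  list(tm = tm, provenance = "predicted")
}

#' Packaged miR-376a-2 Tm / silencing reference values
#'
#' The five measured seed-duplex melting temperatures paired with the
#' microarray fold-change area statistics and rank-sum p-values of the
#' corresponding transfections (miRNA variant x target group), plus the
#' not-determined A:C row. These are the published summary numbers; they let
#' the Tm-silencing correlation be recomputed without the raw arrays.
#'
#' @return Tibble with `mirna_variant`, `target_group`, `pair`, `seed`,
#'   `target`, `tm_C`, `fold_change`, `p_value`.
#' @export
mir376a2_reference <- function() {
  tibble::tibble(
    mirna_variant = c("A", "G", "I", "G", "I", "A"),
    target_group  = c("U", "C", "C", "U", "U", "C"),
    pair          = c("A:U", "G:C", "I:C", "G:U", "I:U", "A:C"),
    seed          = c("UCAUAGA", "UCAUGGA", "UCAUIGA", "UCAUGGA", "UCAUIGA", "UCAUAGA"),
    target        = c("UCUAUGA", "UCCAUGA", "UCCAUGA", "UCUAUGA", "UCUAUGA", "UCCAUGA"),
    tm_C          = c(26.6, 39.0, 23.3, 19.3, 9.3, NA_real_),
    fold_change   = c(0.042, 0.096, 0.024, -0.023, 0.010, -0.002),
    p_value       = c(2.14e-9, 3.51e-16, 1.83e-3, 3.82e-2, 1.01e-1, 3.9e-1)
  )
}

#' Correlate seed-duplex Tm with a silencing readout
#'
#' Pearson correlation between measured Tm values and a silencing readout
#' (microarray fold-change by default, or any user-supplied column such as
#' relative reporter activity). Rows without a measured Tm are dropped.
#'
#' @param data Tibble with a `tm_C` column (default [mir376a2_reference()]).
#' @param readout Name of the readout column (default `"fold_change"`).
#' @return List with `r`, `n` (pairs used) and the paired data.
#' @examples
#' correlate_tm_silencing()$r # 0.82 for the packaged reference values
#' @export
correlate_tm_silencing <- function(data = mir376a2_reference(),
                                   readout = "fold_change") {
  if (!readout %in% names(data)) stop("no column `", readout, "`", call. = FALSE)
  keep <- is.finite(data$tm_C) & is.finite(data[[readout]])
  d <- data[keep, , drop = FALSE]
  list(r = pearson_r(d$tm_C, d[[readout]]), n = nrow(d),
       data = tibble::as_tibble(d))
}
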