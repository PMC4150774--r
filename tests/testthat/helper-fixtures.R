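# shared in-code fixtures for the test suite

# motifs for the wild-type miR-376a-3p seed (edit at seed index 5)
fix_motifs <- function() variant_motifs("UCAUAGA", seed_edit_index = 5)

fix_dead <- function() "AAAUCCA" # dead motif of the packaged example duplex

# flank a motif so no other of the five 7-mers can appear by accident
flanked <- function(...) paste0("GG", paste0(..., collapse = "GG"), "GG")

# minimal probe table builder: intensities is a named list of per-sample
# vectors; detection defaults to all-TRUE
toy_probes <- function(intensities, gene_id = NULL, detected = NULL) {
  np <- length(intensities[[1]])
  out <- tibble::tibble(
    probe_id = sprintf("p%d", seq_len(np)),
    gene_id = gene_id %||% sprintf("g%d", seq_len(np))
  )
  for (s in names(intensities)) {
    out[[paste0(s, ".intensity")]] <- intensities[[s]]
    out[[paste0(s, ".detected")]] <- detected[[s]] %||% rep(TRUE, np)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force oracle for reverse complementation (no I)
oracle_revcomp <- function(s) {
  map <- c(A = "U", C = "G", G = "C", U = "A", I = "C")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# independent sliding-window motif scan oracle
oracle_scan <- function(motif, utr) {
  k <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(nchar(utr) - k + 1)) {
    if (substr(utr, i, i + k - 1) == motif) hits <- c(hits, i)
  }
  hits
}

# independent exact rank-sum enumeration via bitmask subsets (distinct
# algorithm from the package's combn-based path)
oracle_rank_sum <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  total <- 2^(n + m)
  w_all <- numeric(0)
  for (mask in 0:(total - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n + m)]
    if (sum(bits) == n) w_all <- c(w_all, sum(r[bits == 1]))
  }
  p_less <- mean(w_all <= w_obs)
  p_greater <- mean(w_all >= w_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}
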