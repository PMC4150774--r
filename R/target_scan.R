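#' Tabulate 3'-UTR sequences
#'
#' Canonical tabular form for a UTR set: one row per gene, RNA-space
#' sequence. Accepts a tibble/data.frame with `gene_id` and `sequence`
#' columns or a named character vector.
#'
#' @param x Data frame with columns `gene_id`, `sequence`, or a named
#'   character vector of sequences.
#' @return A tibble with `gene_id` and uppercase RNA `sequence`.
#' @export
as_utr_table <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("UTR vector must be named by gene_id", call. = FALSE)
    x <- tibble::tibble(gene_id = names(x), sequence = unname(x))
  }
  x <- tibble::as_tibble(x)
  if (!all(c("gene_id", "sequence") %in% names(x))) {
    stop("UTR table needs `gene_id` and `sequence` columns", call. = FALSE)
  }
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate gene_id in UTR set: ",
         x$gene_id[duplicated(x$gene_id)][1], call. = FALSE)
  }
  if (any(!nzchar(x$sequence))) stop("empty UTR sequence", call. = FALSE)
  x$sequence <- as_rna(x$sequence, allow_inosine = FALSE)
  x
}

#' Find all occurrences of a 7-mer motif in a UTR
#'
#' Exact, case-insensitive, forward-strand matching (UTRs are mRNA-sense);
#' overlapping occurrences are counted.
#'
#' @param motif 7-mer RNA motif (mRNA side; may not contain `I` or `N`).
#' @param utr UTR sequence string (DNA or RNA).
#' @return Integer vector of 1-based start positions (length 0 when absent).
#' @examples
#' scan_utr("UCCAUGA", "AAUCCAUGAAA") # 3
#' @export
scan_utr <- function(motif, utr) {
  motif <- as_rna(motif, allow_inosine = FALSE)
  if (nchar(motif) != 7) stop("motif must be a 7-mer", call. = FALSE)
  utr <- as_rna(utr, allow_inosine = FALSE)
  m <- Biostrings::matchPattern(motif, Biostrings::RNAString(utr))
  as.integer(Biostrings::start(m))
}

#' Count motif occurrences across a UTR set
#'
#' Vectorized overlapping-match counting of several motifs over many UTRs.
#'
#' @param utrs A UTR table ([as_utr_table()]).
#' @param motifs Character vector of 7-mer motifs, optionally named.
#' @return A tibble `gene_id` x one integer count column per motif.
#' @export
count_motif_hits <- function(utrs, motifs) {
  utrs <- as_utr_table(utrs)
  motifs <- as_rna(motifs, allow_inosine = FALSE)
  if (is.null(names(motifs))) names(motifs) <- motifs
  set <- Biostrings::RNAStringSet(utrs$sequence)
  counts <- lapply(motifs, function(m) Biostrings::vcountPattern(m, set))
  dplyr::bind_cols(tibble::tibble(gene_id = utrs$gene_id),
                   tibble::as_tibble(counts))
}

#' Restrict a UTR set to an allowed identifier list
#'
#' Mirrors the restriction of the analysis universe to genes present in the
#' expression data (and reference annotation): set intersection on
#' `gene_id`, order-stable with respect to the input.
#'
#' @param utrs UTR table.
#' @param allowed_ids Character vector of permitted gene ids.
#' @return Filtered UTR tibble.
#' @export
restrict_ids <- function(utrs, allowed_ids) {
  utrs <- as_utr_table(utrs)
  utrs[utrs$gene_id %in% allowed_ids, , drop = FALSE]
}

#' Assign genes to the four seed-match target groups
#'
#' Implements the grouping procedure, in order: (i) discard genes whose UTR
#' contains the dead-seed motif; (ii) group the remaining genes by which of
#' the four variant motifs they match at least once; (iii) discard genes
#' matching motifs of more than one group; (iv) define each group's
#' background as the universe minus dead-seed matches minus that group's
#' members. The four motifs must differ only at the edit-opposite position,
#' so each UTR occurrence belongs to exactly one motif; backgrounds therefore
#' differ slightly between groups (a group's own discarded multi-matches
#' remain excluded from every group but sit in every background).
#'
#' @param utrs UTR table (the universe: genes surviving expression filtering
#'   and id restriction).
#' @param motifs Tibble with columns `group` and `motif` (from
#'   [variant_motifs()]), or a named character vector `c(A=,C=,G=,U=)`.
#' @param dead Dead-seed 7-mer motif.
#' @return A `target_groups` object: a tibble with `gene_id`, `assignment`
#'   (one of `A`,`C`,`G`,`U`,`dead`,`multi`,`none`) and per-motif hit-count
#'   columns `hits_A` ... `hits_dead`, plus attributes `motifs` and `dead`.
#'   Use [group_members()] and [group_background()] to pull gene sets.
#' @examples
#' utrs <- tibble::tibble(
#'   gene_id = c("g1", "g2"),
#'   sequence = c("AAUCUAUGAAA", "GGUCCAUGAGG")
#' )
#' tg <- assign_target_groups(utrs, variant_motifs("UCAUAGA", 5), "GGGGGGG")
#' group_members(tg, "U")
#' @export
assign_target_groups <- function(utrs, motifs, dead) {
  utrs <- as_utr_table(utrs)
  if (is.data.frame(motifs)) {
    mot <- stats::setNames(motifs$motif, motifs$group)
  } else {
    mot <- motifs
  }
  if (!setequal(names(mot), c("A", "C", "G", "U"))) {
    stop("motifs must be named A, C, G, U", call. = FALSE)
  }
  mot <- mot[c("A", "C", "G", "U")]
  dead <- as_rna(dead, allow_inosine = FALSE)
  diffs <- lapply(strsplit(unname(mot), ""), function(x) x)
  pos_diff <- which(apply(do.call(rbind, diffs), 2, function(col) length(unique(col)) > 1))
  if (!identical(length(pos_diff), 1L)) {
    stop("the four variant motifs must differ at exactly one position", call. = FALSE)
  }

  hits <- count_motif_hits(utrs, c(mot, dead = dead))
  names(hits) <- c("gene_id", paste0("hits_", c(names(mot), "dead")))

  grp_cols <- paste0("hits_", c("A", "C", "G", "U"))
  n_groups <- rowSums(hits[grp_cols] > 0)
  assignment <- rep("none", nrow(hits))
  single <- which(hits$hits_dead == 0 & n_groups == 1)
  if (length(single)) {
    assignment[single] <- c("A", "C", "G", "U")[
      max.col(hits[single, grp_cols, drop = FALSE] > 0)]
  }
  assignment[hits$hits_dead == 0 & n_groups > 1] <- "multi"
  assignment[hits$hits_dead > 0] <- "dead"

  out <- dplyr::bind_cols(tibble::tibble(gene_id = hits$gene_id,
                                         assignment = assignment),
                          hits[-1])
  structure(out, class = c("target_groups", class(out)),
            motifs = mot, dead = dead)
}

#' @export
print.target_groups <- function(x, ...) {
  tab <- table(factor(x$assignment,
                      levels = c("A", "C", "G", "U", "dead", "multi", "none")))
  cat("<target_groups> ", nrow(x), " genes | ",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n", sep = "")
  NextMethod()
}

#' Members of one target group
#'
#' @param tg A `target_groups` object.
#' @param group One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return Character vector of gene ids.
#' @export
group_members <- function(tg, group = c("A", "C", "G", "U")) {
  group <- match.arg(group)
  tg$gene_id[tg$assignment == group]
}

#' Background gene set of one target group
#'
#' The background for group X is the universe minus dead-seed matches minus
#' the members of X itself; genes of other groups (and multi-group discards)
#' remain in X's background, which is why backgrounds differ slightly
#' between groups.
#'
#' @inheritParams group_members
#' @return Character vector of gene ids.
#' @export
group_background <- function(tg, group = c("A", "C", "G", "U")) {
  group <- match.arg(group)
  tg$gene_id[tg$assignment != "dead" & tg$assignment != group]
}

#' @describeIn group_members Genes discarded for matching multiple groups.
#' @export
group_discards <- function(tg) tg$gene_id[tg$assignment == "multi"]

#' @describeIn group_members Genes excluded for matching the dead seed.
#' @export
dead_set <- function(tg) tg$gene_id[tg$assignment == "dead"]
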