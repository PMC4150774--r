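#' Normalize a nucleotide sequence to RNA space
#'
#' Uppercases and converts `T` to `U`. The working alphabet is `A`, `C`, `G`,
#' `U` plus `I` (inosine) on the miRNA side; mRNA-side motifs never contain
#' `I`.
#'
#' @param seq Character vector of sequences (DNA or RNA, any case).
#' @param allow_inosine Should `I` be accepted? Defaults to `TRUE`.
#' @return Character vector of uppercase RNA sequences.
#' @examples
#' as_rna("tcatAGA")
#' @export
as_rna <- function(seq, allow_inosine = TRUE) {
  stopifnot(is.character(seq))
  out <- chartr("T", "U", toupper(seq))
  alphabet <- if (allow_inosine) "ACGUI" else "ACGU"
  bad <- grepl(sprintf("[^%s]", alphabet), out)
  if (any(bad)) {
    stop("sequence contains characters outside {", paste(strsplit(alphabet, "")[[1]], collapse = ","),
         "}: ", out[bad][1], call. = FALSE)
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' Complement map: A<->U, G<->C, and I -> C, because inosine preferentially
#' base-pairs with cytidine. Since the I -> C mapping is not invertible, the
#' usual involution `revcomp(revcomp(x)) == x` holds only for inosine-free
#' input.
#'
#' @param seq Character vector of RNA sequences over `{A,C,G,U,I}`.
#' @return Character vector of reverse-complemented sequences (never contains
#'   `I`).
#' @examples
#' rna_reverse_complement("UCAUGGA") # "UCCAUGA"
#' @export
rna_reverse_complement <- function(seq) {
  seq <- as_rna(seq)
  comp <- chartr("ACGUI", "UGCAC", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), character(1))
}

#' Construct a miRNA strand
#'
#' A mature miRNA strand, 5'->3', with an optional 1-based A-to-I editing
#' site. Positions are always counted from the 5' end, matching the "+6"
#' convention used for editing sites.
#'
#' @param name Strand identifier, e.g. `"miR-376a-3p-A"`.
#' @param sequence RNA (or DNA) string, length 19-24.
#' @param edit_position Optional 1-based index of the editing site. On a
#'   wild-type strand this base is `A`; after [apply_edit()] it is `I` or `G`.
#' @return An object of class `mirna_strand`.
#' @examples
#' mirna_strand("miR-376a-3p-A", "AUCAUAGAGGAAAAUCCACGU", edit_position = 6)
#' @export
mirna_strand <- function(name, sequence, edit_position = NULL) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n < 19 || n > 24) {
    stop("mature miRNA strand must be 19-24 nt, got ", n, " nt", call. = FALSE)
  }
  if (!is.null(edit_position)) {
    edit_position <- as.integer(edit_position)
    if (edit_position < 1 || edit_position > n) {
      stop("edit_position ", edit_position, " outside sequence bounds [1, ", n, "]",
           call. = FALSE)
    }
    base <- substr(sequence, edit_position, edit_position)
    if (!base %in% c("A", "I", "G")) {
      stop("base at edit_position must be A (wild type) or a substituted I/G, got ",
           base, call. = FALSE)
    }
  }
  structure(
    list(name = name, sequence = sequence, edit_position = edit_position),
    class = "mirna_strand"
  )
}

#' @export
print.mirna_strand <- function(x, ...) {
  cat("<mirna_strand> ", x$name, "\n  5'-", x$sequence, "-3'", sep = "")
  if (!is.null(x$edit_position)) cat("  (edit site at +", x$edit_position, ")", sep = "")
  cat("\n")
  invisible(x)
}

as_mirna_strand <- function(x) {
  if (inherits(x, "mirna_strand")) return(x)
  stop("expected a `mirna_strand`; build one with mirna_strand()", call. = FALSE)
}

#' Construct a miRNA duplex
#'
#' Two annealed strands, both written 5'->3'. The `edited_strand` carries the
#' (possible) editing site; the opposite strand is the wild-type passenger.
#' Under the canonical duplex register (full antiparallel complementarity with
#' 2-nt 3' overhangs) the opposite strand carries `U` at the position pairing
#' the editing site, so A:U, I:U and G:U pairs form there for the A-, I- and
#' G-type duplexes respectively; a warning is raised when that check cannot be
#' confirmed (real duplexes may contain bulges that shift the register).
#'
#' @param edited_strand,opposite_strand [mirna_strand()] objects.
#' @param overhang Length of the 3' overhangs assumed when checking the pair
#'   formed at the editing site (default 2).
#' @return An object of class `mirna_duplex` with a `variant` field in
#'   `{A, I, G}` read off the edited strand.
#' @examples
#' mir376a2_duplex()
#' @export
mirna_duplex <- function(edited_strand, opposite_strand, overhang = 2L) {
  edited_strand <- as_mirna_strand(edited_strand)
  opposite_strand <- as_mirna_strand(opposite_strand)
  if (is.null(edited_strand$edit_position)) {
    stop("edited_strand must carry an edit_position", call. = FALSE)
  }
  ep <- edited_strand$edit_position
  variant <- substr(edited_strand$sequence, ep, ep)
  # guide position i pairs passenger position (L_opp - overhang) - i + 1
  j <- (nchar(opposite_strand$sequence) - overhang) - ep + 1L
  if (j >= 1 && j <= nchar(opposite_strand$sequence)) {
    opp_base <- substr(opposite_strand$sequence, j, j)
    if (opp_base != "U") {
      warning("opposite strand does not carry U at the position pairing the edit site (found ",
              opp_base, "); duplex register may differ", call. = FALSE)
    }
  } else {
    warning("cannot locate the base pairing the edit site on the opposite strand",
            call. = FALSE)
  }
  structure(
    list(edited_strand = edited_strand, opposite_strand = opposite_strand,
         variant = variant),
    class = "mirna_duplex"
  )
}

#' @export
print.mirna_duplex <- function(x, ...) {
  cat("<mirna_duplex> variant ", x$variant, "-type\n", sep = "")
  cat("  edited:   5'-", x$edited_strand$sequence, "-3'  (", x$edited_strand$name,
      ", edit +", x$edited_strand$edit_position, ")\n", sep = "")
  cat("  opposite: 5'-", x$opposite_strand$sequence, "-3'  (",
      x$opposite_strand$name, ")\n", sep = "")
  invisible(x)
}

#' Example miR-376a-2-like duplex
#'
#' A synthetic reconstruction of the wild-type (A-type) miR-376a-2 duplex:
#' the mature miR-376a-3p guide (miRBase), whose editing site sits at position
#' +6 inside the seed, paired with a perfectly complementary passenger strand
#' carrying 2-nt 3' overhangs. The passenger sequence is constructed, not a
#' database sequence; it serves as a reproducible example and test fixture.
#'
#' @return A `mirna_duplex`.
#' @export
mir376a2_duplex <- function() {
  guide <- "AUCAUAGAGGAAAAUCCACGU"
  passenger <- paste0(rna_reverse_complement(substr(guide, 1, 19)), "UU")
  mirna_duplex(
    mirna_strand("miR-376a-3p-A", guide, edit_position = 6),
    mirna_strand("miR-376a-2-5p(synthetic)", passenger)
  )
}

#' Extract the seed region (positions 2-8) of a miRNA strand
#'
#' The seed is the 7-mer at nucleotide positions 2-8 from the 5' end, the
#' primary determinant of target recognition. When the strand's editing site
#' falls inside the seed, its 1-based index within the 7-mer
#' (`edit_position - 1`) is returned alongside.
#'
#' @param strand A [mirna_strand()], or a plain sequence string (then
#'   `edit_position` may be given directly).
#' @param edit_position Optional 1-based edit site, used when `strand` is a
#'   plain string.
#' @return A list with `seed` (7-mer) and `seed_edit_index` (integer or `NA`
#'   when the edit lies outside positions 2-8 or is unset).
#' @examples
#' extract_seed("AUCAUAGAGGAAAAUCCACGU", edit_position = 6)
#' @export
extract_seed <- function(strand, edit_position = NULL) {
  if (inherits(strand, "mirna_strand")) {
    seq <- strand$sequence
    edit_position <- strand$edit_position
  } else {
    seq <- as_rna(strand)
  }
  if (nchar(seq) < 8) {
    stop("strand too short to contain a seed (need >= 8 nt, got ",
         nchar(seq), ")", call. = FALSE)
  }
  seed <- substr(seq, 2, 8)
  idx <- NA_integer_
  if (!is.null(edit_position) && edit_position >= 2 && edit_position <= 8) {
    idx <- as.integer(edit_position) - 1L
  }
  list(seed = seed, seed_edit_index = idx)
}

#' Apply an A-to-I or A-to-G edit at the editing site
#'
#' Replaces the base at the strand's editing site with the requested variant.
#' The wild-type input must carry `A` there; `variant = "A"` returns the
#' strand unchanged (identity edit). The strand name gains a `-I`/`-G` style
#' suffix for non-identity edits.
#'
#' @param strand A [mirna_strand()] with `edit_position` set, or a plain
#'   sequence string plus `edit_position`.
#' @param variant One of `"A"`, `"I"`, `"G"`.
#' @param edit_position 1-based edit site when `strand` is a plain string.
#' @return Same type as the input (`mirna_strand` or string).
#' @examples
#' apply_edit("UCAUAGA", "I", edit_position = 5) # seed-level edit
#' @export
apply_edit <- function(strand, variant = c("A", "I", "G"), edit_position = NULL) {
  variant <- match.arg(variant)
  is_obj <- inherits(strand, "mirna_strand")
  seq <- if (is_obj) strand$sequence else as_rna(strand)
  ep <- if (is_obj) strand$edit_position else edit_position
  if (is.null(ep)) {
    stop("edit_position is not set; cannot apply an edit", call. = FALSE)
  }
  base <- substr(seq, ep, ep)
  if (base != "A") {
    stop("wild-type strand must carry A at the edit site, found ", base, call. = FALSE)
  }
  substr(seq, ep, ep) <- variant
  if (!is_obj) return(seq)
  name <- strand$name
  if (variant != "A") {
    name <- sub("-A$", "", name)
    name <- paste0(name, "-", variant)
  }
  mirna_strand(name, seq, edit_position = ep)
}

#' Build one mRNA-side target motif for a seed variant
#'
#' The motif is the 7-mer a 3'-UTR must contain to be seed-complementary:
#' the reverse complement of the seed, except that the position opposite the
#' editing site (motif index `8 - seed_edit_index`) is set to `variant_nt`.
#' Enumerating `variant_nt` over `{A,C,G,U}` yields the four target motifs
#' that define the A-, C-, G- and U-target gene groups.
#'
#' @param seed A seed list as returned by [extract_seed()] (fields `seed`,
#'   `seed_edit_index`), or a 7-mer string with `seed_edit_index` supplied.
#' @param variant_nt Nucleotide placed at the edit-opposite motif position.
#' @param seed_edit_index 1-based index of the edit within the 7-mer, when
#'   `seed` is a plain string.
#' @return A list with `motif` (7-mer, mRNA sense), `variant_nt` and
#'   `group_label` (e.g. `"C-target"`).
#' @examples
#' make_variant_motif("UCAUAGA", "C", seed_edit_index = 5) # UCCAUGA
#' @export
make_variant_motif <- function(seed, variant_nt = c("A", "C", "G", "U"),
                               seed_edit_index = NULL) {
  variant_nt <- match.arg(variant_nt)
  if (is.list(seed)) {
    seed_edit_index <- seed$seed_edit_index
    seed <- seed$seed
  }
  seed <- as_rna(seed)
  if (nchar(seed) != 7) stop("seed must be a 7-mer", call. = FALSE)
  if (is.null(seed_edit_index) || is.na(seed_edit_index)) {
    stop("editing site lies outside seed positions 2-8; variant motifs are ",
         "defined only for seed edits", call. = FALSE)
  }
  motif <- rna_reverse_complement(seed)
  pos <- 8L - as.integer(seed_edit_index)
  substr(motif, pos, pos) <- variant_nt
  list(motif = motif, variant_nt = variant_nt,
       group_label = paste0(variant_nt, "-target"))
}

#' All four variant target motifs for a seed
#'
#' @param seed As in [make_variant_motif()].
#' @param seed_edit_index As in [make_variant_motif()].
#' @return A tibble with columns `group` (`A`,`C`,`G`,`U`), `group_label`,
#'   and `motif`.
#' @examples
#' variant_motifs("UCAUAGA", seed_edit_index = 5)
#' @export
variant_motifs <- function(seed, seed_edit_index = NULL) {
  nts <- c("A", "C", "G", "U")
  rows <- lapply(nts, function(nt) {
    m <- make_variant_motif(seed, nt, seed_edit_index = seed_edit_index)
    tibble::tibble(group = nt, group_label = m$group_label, motif = m$motif)
  })
  dplyr::bind_rows(rows)
}

#' Dead-seed motif of a duplex
#'
#' The "dead seed" is the seed (positions 2-8) of the strand opposite the
#' edited strand. Genes whose 3'-UTR is complementary to it may be silenced
#' by the passenger strand and are excluded from all target groups and
#' backgrounds. Returns the mRNA-side motif, i.e. the reverse complement of
#' the opposite strand's seed.
#'
#' @param duplex A [mirna_duplex()].
#' @return A 7-mer motif string.
#' @export
dead_seed_motif <- function(duplex) {
  stopifnot(inherits(duplex, "mirna_duplex"))
  seed <- extract_seed(duplex$opposite_strand)$seed
  rna_reverse_complement(seed)
}

#' Seed and target-motif table for all editing variants of a duplex
#'
#' For each requested miRNA variant (A/I/G at the editing site) derives the
#' variant seed; motifs are shared across variants since the four target
#' motifs enumerate the mRNA-side nucleotide independently of which miRNA
#' variant is transfected.
#'
#' @param duplex A [mirna_duplex()] whose edited strand is wild type (A).
#' @param variants miRNA variants to derive, subset of `c("A","I","G")`.
#' @return A list with `seeds` (tibble: variant, seed, seed_edit_index),
#'   `motifs` (tibble from [variant_motifs()]) and `dead` (7-mer).
#' @export
duplex_seed_table <- function(duplex, variants = c("A", "I", "G")) {
  stopifnot(inherits(duplex, "mirna_duplex"))
  variants <- match.arg(variants, c("A", "I", "G"), several.ok = TRUE)
  seeds <- dplyr::bind_rows(lapply(variants, function(v) {
    s <- extract_seed(apply_edit(duplex$edited_strand, v))
    tibble::tibble(variant = v, seed = s$seed, seed_edit_index = s$seed_edit_index)
  }))
  wt <- extract_seed(duplex$edited_strand)
  list(
    seeds = seeds,
    motifs = variant_motifs(wt$seed, wt$seed_edit_index),
    dead = dead_seed_motif(duplex)
  )
}
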