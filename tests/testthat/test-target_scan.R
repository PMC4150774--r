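test_that("motif scanning finds all overlapping occurrences, 1-based", {
  expect_identical(scan_utr("UCCAUGA", "AAUCCAUGAAA"), 3L)
  expect_identical(scan_utr("UCCAUGA", "GGGGGGGGGG"), integer(0))
  expect_identical(scan_utr("AAAAAAA", "AAAAAAAA"), c(1L, 2L))
  expect_error(scan_utr("UCCAUGI", "AAA"), "characters")
  expect_error(scan_utr("UCCAUG", "AAA"), "7-mer")
  # matching is case-insensitive and DNA-tolerant
  expect_identical(scan_utr("uccauga", "aatccatgaaa"), 3L)
})

test_that("scanning agrees with a sliding-window oracle on random sequences", {
  set.seed(101)
  for (i in 1:30) {
    utr <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE), collapse = "")
    motif <- substr(utr, 11, 17) # guaranteed at least one hit
    expect_identical(scan_utr(motif, utr), oracle_scan(motif, utr))
  }
})

test_that("group assignment follows the four ordered steps on a toy set", {
  m <- fix_motifs()
  mot <- setNames(m$motif, m$group)
  utrs <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    sequence = c(
      flanked(mot[["U"]]),             # U only
      flanked(mot[["C"]]),             # C only
      flanked(c(mot[["U"]], mot[["C"]])), # U and C -> multi-group discard
      flanked(fix_dead()),             # dead-seed match
      "GGGGGGGGGG",                    # background
      flanked(mot[["G"]])              # G only
    )
  )
  tg <- assign_target_groups(utrs, m, fix_dead())
  expect_identical(group_members(tg, "U"), "g1")
  expect_identical(group_members(tg, "C"), "g2")
  expect_identical(group_members(tg, "G"), "g6")
  expect_identical(group_members(tg, "A"), character(0))
  expect_identical(group_discards(tg), "g3")
  expect_identical(dead_set(tg), "g4")
  expect_setequal(group_background(tg, "U"), c("g2", "g3", "g5", "g6"))
  expect_setequal(group_background(tg, "C"), c("g1", "g3", "g5", "g6"))
})

test_that("degenerate inputs assign everything to one side", {
  m <- fix_motifs()
  none <- tibble::tibble(gene_id = c("a", "b"),
                         sequence = c("GGGGGGGG", "CCCCCCCC"))
  tg <- assign_target_groups(none, m, fix_dead())
  expect_true(all(tg$assignment == "none"))
  for (g in c("A", "C", "G", "U")) {
    expect_setequal(group_background(tg, g), c("a", "b"))
  }

  all_dead <- tibble::tibble(gene_id = c("a", "b"),
                             sequence = rep(flanked(fix_dead()), 2))
  tg2 <- assign_target_groups(all_dead, m, fix_dead())
  expect_setequal(dead_set(tg2), c("a", "b"))
  for (g in c("A", "C", "G", "U")) {
    expect_identical(group_members(tg2, g), character(0))
    expect_identical(group_background(tg2, g), character(0))
  }
})

test_that("group structure invariants hold on random planted inputs", {
  m <- fix_motifs()
  mot <- setNames(m$motif, m$group)
  set.seed(202)
  for (rep in 1:5) {
    n <- 40
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), 50, replace = TRUE), collapse = "")
    }, character(1))
    # plant a random subset of motifs into random genes
    for (i in sample(n, 25, replace = TRUE)) {
      w <- sample(c(mot, dead = fix_dead()), 1)
      p <- sample(44, 1)
      substr(seqs[i], p, p + 6) <- w
    }
    utrs <- tibble::tibble(gene_id = sprintf("g%02d", 1:n), sequence = seqs)
    tg <- assign_target_groups(utrs, m, fix_dead())

    groups <- lapply(c("A", "C", "G", "U"), group_members, tg = tg)
    # pairwise disjoint, disjoint from dead
    expect_identical(anyDuplicated(unlist(groups)), 0L)
    expect_length(intersect(unlist(groups), dead_set(tg)), 0)
    # background composition: universe - dead - own group
    for (g in c("A", "C", "G", "U")) {
      expect_setequal(group_background(tg, g),
                      setdiff(utrs$gene_id,
                              union(dead_set(tg), group_members(tg, g))))
    }
    # a grouped gene matches its own motif only, and never the dead seed
    for (g in c("A", "C", "G", "U")) {
      for (gene in group_members(tg, g)) {
        seq <- utrs$sequence[utrs$gene_id == gene]
        expect_gte(length(scan_utr(mot[[g]], seq)), 1)
        for (other in setdiff(names(mot), g)) {
          expect_length(scan_utr(mot[[other]], seq), 0)
        }
        expect_length(scan_utr(fix_dead(), seq), 0)
      }
    }
    # permutation invariance of the assignment
    perm <- sample(n)
    tg_perm <- assign_target_groups(utrs[perm, ], m, fix_dead())
    joined <- merge(as.data.frame(tg)[c("gene_id", "assignment")],
                    as.data.frame(tg_perm)[c("gene_id", "assignment")],
                    by = "gene_id")
    expect_identical(joined$assignment.x, joined$assignment.y)
  }
})

test_that("id restriction is an order-stable intersection", {
  utrs <- tibble::tibble(gene_id = paste0("g", 1:6),
                         sequence = rep("ACGUACGU", 6))
  expect_identical(restrict_ids(utrs, utrs$gene_id), utrs)
  expect_identical(nrow(restrict_ids(utrs, character(0))), 0L)
  expect_identical(restrict_ids(utrs, c("g9", "g1"))$gene_id, "g1")
  expect_identical(restrict_ids(utrs, c("g5", "g2"))$gene_id, c("g2", "g5"))
})

test_that("duplicate gene ids and empty sequences are rejected", {
  expect_error(as_utr_table(tibble::tibble(gene_id = c("a", "a"),
                                           sequence = c("ACG", "ACG"))),
               "duplicate")
  expect_error(as_utr_table(tibble::tibble(gene_id = "a", sequence = "")),
               "empty")
})

test_that("hit counting retains per-motif occurrence counts", {
  m <- fix_motifs()
  utrs <- tibble::tibble(
    gene_id = "g1",
    sequence = flanked(c(m$motif[m$group == "U"], m$motif[m$group == "U"]))
  )
  hits <- count_motif_hits(utrs, setNames(m$motif, m$group))
  expect_identical(hits$U, 2L)
  expect_identical(hits$A + hits$C + hits$G, 0L)
})
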