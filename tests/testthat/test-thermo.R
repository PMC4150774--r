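test_that("Tm from aggregate energies follows the two-state formula", {
  # -50 kcal/mol, -140 cal/(mol K), 5 uM: R*ln(Ct/4) = -27.0
  expect_equal(tm_from_energies(-50, -140, 5e-6), 26.2, tolerance = 0.05)
  # doubling concentration strictly increases Tm for negative dS
  expect_gt(tm_from_energies(-50, -140, 1e-5), tm_from_energies(-50, -140, 5e-6))
  expect_error(tm_from_energies(-50, 30, 5e-6), "non-physical")
  expect_error(tm_from_energies(-50, -140, 0), "positive")
})

test_that("nearest-neighbor prediction agrees with a brute-force stack oracle", {
  params <- nn_parameters()
  lut_h <- setNames(params$dH_kcal, params$stack)
  lut_s <- setNames(params$dS_cal, params$stack)
  oracle_tm <- function(a, b, conc = 5e-6) {
    av <- strsplit(a, "")[[1]]; bv <- rev(strsplit(b, "")[[1]])
    dH <- lut_h[["init"]]; dS <- lut_s[["init"]]
    for (i in seq_len(length(av) - 1)) {
      key <- paste0(av[i], av[i + 1], "/", bv[i], bv[i + 1])
      dH <- dH + lut_h[[key]]; dS <- dS + lut_s[[key]]
    }
    for (i in c(1, length(av))) {
      if (paste0(av[i], bv[i]) %in% c("AU", "UA")) {
        dH <- dH + lut_h[["termAU"]]; dS <- dS + lut_s[["termAU"]]
      }
    }
    dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
  }
  # every one of the 16 WC dinucleotide stacks, as a 2-bp duplex
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  for (x in names(wc)) for (y in names(wc)) {
    top <- paste0(x, y)
    bottom <- paste0(wc[y], wc[x]) # 5'->3' on the other strand
    expect_equal(predict_tm_nn(top, bottom), oracle_tm(top, bottom),
                 tolerance = 1e-9, label = top)
  }
  # and on full 7-mer seed/target duplexes
  set.seed(123)
  for (i in 1:10) {
    a <- paste(sample(names(wc), 7, replace = TRUE), collapse = "")
    b <- rna_reverse_complement(a)
    expect_equal(predict_tm_nn(a, b), oracle_tm(a, b), tolerance = 1e-9)
  }
})

test_that("prediction is unavailable, not an error, without inosine parameters", {
  expect_true(is.na(predict_tm_nn("UCAUIGA", "UCCAUGA")))
  # G:U wobble stacks are also outside the Watson-Crick set
  expect_true(is.na(predict_tm_nn("UCAUGGA", "UCUAUGA")))
  # user-supplied parameters unlock the stacks
  extra <- tibble::tibble(stack = c("UI/AC", "IG/CC"),
                          dH_kcal = c(-8, -10), dS_cal = c(-22, -26))
  params <- rbind(nn_parameters(), extra)
  expect_false(is.na(predict_tm_nn("UCAUIGA", "UCCAUGA", params = params)))
  expect_error(predict_tm_nn("ACGU", "ACG"), "equal length")
})

test_that("calibration lookups return the measured values exactly", {
  tab <- calibration_table()
  expect_equal(lookup_tm(tab, "UCAUAGA", "UCUAUGA"), 26.6)
  expect_equal(lookup_tm(tab, "UCAUGGA", "UCCAUGA"), 39.0)
  expect_equal(lookup_tm(tab, "UCAUIGA", "UCCAUGA"), 23.3)
  expect_equal(lookup_tm(tab, "UCAUGGA", "UCUAUGA"), 19.3)
  expect_equal(lookup_tm(tab, "UCAUIGA", "UCUAUGA"), 9.3)
  # the A:C duplex is present but not determined
  expect_true(is.na(lookup_tm(tab, "UCAUAGA", "UCCAUGA")))
  # an absent key is a distinguishable missing-entry condition
  expect_error(lookup_tm(tab, "AAAAAAA", "UUUUUUU"),
               class = "inoseed_missing_entry")
})

test_that("stored calibration reproduces the pairing stability ranking", {
  tab <- calibration_table()
  tm_of <- function(p) tab$tm_C[tab$pair == p]
  expect_true(tm_of("G:C") > tm_of("A:U"))
  expect_true(tm_of("A:U") > tm_of("I:C"))
  expect_true(tm_of("I:C") > tm_of("G:U"))
  expect_true(tm_of("G:U") > tm_of("I:U"))
})

test_that("two-point-average recovers the midpoint of a symmetric transition", {
  curve <- simulate_melting_curve(40, width = 3)
  expect_equal(tm_two_point_average(curve), 40, tolerance = 0.1)
  # constant absorbance offset leaves Tm unchanged
  shifted <- curve
  shifted$absorbance <- shifted$absorbance + 0.25
  expect_equal(tm_two_point_average(shifted), tm_two_point_average(curve),
               tolerance = 1e-9)
  # invariance under affine rescaling of the absorbance axis
  scaled <- curve
  scaled$absorbance <- 3.7 * scaled$absorbance - 1.2
  expect_equal(tm_two_point_average(scaled), tm_two_point_average(curve),
               tolerance = 1e-9)
})

test_that("two-point-average validates its inputs and failure modes", {
  curve <- simulate_melting_curve(40)
  expect_error(tm_two_point_average(curve, baseline_fraction = 0.6),
               "baseline_fraction")
  bad <- curve
  bad$temperature <- rev(bad$temperature)
  expect_error(tm_two_point_average(bad), "increasing")
  expect_error(tm_two_point_average(curve[1:5, ]), ">= 10")
  # a decreasing (hypochromic) curve still crosses its midpoint
  monot <- tibble::tibble(temperature = seq(4, 95, length.out = 20),
                          absorbance = seq(1, 0.05, length.out = 20))
  expect_no_error(tm_two_point_average(monot, baseline_fraction = 0.05))
})

test_that("miScore is linear with the printed 0.5 coefficient", {
  expect_equal(miscore(39.0, 0), 39.0)
  expect_equal(miscore(26.6, 10.0), 21.6)
  expect_equal(miscore(23.3, -10.0), 28.3)
  expect_error(miscore(NA, 1), "finite")
  set.seed(11)
  a <- runif(5, 0, 40); b <- runif(5, -20, 20)
  expect_equal(miscore(a, b), a - 0.5 * b)
})

test_that("seed-duplex Tm resolution records provenance", {
  res <- seed_duplex_tm("UCAUAGA", "UCUAUGA")
  expect_equal(res$tm, 26.6)
  expect_identical(res$provenance, "measured")

  nd <- seed_duplex_tm("UCAUAGA", "UCCAUGA")
  expect_true(is.na(nd$tm))
  expect_identical(nd$provenance, "not_determined")

  # nn mode on a Watson-Crick pair delegates to the predictor
  nn <- seed_duplex_tm("UCAUAGA", "UCUAUGA", method = "nn")
  expect_equal(nn$tm, predict_tm_nn("UCAUAGA", "UCUAUGA"))
  expect_identical(nn$provenance, "predicted")

  # inosine pair in nn mode without parameters is unavailable
  un <- seed_duplex_tm("UCAUIGA", "UCCAUGA", method = "nn")
  expect_true(is.na(un$tm))
  expect_identical(un$provenance, "unavailable")

  # absent lookup key without fallback is unavailable; with fallback, predicted
  miss <- seed_duplex_tm("AAAAAAA", "UUUUUUU")
  expect_identical(miss$provenance, "unavailable")
  fb <- seed_duplex_tm("AAAAAAA", "UUUUUUU", fallback_nn = TRUE)
  expect_identical(fb$provenance, "predicted")
  expect_equal(fb$tm, predict_tm_nn("AAAAAAA", "UUUUUUU"))
})
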