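test_that("foldedness windows classify the canonical distances", {
  expect_identical(classify_foldedness(4.5), "folded")
  expect_identical(classify_foldedness(9.0), "semi_extended")
  expect_identical(classify_foldedness(13.5), "extended")
  expect_identical(classify_foldedness(7.0), "intermediate")
  # boundaries: folded upper bound open, others closed
  expect_identical(classify_foldedness(c(0, 5.999, 6, 8, 10, 12, 15, 15.5)),
                   c("folded", "folded", "intermediate", "semi_extended",
                     "semi_extended", "extended", "extended", "intermediate"))
  expect_error(classify_foldedness(-1), "negative")
})

test_that("overlapping or degenerate foldedness windows are rejected", {
  w <- classification_windows()
  w$foldedness$semi_extended <- c(5, 10)
  expect_error(classify_foldedness(4, w), "overlap")
  w2 <- classification_windows()
  w2$foldedness$folded <- c(6, 6)
  expect_error(classify_foldedness(4, w2), "degenerate")
})

test_that("glycosidic torsions classify as syn/anti with high-anti/high-syn sub-flags", {
  expect_identical(classify_glycosidic(-160), "anti")
  expect_identical(classify_glycosidic(20), "syn")
  expect_identical(glycosidic_subflag(-60), "high_anti")
  expect_identical(glycosidic_subflag(110), "high_syn")
  expect_identical(glycosidic_subflag(c(-160, 20)), c("none", "none"))
  # high-syn lies inside the anti primary window; high-anti in the gap
  expect_identical(classify_glycosidic(110), "anti")
  expect_identical(classify_glycosidic(-60, base = "A"), "other")
})

test_that("glycosidic classification is periodic in 360 degrees", {
  set.seed(12)
  chi <- stats::runif(200, -180, 180)
  expect_identical(classify_glycosidic(chi), classify_glycosidic(chi + 360))
  expect_identical(classify_glycosidic(chi), classify_glycosidic(chi - 360))
  expect_identical(glycosidic_subflag(chi), glycosidic_subflag(chi + 720))
})

test_that("pucker classification splits C2'-endo / C3'-endo / flat at nu2 = +-10", {
  expect_identical(classify_pucker(-38), "C2p_endo")
  expect_identical(classify_pucker(38), "C3p_endo")
  expect_identical(classify_pucker(0), "flat")
  expect_identical(classify_pucker(c(-10, -9.99, 9.99, 10)),
                   c("C2p_endo", "flat", "flat", "C3p_endo"))
})

test_that("amide orientation classifies its four populations", {
  expect_identical(classify_amide(0), "near_0")
  expect_identical(classify_amide(180), "near_180")
  expect_identical(classify_amide(-170), "near_180")
  expect_identical(classify_amide(45), "offset_plus")
  expect_identical(classify_amide(-45), "offset_minus")
  expect_identical(classify_amide(120), "other")
})

test_that("classification is total and ensemble fractions sum to one", {
  set.seed(8)
  d <- stats::runif(500, 0, 20)
  states <- classify_foldedness(d)
  expect_false(anyNA(states))
  expect_equal(sum(state_fractions(states)), 1)
  th <- stats::runif(500, -180, 180)
  expect_false(anyNA(classify_amide(th)))
  expect_false(anyNA(classify_glycosidic(th)))
  expect_false(anyNA(classify_pucker(th)))
})

test_that("windows serialize verbatim for report provenance", {
  txt <- format_windows()
  expect_true(any(grepl("foldedness.folded = 0, 6", txt)))
  expect_true(any(grepl("pucker_flat_halfwidth = 10", txt)))
})
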