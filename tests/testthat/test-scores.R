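test_that("per-atom vectors spread onto atom tokens with zeros elsewhere", {
  sc <- attachScores(tokenizeSmiles("C1CC1"), c(0.1, 0.2, 0.3))
  expect_identical(scoreMode(sc), "PER_ATOM")
  expect_equal(scores(sc), c(0.1, 0, 0.2, 0.3, 0))
  # conservation under spreading
  expect_equal(sum(scores(sc)), sum(c(0.1, 0.2, 0.3)))
  expect_equal(sum(scores(sc)[tokenTable(sc)$kind != "ATOM"]), 0)

  sc2 <- attachScores(tokenizeSmiles("CCO"), c(1, 2, 3))
  expect_equal(scores(sc2), c(1, 2, 3))

  sc3 <- attachScores(tokenizeSmiles("C1CC1"), c(1, 2, 3, 4, 5))
  expect_identical(scoreMode(sc3), "PER_TOKEN")
})

test_that("inadmissible score lengths raise naming both admissible lengths", {
  expect_error(attachScores(tokenizeSmiles("C1CC1"), rep(0.1, 4)),
               "3 \\(per atom\\) or 5 \\(per token\\)")
  expect_error(attachScores(tokenizeSmiles("CCO"), c(1, NA, 3)), "finite")
})

test_that("default domain is symmetric at the molecule's max |score|", {
  sc <- attachScores(tokenizeSmiles("CCO"), c(0.2, -0.6, 0.4))
  expect_equal(defaultDomain(sc), c(-0.6, 0.6))
  expect_equal(defaultDomain(c(-0.9, 0.2)), c(-0.9, 0.9))
  expect_warning(d <- defaultDomain(c(0, 0, 0)), "zero")
  expect_equal(d, c(-1, 1))
})

test_that("normalization scales per sign and clamps at the domain", {
  expect_equal(normalizeScore(0.6, c(-0.33, 0.33)), 1)
  expect_equal(normalizeScore(0, c(-0.33, 0.33)), 0)
  expect_equal(normalizeScore(-0.165, c(-0.33, 0.33)), -0.5)
  # asymmetric domains normalize each sign against its own bound
  expect_equal(normalizeScore(c(-0.2, 0.3), c(-0.4, 0.6)), c(-0.5, 0.5))
  # triple form accepted
  expect_equal(normalizeScore(0.25, c(-0.5, 0, 0.5)), 0.5)
  expect_error(normalizeScore(1, c(-0.5, 0.1, 0.5)), "midpoint")
  # monotone and sign-preserving over a sweep
  x <- seq(-2, 2, by = 0.01)
  v <- normalizeScore(x, c(-0.7, 0.7))
  expect_true(all(diff(v) >= 0))
  expect_identical(sign(v), sign(pmax(pmin(x, 1), -1)))
  # idempotent at the boundary
  expect_equal(normalizeScore(normalizeScore(5, c(-1, 1)), c(-1, 1)), 1)
})

test_that("threshold fractions become absolute cutoffs on the domain max", {
  expect_equal(thresholdCutoffs(0.5, c(-0.5, 0, 0.5)), 0.25)
  expect_equal(thresholdCutoffs(0, c(-0.3, 0.3)), 0)
  expect_equal(thresholdCutoffs(c(0.5, 0.75), c(-1, 1)), c(0.5, 0.75))
  expect_identical(thresholdCutoffs(numeric(0), c(-1, 1)), numeric(0))
  expect_error(thresholdCutoffs(1.2, c(-1, 1)), "\\[0, 1\\]")
  expect_error(thresholdCutoffs(-0.1, c(-1, 1)), "\\[0, 1\\]")
})

test_that("highlighted atom sets use |score| >= cutoff and are nested", {
  sc <- attachScores(tokenizeSmiles("CCO"), c(0.3, -0.26, 0.1))
  expect_identical(highlightedAtoms(sc, 0.25)[[1]], c(1L, 2L))
  # cutoff 0 selects every atom with nonzero score
  sc0 <- attachScores(tokenizeSmiles("CCO"), c(0.3, 0, 0.1))
  expect_identical(highlightedAtoms(sc0, 0)[[1]], c(1L, 3L))
  hl <- highlightedAtoms(sc, c(0.25, 0.5))
  expect_true(all(hl[[2]] %in% hl[[1]]))
  # monotone shrinkage along a cutoff sweep
  sizes <- lengths(highlightedAtoms(sc, seq(0, 0.4, by = 0.05)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("score colors anchor at middle and endpoints and darken outward", {
  pal <- divergingPalettes()$RdBu
  expect_identical(scoreToColor(0, c(-1, 1), "RdBu"), pal[3])
  expect_identical(scoreToColor(0.6, c(-0.6, 0.6), "RdBu"), pal[5])
  expect_identical(scoreToColor(2, c(-1, 1), "RdBu"), pal[5])
  expect_identical(scoreToColor(-2, c(-1, 1), "RdBu"), pal[1])
  # lightness decreases monotonically toward either endpoint
  for (name in names(divergingPalettes())) {
    vals <- seq(0.05, 1, by = 0.05)
    Lpos <- smivis:::colorLightness(scoreToColor(vals, c(-1, 1), name))
    Lneg <- smivis:::colorLightness(scoreToColor(-vals, c(-1, 1), name))
    expect_true(all(diff(Lpos) < 0))
    expect_true(all(diff(Lneg) < 0))
  }
})

test_that("palette mirror symmetry holds for symmetric scores", {
  pal <- divergingPalettes()$PiYG
  mirrored <- rev(pal)
  for (s in c(0.15, 0.4, 0.85)) {
    expect_identical(scoreToColor(-s, c(-1, 1), pal),
                     scoreToColor(s, c(-1, 1), mirrored))
  }
})

test_that("even-length custom palettes are rejected", {
  expect_error(scoreToColor(0.5, c(-1, 1), c("#FF0000", "#0000FF")),
               "odd length")
  expect_error(panelConfig(palette = c("#FF0000", "#0000FF")), "odd length")
  # odd custom palettes work
  expect_identical(scoreToColor(0, c(-1, 1),
                                c("#FF0000", "#FFFFFF", "#0000FF")),
                   "#FFFFFF")
})

test_that("palettes load from JSON color-list files", {
  f <- system.file("extdata", "palette-teal-maroon.json", package = "smivis")
  cols <- as.character(unlist(jsonlite::fromJSON(f)))
  expect_identical(scoreToColor(0, c(-1, 1), f), cols[3])
  expect_identical(scoreToColor(5, c(-1, 1), f), cols[5])
  expect_error(scoreToColor(0, c(-1, 1), "no-such-palette.json"),
               "does not exist")
})
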