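svgDoc <- function(fragment) {
  xml2::read_xml(paste0('<svg xmlns="http://www.w3.org/2000/svg">',
                        fragment, "</svg>"))
}

test_that("bar chart draws one bar per token in token order", {
  sc <- attachScores(tokenizeSmiles("C1CC1"), c(0.1, 0.2, 0.3))
  g <- svgDoc(renderBarChart(sc, panelConfig(), c(-1, 1)))
  bars <- xml2::xml_find_all(g, ".//*[@class='bar']")
  expect_length(bars, 5L)
  toks <- xml2::xml_find_all(g, ".//*[@class='tok']")
  expect_identical(xml2::xml_attr(toks, "data-token"), as.character(1:5))
})

test_that("bars clamp to full height at the domain and flag negatives", {
  cfg <- panelConfig()
  bh <- cfg@geometry$barHeight
  sc <- attachScores(tokenizeSmiles("CCO"), c(0.5, -0.5, 0.5))
  g <- svgDoc(renderBarChart(sc, cfg, c(-0.5, 0.5)))
  bars <- xml2::xml_find_all(g, ".//*[@class='bar']")
  expect_identical(unique(xml2::xml_attr(bars, "height")),
                   formatC(bh, format = "f", digits = 2))
  signs <- xml2::xml_find_all(g, ".//*[@class='sign']")
  expect_length(signs, 1L)  # only the negative bar carries the marker
  # sign-only mode: a tiny domain sends every nonzero bar to full height
  sc2 <- attachScores(tokenizeSmiles("CCO"), c(0.001, -2, 0.4))
  g2 <- svgDoc(renderBarChart(sc2, panelConfig(signOnly = TRUE)))
  h2 <- xml2::xml_attr(xml2::xml_find_all(g2, ".//*[@class='bar']"), "height")
  expect_identical(unique(h2), formatC(bh, format = "f", digits = 2))
})

test_that("guide lines sit at the threshold fractions, default 0.5 and 1", {
  sc <- attachScores(tokenizeSmiles("CCO"), c(0.2, 0.4, 0.1))
  cfg <- panelConfig()
  bh <- cfg@geometry$barHeight
  g <- svgDoc(renderBarChart(sc, cfg, c(-1, 1)))
  ys <- xml2::xml_attr(xml2::xml_find_all(g, ".//*[@class='guide']"), "y1")
  expect_identical(ys, formatC(bh - c(0.5, 1) * bh, format = "f", digits = 2))
  g2 <- svgDoc(renderBarChart(sc, panelConfig(thresholds = 0.75), c(-1, 1)))
  ys2 <- xml2::xml_attr(xml2::xml_find_all(g2, ".//*[@class='guide']"), "y1")
  expect_identical(ys2, formatC(bh - 0.75 * bh, format = "f", digits = 2))
})

test_that("molecule panel separates positive and negative heatmap layers", {
  lay <- buildAtomLayout("CCO")
  sc <- attachScores(tokenizeSmiles("CCO"), c(0.5, -0.5, 0))
  g <- svgDoc(renderMoleculePanel(lay, sc, panelConfig(), c(-1, 1)))
  neg <- xml2::xml_find_all(g, ".//*[@class='heat-neg']/*")
  pos <- xml2::xml_find_all(g, ".//*[@class='heat-pos']/*")
  expect_length(neg, 1L)
  expect_length(pos, 1L)
  # zero scores draw no heat mark at all
  sc0 <- attachScores(tokenizeSmiles("CCO"), c(0, 0, 0))
  g0 <- svgDoc(renderMoleculePanel(lay, sc0, panelConfig(), c(-1, 1)))
  expect_length(xml2::xml_find_all(g0, ".//*[@class='heat-neg']/*"), 0L)
  expect_length(xml2::xml_find_all(g0, ".//*[@class='heat-pos']/*"), 0L)
})

test_that("threshold circles and score labels follow the configuration", {
  lay <- buildAtomLayout("CCO")
  sc <- attachScores(tokenizeSmiles("CCO"), c(1, 0.2, -0.1))
  g <- svgDoc(renderMoleculePanel(lay, sc, panelConfig(thresholds = 0.75),
                                  c(-1, 1)))
  expect_length(xml2::xml_find_all(g, ".//*[@class='thresh']"), 1L)
  # no thresholds + labels: numeric labels, no circles
  gl <- svgDoc(renderMoleculePanel(lay, sc,
                                   panelConfig(showScoreLabels = TRUE),
                                   c(-1, 1)))
  expect_length(xml2::xml_find_all(gl, ".//*[@class='thresh']"), 0L)
  labs <- xml2::xml_find_all(gl, ".//*[@class='scorelabel']")
  expect_identical(xml2::xml_text(labs), c("1.00", "0.20", "-0.10"))
})

test_that("bar colors and heatmap colors agree per atom", {
  smi <- "CC(=O)O"
  lay <- buildAtomLayout(smi)
  sc <- attachScores(tokenizeSmiles(smi), c(0.5, -0.2, 0.8, -0.9))
  dom <- defaultDomain(sc)
  cfg <- panelConfig()
  bar <- svgDoc(renderBarChart(sc, cfg, dom))
  mol <- renderMoleculePanel(lay, sc, cfg, dom)
  fills <- xml2::xml_attr(xml2::xml_find_all(bar, ".//*[@class='bar']"),
                          "fill")
  tk <- tokenTable(sc)
  for (p in atomTokenPositions(sc)) {
    a <- tk$atomIndex[p]
    stop1 <- regmatches(mol, regexpr(
      sprintf('id="p0-hm-%d"><stop offset="0%%" stop-color="[^"]+"', a),
      mol))
    expect_match(stop1, fills[p], fixed = TRUE)
  }
})

test_that("attribute table renders rows in input order, or not at all", {
  g <- svgDoc(renderAttributeTable(c(method = "CDDD-Substitution",
                                     pred = "3.2")))
  rows <- xml2::xml_find_all(g, ".//*[@class='attrow']")
  expect_length(rows, 2L)
  expect_match(xml2::xml_text(rows[[1]]), "method")
  expect_identical(renderAttributeTable(character(0)), "")
  g4 <- svgDoc(renderAttributeTable(c(a = "1", b = "2", c = "3", d = "4")))
  expect_identical(
    substr(xml2::xml_text(xml2::xml_find_all(g4, ".//*[@class='attrow']")),
           1, 1), c("a", "b", "c", "d"))
})

test_that("composed panels are well-formed, deterministic, and complete", {
  rec <- new("SmilesRecord", smiles = "CC(=O)Oc1ccccc1C(=O)O",
             scores = c(0.5, -0.2, 0.8, -0.9, 0.1, 0.2, 0.1, -0.3, 0.4,
                        -0.1, 0.6, 0.2, -0.5),
             attributes = c(method = "demo"), config = list(),
             id = "aspirin", extra = list())
  svg <- composePanel(rec)
  doc <- xml2::read_xml(svg)  # parses as XML
  expect_identical(xml2::xml_name(doc), "svg")
  expect_identical(composePanel(rec), svg)  # byte-identical re-render
  # PER_ATOM record: bars equal token count, not score-vector length
  nt <- nTokens(tokenizeSmiles(rec@smiles))
  bars <- xml2::xml_find_all(doc, ".//*[local-name()='rect'][@class='bar']")
  expect_length(bars, nt)
  expect_gt(nt, length(rec@scores))
  # heat layers precede the structure drawing in document order
  expect_lt(regexpr('class="heat-pos"', svg, fixed = TRUE),
            regexpr('class="mol"', svg, fixed = TRUE))
  # hover map embedded
  expect_match(svg, "data-hovermap")
  # errors carry the record id
  bad <- new("SmilesRecord", smiles = "CC(", scores = numeric(0),
             attributes = character(0), config = list(), id = "brokenrec",
             extra = list())
  expect_error(composePanel(bad), "brokenrec")
})

test_that("galleries hold one panel per record and are self-contained", {
  recs <- list(
    new("SmilesRecord", smiles = "CCO", scores = c(1, -1, 0.5),
        attributes = character(0), config = list(), id = "r1",
        extra = list()),
    new("SmilesRecord", smiles = "c1ccccc1", scores = rep(0.3, 6),
        attributes = character(0), config = list(), id = "r2",
        extra = list()),
    new("SmilesRecord", smiles = "CC(=O)O", scores = c(0.1, -0.2, 0.3, 0.4),
        attributes = character(0), config = list(), id = "r3",
        extra = list()))
  html <- renderGallery(recs)
  expect_identical(lengths(regmatches(html,
    gregexpr('class="smivis-panel"', html, fixed = TRUE))), 3L)
  ids <- regmatches(html, gregexpr('data-id="[^"]+"', html))[[1]]
  expect_identical(ids, sprintf('data-id="r%d"', 1:3))
  # no external references (the SVG namespace URI is an identifier, not a
  # fetched resource)
  expect_false(grepl('(src|href)="http', html))
  # same molecule, two configs: panels differ, hover maps agree
  one <- recs[[1]]
  p1 <- composePanel(one, panelConfig(palette = "RdBu"))
  p2 <- composePanel(one, panelConfig(palette = "PiYG"))
  expect_false(identical(p1, p2))
  hm <- function(x) regmatches(x, regexpr("data-hovermap='[^']*'", x))
  expect_identical(hm(p1), hm(p2))
  expect_error(renderGallery(list()), "non-empty")
})
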