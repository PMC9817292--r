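# SVG panel composition: dual positive/negative heatmap layers beneath the
# skeletal structure, the token bar chart, the attribute table, and the
# multi-molecule HTML gallery with embedded hover maps. Output is plain
# text built with fixed-precision formatting, so identical input yields
# byte-identical documents.

.fmt <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

.escapeXml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

.ELEMENT_COLORS <- c(
  C = "#000000", N = "#3050F8", O = "#E00000", S = "#9A7D0A", P = "#FF8000",
  F = "#00A550", Cl = "#1DA51D", Br = "#A62929", I = "#940094", B = "#DB7D54")
.DEFAULT_ELEMENT_COLOR <- "#444444"

.elementColor <- function(symbol, blackAtoms) {
  if (blackAtoms) return("#000000")
  hit <- .ELEMENT_COLORS[symbol]
  ifelse(is.na(hit), .DEFAULT_ELEMENT_COLOR, hit)
}

# map depiction coordinates into a width x height viewport (y flipped)
.screenCoords <- function(coords, width, height, pad) {
  if (!nrow(coords)) return(coords)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  dx <- max(rx[2] - rx[1], 1e-9); dy <- max(ry[2] - ry[1], 1e-9)
  s <- min((width - 2 * pad) / dx, (height - 2 * pad) / dy)
  x <- (coords[, 1] - rx[1]) * s
  y <- (ry[2] - coords[, 2]) * s
  x <- x + (width - max(x)) / 2
  y <- y + (height - max(y)) / 2
  cbind(x = x, y = y)
}

.medianBondLength <- function(xy, bonds, fallback) {
  if (!nrow(bonds)) return(fallback)
  d <- sqrt((xy[bonds[, 1], 1] - xy[bonds[, 2], 1])^2 +
            (xy[bonds[, 1], 2] - xy[bonds[, 2], 2])^2)
  stats::median(d)
}

#' Render the token bar chart
#'
#' One bar per token, in token order: bar height is |normalized score| times
#' the chart height, bar fill is the score's palette color, the token text
#' sits beneath its bar and a minus marker flags bars of negative score.
#' Horizontal guide lines are drawn at the configured threshold fractions
#' (or at 0.5 and 1 when no thresholds are set). Under a deliberately tiny
#' domain every nonzero bar therefore clamps to full height, leaving only
#' the sign visible.
#'
#' @param scored a [ScoredSmiles-class] object.
#' @param config a [PanelConfig-class].
#' @param domain resolved colormap domain (defaults to the config's domain
#'   or, failing that, the molecule's [defaultDomain()]).
#' @return character scalar: an SVG \code{<g>} fragment.
#' @export
renderBarChart <- function(scored, config = panelConfig(), domain = NULL) {
  stopifnot(is(scored, "ScoredSmiles"), is(config, "PanelConfig"))
  if (is.null(domain))
    domain <- if (length(config@domain)) config@domain else
      defaultDomain(scored)
  geo <- config@geometry
  nt <- nTokens(scored)
  bw <- geo$barWidth; bh <- geo$barHeight; gap <- geo$barGap
  fs <- geo$fontSize
  v <- normalizeScore(scored@scores, domain)
  cols <- scoreToColor(scored@scores, domain, config@palette)
  width <- nt * bw
  out <- sprintf('<g class="barchart" font-size="%s" font-family="monospace">',
                 .fmt(fs, 0))
  fractions <- if (length(config@thresholds)) config@thresholds else c(0.5, 1)
  for (f in fractions) {
    y <- .fmt(bh - f * bh)
    out <- c(out, sprintf(
      '<line class="guide" x1="0" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-dasharray="3,2"/>',
      y, .fmt(width), y))
  }
  tk <- tokenTable(scored)
  for (i in seq_len(nt)) {
    h <- abs(v[i]) * bh
    x <- (i - 1) * bw
    bar <- sprintf(
      '<rect class="bar" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
      .fmt(x + gap / 2), .fmt(bh - h), .fmt(bw - gap), .fmt(h), cols[i])
    label <- sprintf(
      '<text class="toktext" x="%s" y="%s" text-anchor="middle">%s</text>',
      .fmt(x + bw / 2), .fmt(bh + fs), .escapeXml(tk$text[i]))
    sign <- if (scored@scores[i] < 0) sprintf(
      '<text class="sign" x="%s" y="%s" text-anchor="middle">-</text>',
      .fmt(x + bw / 2), .fmt(bh + 2 * fs)) else NULL
    out <- c(out, sprintf('<g class="tok" data-token="%d">', i),
             bar, label, sign, "</g>")
  }
  paste(c(out, "</g>"), collapse = "\n")
}

#' Render the molecule diagram with its heatmap layers
#'
#' Draws, in document order: the negative-score heatmap layer, the
#' positive-score heatmap layer (one radial-gradient mark per scored atom,
#' opacity proportional to |normalized score|), white-stroked threshold
#' circles whose radius grows with the distance of the score from the
#' threshold, the skeletal structure (bonds plus element labels), and
#' optional numeric per-atom score labels. Keeping the structure above the
#' color fields keeps bond lines legible.
#'
#' @inheritParams renderBarChart
#' @param layout the molecule's [AtomLayout-class] (same SMILES as
#'   \code{scored}).
#' @param panelId id prefix namespacing gradient definitions when several
#'   panels share one document.
#' @return character scalar: SVG \code{<defs>} plus a \code{<g>} fragment.
#' @export
renderMoleculePanel <- function(layout, scored, config = panelConfig(),
                                domain = NULL, panelId = "p0") {
  stopifnot(is(layout, "AtomLayout"), is(scored, "ScoredSmiles"),
            is(config, "PanelConfig"))
  if (smiles(layout) != smiles(scored))
    stop("layout and scores refer to different SMILES strings",
         call. = FALSE)
  if (is.null(domain))
    domain <- if (length(config@domain)) config@domain else
      defaultDomain(scored)
  geo <- config@geometry
  w <- geo$molWidth; h <- geo$molHeight; fs <- geo$fontSize
  mol <- obParseSmiles(smiles(layout))
  xy <- .screenCoords(layout@coords, w, h, geo$pad)
  bonds <- layout@bonds
  medBond <- .medianBondLength(xy, bonds, min(w, h) / 8)
  heatR <- 0.9 * medBond
  pos <- atomTokenPositions(scored)
  atomScore <- scored@scores[pos]
  vAtom <- normalizeScore(atomScore, domain)
  colAtom <- scoreToColor(atomScore, domain, config@palette)
  na <- nAtoms(layout)

  defs <- character(0)
  heatNeg <- character(0); heatPos <- character(0)
  for (a in seq_len(na)) {
    if (atomScore[a] == 0) next
    alpha <- 0.75 * abs(vAtom[a])
    gid <- sprintf("%s-hm-%d", panelId, a)
    defs <- c(defs, sprintf(
      paste0('<radialGradient id="%s"><stop offset="0%%" stop-color="%s" ',
             'stop-opacity="%s"/><stop offset="100%%" stop-color="%s" ',
             'stop-opacity="0"/></radialGradient>'),
      gid, colAtom[a], .fmt(alpha, 4), colAtom[a]))
    mark <- sprintf(
      '<circle class="heat" cx="%s" cy="%s" r="%s" fill="url(#%s)"/>',
      .fmt(xy[a, 1]), .fmt(xy[a, 2]), .fmt(heatR), gid)
    if (atomScore[a] < 0) heatNeg <- c(heatNeg, mark) else
      heatPos <- c(heatPos, mark)
  }

  circles <- character(0)
  for (t in config@thresholds) {
    hit <- which(abs(atomScore) >= t * domain[2] & atomScore != 0)
    for (a in hit) {
      r <- fs + medBond * (abs(vAtom[a]) - t)
      circles <- c(circles, sprintf(
        '<circle class="thresh" cx="%s" cy="%s" r="%s" fill="none" stroke="#FFFFFF" stroke-width="2.5"/>',
        .fmt(xy[a, 1]), .fmt(xy[a, 2]), .fmt(r)))
    }
  }

  bondLines <- character(0)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]; ord <- bonds[k, 3]
    x1 <- xy[a, 1]; y1 <- xy[a, 2]; x2 <- xy[b, 1]; y2 <- xy[b, 2]
    len <- max(sqrt((x2 - x1)^2 + (y2 - y1)^2), 1e-9)
    ox <- -(y2 - y1) / len * 2.2; oy <- (x2 - x1) / len * 2.2
    offs <- switch(as.character(ord),
                   "2" = c(-1, 1), "3" = c(-2, 0, 2), "4" = c(-1, 1), 0)
    for (o in offs) {
      dash <- if (ord == 4 && o > 0) ' stroke-dasharray="4,3"' else ""
      bondLines <- c(bondLines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1.4"%s/>',
        .fmt(x1 + o * ox), .fmt(y1 + o * oy),
        .fmt(x2 + o * ox), .fmt(y2 + o * oy), dash))
    }
  }

  atomGlyphs <- character(0)
  for (a in seq_len(na)) {
    sym <- mol$symbols[a]
    labelled <- sym != "C" || !nrow(bonds) ||
      !a %in% c(bonds[, 1], bonds[, 2])
    if (labelled) {
      atomGlyphs <- c(atomGlyphs, sprintf(
        paste0('<text class="atomlabel" x="%s" y="%s" text-anchor="middle" ',
               'dy="%s" fill="%s" stroke="#FFFFFF" stroke-width="3" ',
               'paint-order="stroke" font-weight="bold">%s</text>'),
        .fmt(xy[a, 1]), .fmt(xy[a, 2]), .fmt(fs * 0.36),
        .elementColor(sym, config@blackAtoms), .escapeXml(sym)))
    }
  }

  scoreLabels <- character(0)
  if (config@showScoreLabels) for (a in seq_len(na)) {
    scoreLabels <- c(scoreLabels, sprintf(
      paste0('<text class="scorelabel" x="%s" y="%s" text-anchor="middle" ',
             'fill="#333333" stroke="#FFFFFF" stroke-width="2" ',
             'paint-order="stroke">%s</text>'),
      .fmt(xy[a, 1]), .fmt(xy[a, 2] - fs * 0.9), .fmt(atomScore[a])))
  }

  hits <- vapply(seq_len(na), function(a) sprintf(
    '<circle class="atomhit" data-atom="%d" data-signcolor="%s" cx="%s" cy="%s" r="%s" fill="transparent"/>',
    a, colAtom[a], .fmt(xy[a, 1]), .fmt(xy[a, 2]), .fmt(fs)), character(1))

  paste(c(if (length(defs)) c("<defs>", defs, "</defs>"),
          sprintf('<g class="molpanel" font-size="%s" font-family="sans-serif">',
                  .fmt(fs, 0)),
          '<g class="heat-neg">', heatNeg, "</g>",
          '<g class="heat-pos">', heatPos, "</g>",
          '<g class="thresholds">', circles, "</g>",
          '<g class="mol">', bondLines, atomGlyphs, "</g>",
          '<g class="scorelabels">', scoreLabels, "</g>",
          '<g class="atomhits">', hits, "</g>",
          "</g>"), collapse = "\n")
}

#' Render the attribute table
#'
#' One row per attribute, in input order; an empty input yields no group at
#' all (the table is optional).
#'
#' @param attributes named character vector (ordered key/value rows).
#' @param config a [PanelConfig-class].
#' @return character scalar: an SVG \code{<g>} fragment, or \code{""}.
#' @export
renderAttributeTable <- function(attributes, config = panelConfig()) {
  stopifnot(is(config, "PanelConfig"))
  if (!length(attributes)) return("")
  geo <- config@geometry
  rh <- geo$tableRowHeight; fs <- geo$fontSize
  rows <- vapply(seq_along(attributes), function(i) sprintf(
    paste0('<text class="attrow" x="0" y="%s"><tspan font-weight="bold">',
           '%s</tspan><tspan x="110">%s</tspan></text>'),
    .fmt(i * rh), .escapeXml(names(attributes)[i]),
    .escapeXml(attributes[[i]])), character(1))
  paste(c(sprintf('<g class="attrs" font-size="%s" font-family="sans-serif">',
                  .fmt(fs, 0)),
          rows, "</g>"), collapse = "\n")
}

#' Compose the full panel for one molecule record
#'
#' Runs the whole pipeline for one record -- tokenize, build the layout,
#' attach the scores, resolve the colormap domain and the hover map -- and
#' assembles the three coordinated components (molecule diagram over its
#' heatmap layers, token bar chart, attribute table) into one well-formed
#' standalone SVG document. The complete hover map is embedded in the root
#' element's \code{data-hovermap} attribute (1-based indices). Output is
#' deterministic: the same record and configuration produce identical
#' bytes.
#'
#' @param record a [SmilesRecord-class] (or a bare SMILES string, rendered
#'   score-less).
#' @param config a [PanelConfig-class]; the record's own config override,
#'   if any, is merged on top.
#' @param panelId id prefix for definitions inside the document.
#' @return character scalar: an SVG 1.1 document.
#' @examples
#' \donttest{
#' rec <- makeFixtures(1, seed = 7)[[1]]
#' svg <- composePanel(rec)
#' }
#' @export
composePanel <- function(record, config = panelConfig(), panelId = "p0") {
  if (is.character(record) && length(record) == 1L)
    record <- new("SmilesRecord", smiles = record, scores = numeric(0),
                  attributes = character(0), config = list(),
                  id = record, extra = list())
  stopifnot(is(record, "SmilesRecord"), is(config, "PanelConfig"))
  withCallingHandlers(
    tryCatch(.composePanelImpl(record, config, panelId),
             error = function(e) stop("record '", record@id, "': ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      warning("record '", record@id, "': ", conditionMessage(w),
              call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

.composePanelImpl <- function(record, config, panelId) {
  config <- .mergeConfig(config, record@config)
  seq <- tokenizeSmiles(record@smiles)
  checkStructure(seq)
  layout <- buildAtomLayout(record@smiles)
  scoreless <- !length(record@scores)
  scored <- if (scoreless) attachScores(seq, rep(0, nTokens(seq))) else
    attachScores(seq, record@scores)
  domain <- if (length(config@domain)) config@domain else
    if (scoreless) c(-1, 1) else defaultDomain(scored)
  geo <- config@geometry
  nt <- nTokens(seq)
  barBlockW <- nt * geo$barWidth
  innerW <- max(geo$molWidth, barBlockW)
  width <- innerW + 2 * geo$pad
  barBlockH <- geo$barHeight + 2.6 * geo$fontSize
  tableH <- if (length(record@attributes))
    (length(record@attributes) + 0.5) * geo$tableRowHeight else 0
  height <- geo$molHeight + barBlockH + tableH + 3 * geo$pad

  hover <- exportHoverMap(seq, layout)
  hoverJson <- as.character(jsonlite::toJSON(hover, auto_unbox = TRUE))

  molX <- geo$pad + (innerW - geo$molWidth) / 2
  barX <- geo$pad + (innerW - barBlockW) / 2
  barY <- geo$pad + geo$molHeight + geo$pad
  tabY <- barY + barBlockH + geo$pad / 2

  parts <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s" ',
                   'class="smivis-panel" data-id="%s" data-hovermap=\'%s\'>'),
            .fmt(width), .fmt(height), .fmt(width), .fmt(height),
            .escapeXml(record@id),
            gsub("'", "&apos;", hoverJson, fixed = TRUE)),
    sprintf('<rect width="%s" height="%s" fill="#FFFFFF"/>',
            .fmt(width), .fmt(height)),
    sprintf('<g transform="translate(%s,%s)">', .fmt(molX), .fmt(geo$pad)),
    renderMoleculePanel(layout, scored, config, domain, panelId),
    "</g>",
    sprintf('<g transform="translate(%s,%s)">', .fmt(barX), .fmt(barY)),
    renderBarChart(scored, config, domain),
    "</g>")
  tab <- renderAttributeTable(record@attributes, config)
  if (nzchar(tab))
    parts <- c(parts,
               sprintf('<g transform="translate(%s,%s)">', .fmt(barX),
                       .fmt(tabY)),
               tab, "</g>")
  paste(c(parts, "</svg>"), collapse = "\n")
}

.GALLERY_CSS <- paste(
  "body{font-family:sans-serif;background:#FAFAFA;margin:16px;}",
  ".smivis-gallery{display:flex;flex-wrap:wrap;gap:16px;}",
  ".smivis-cell{background:#FFFFFF;border:1px solid #DDDDDD;padding:8px;}",
  ".tok.hl rect{stroke:#000000;stroke-width:1.5;}",
  ".tok.hl text{font-weight:bold;}",
  sep = "\n")

# hover behavior replayed from the precomputed map: no decisions are made
# in the browser beyond class toggling
.GALLERY_JS <- paste(
  "document.querySelectorAll('.smivis-panel').forEach(function(svg){",
  "  var map = JSON.parse(svg.getAttribute('data-hovermap'));",
  "  var toks = svg.querySelectorAll('.tok');",
  "  var hits = svg.querySelectorAll('.atomhit');",
  "  function ring(a, extra){",
  "    var hit = svg.querySelector('.atomhit[data-atom=\"'+a+'\"]');",
  "    if(!hit) return;",
  "    ['#FFD700', hit.getAttribute('data-signcolor')].forEach(function(c,k){",
  "      var n = document.createElementNS(svg.namespaceURI,'circle');",
  "      n.setAttribute('cx', hit.getAttribute('cx'));",
  "      n.setAttribute('cy', hit.getAttribute('cy'));",
  "      n.setAttribute('r', String(Number(hit.getAttribute('r'))+2+4*k));",
  "      n.setAttribute('fill','none');",
  "      n.setAttribute('stroke', k ? c : '#FFD700');",
  "      n.setAttribute('stroke-width','2.5');",
  "      n.setAttribute('class','hoverring');",
  "      hit.parentNode.appendChild(n);",
  "    });",
  "  }",
  "  function clear(){",
  "    svg.querySelectorAll('.hoverring').forEach(function(n){n.remove();});",
  "    toks.forEach(function(t){t.classList.remove('hl');});",
  "  }",
  "  toks.forEach(function(t){",
  "    var i = Number(t.getAttribute('data-token'));",
  "    t.addEventListener('mouseenter', function(){",
  "      clear();",
  "      var e = map.tokens[i-1];",
  "      e.tokens.forEach(function(j){toks[j-1].classList.add('hl');});",
  "      e.atoms.forEach(ring);",
  "    });",
  "    t.addEventListener('mouseleave', clear);",
  "  });",
  "  hits.forEach(function(hdot){",
  "    var a = Number(hdot.getAttribute('data-atom'));",
  "    hdot.addEventListener('mouseenter', function(){",
  "      clear();",
  "      var j = Array.isArray(map.atoms) ? map.atoms[a-1] : map.atoms;",
  "      toks[j-1].classList.add('hl');",
  "      ring(a);",
  "    });",
  "    hdot.addEventListener('mouseleave', clear);",
  "  });",
  "});",
  sep = "\n")

#' Render a multi-molecule HTML gallery
#'
#' Composes one panel per record and embeds them side by side in a single
#' self-contained HTML document (no external references). Hover behavior
#' -- token/substructure highlighting with a contrasting highlight ring
#' plus a sign-colored ring -- is replayed by a small static script from
#' the hover maps precomputed into each panel.
#'
#' @param records non-empty list of [SmilesRecord-class] objects.
#' @param config gallery-level [PanelConfig-class]; per-record overrides
#'   apply on top.
#' @param title document title.
#' @return character scalar: an HTML5 document.
#' @export
renderGallery <- function(records, config = panelConfig(),
                          title = "smivis gallery") {
  if (is(records, "SmilesRecord")) records <- list(records)
  if (!is.list(records) || !length(records))
    stop("'records' must be a non-empty list of SmilesRecord objects",
         call. = FALSE)
  panels <- vapply(seq_along(records), function(i) {
    composePanel(records[[i]], config, panelId = sprintf("p%d", i))
  }, character(1))
  cells <- sprintf('<div class="smivis-cell">\n%s\n</div>', panels)
  paste(c("<!DOCTYPE html>",
          '<html lang="en"><head><meta charset="utf-8"/>',
          sprintf("<title>%s</title>", .escapeXml(title)),
          "<style>", .GALLERY_CSS, "</style>",
          "</head><body>",
          sprintf("<h1>%s</h1>", .escapeXml(title)),
          '<div class="smivis-gallery">',
          cells,
          "</div>",
          "<script>", .GALLERY_JS, "</script>",
          "</body></html>"), collapse = "\n")
}
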