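# Panel configuration: layered defaults < per-record override < CLI flags.

.DEFAULT_GEOMETRY <- list(
  molWidth = 300, molHeight = 240,   # molecule viewport, drawing units
  barWidth = 16,                     # horizontal room per token
  barHeight = 90,                    # full-height bar
  barGap = 3,                        # gap between adjacent bars
  pad = 12,                          # outer padding
  fontSize = 11,                     # token and label text
  tableRowHeight = 16)               # attribute-table line height

#' Construct a panel configuration
#'
#' Bundles everything that controls how one panel looks: the diverging
#' palette, the colormap domain, the threshold list, label/atom-color
#' flags and drawing geometry. All geometry values are in SVG user units.
#'
#' @param palette built-in palette name (one of
#'   \code{names(divergingPalettes())}), a custom odd-length diverging
#'   color vector with a neutral middle, or the path to a JSON file
#'   holding such a color list.
#' @param domain \code{NULL} for the per-molecule automatic symmetric
#'   domain (see [defaultDomain()]), or \code{c(min, max)} /
#'   \code{c(min, 0, max)} with \code{min < 0 < max}. Scores beyond the
#'   domain clamp to full bar height and the strongest color.
#' @param thresholds ascending fractions in [0, 1]; atoms whose |score|
#'   reaches \code{threshold * max(domain)} are highlighted on the diagram
#'   and a guide line is drawn on the bar chart. Empty (the default) means
#'   no diagram highlight and guide lines at 0.5 and 1.
#' @param showScoreLabels draw each atom's score (2 decimals) on the
#'   diagram.
#' @param blackAtoms draw atom glyphs black instead of element-colored.
#' @param signOnly collapse the domain to (-1e-5, 1e-5) so every nonzero
#'   score renders at full strength and only its sign is visible.
#' @param geometry named list merged over the geometry defaults.
#' @return a [PanelConfig-class] object.
#' @examples
#' panelConfig(palette = "PiYG", thresholds = c(0.5, 0.75))
#' @export
panelConfig <- function(palette = "RdBu", domain = NULL,
                        thresholds = numeric(0), showScoreLabels = FALSE,
                        blackAtoms = FALSE, signOnly = FALSE,
                        geometry = list()) {
  pal <- .resolvePalette(palette)
  if (isTRUE(signOnly)) domain <- c(-1e-5, 1e-5)
  dom <- if (is.null(domain) || !length(domain)) numeric(0) else
    .asDomain(domain)
  th <- sort(as.numeric(thresholds))
  geo <- utils::modifyList(.DEFAULT_GEOMETRY, geometry)
  new("PanelConfig", palette = as.character(pal),
      paletteName = attr(pal, "name"), domain = dom, thresholds = th,
      showScoreLabels = isTRUE(showScoreLabels),
      blackAtoms = isTRUE(blackAtoms), geometry = geo)
}

# per-record override: a named list of panelConfig() arguments
.mergeConfig <- function(config, override) {
  if (!length(override)) return(config)
  base <- list(
    palette = if (config@paletteName == "custom") config@palette else
      config@paletteName,
    domain = config@domain, thresholds = config@thresholds,
    showScoreLabels = config@showScoreLabels, blackAtoms = config@blackAtoms,
    geometry = config@geometry)
  known <- c(names(base), "signOnly")
  bad <- setdiff(names(override), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(panelConfig, utils::modifyList(base, override))
}

#' @describeIn PanelConfig-class compact display.
#' @param object a \code{PanelConfig} object.
#' @export
setMethod("show", "PanelConfig", function(object) {
  cat(class(object), "palette=", object@paletteName,
      "domain=", if (length(object@domain))
        paste0("(", object@domain[1], ", ", object@domain[2], ")") else "auto",
      "thresholds=[", paste(object@thresholds, collapse = ", "), "]\n")
})
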