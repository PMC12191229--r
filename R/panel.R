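#' @useDynLib imcpheno, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.compartments <- c("nuclear", "membrane", "dna", "excluded")

#' Construct a marker panel
#'
#' A marker panel maps each antibody/metal channel of a multiplexed imaging
#' mass cytometry (IMC) acquisition to the cellular compartment in which the
#' marker is expressed.  The compartment drives composite-image construction
#' for segmentation: `"dna"` channels (iridium intercalator) mark nuclei,
#' `"nuclear"` and `"membrane"` markers enter the nuclear and membrane
#' composites respectively, and `"excluded"` channels are quantified but kept
#' out of all composites.
#'
#' @param marker Character vector of unique marker names.
#' @param metal Character vector of metal-tag labels (isotope names); may be
#'   `NA`.
#' @param compartment Character vector; each entry one of `"nuclear"`,
#'   `"membrane"`, `"dna"`, `"excluded"`.
#' @return A `marker_panel` data frame with columns `marker`, `metal`,
#'   `compartment`, in the given order.
#' @examples
#' marker_panel(c("DNA1", "CD44"), c("191Ir", "161Dy"), c("dna", "membrane"))
#' @export
marker_panel <- function(marker, metal = NA_character_, compartment) {
  panel <- data.frame(
    marker = as.character(marker),
    metal = rep_len(as.character(metal), length(marker)),
    compartment = as.character(compartment),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("marker_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' Validate a marker panel
#'
#' Checks uniqueness of marker names, membership of every compartment token
#' in the closed set, and presence of at least one DNA channel.
#'
#' @param panel A `marker_panel` or a data frame with columns `marker`,
#'   `metal`, `compartment`.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  required <- c("marker", "metal", "compartment")
  missing <- setdiff(required, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  dup <- panel$marker[duplicated(panel$marker)]
  if (length(dup))
    stop("duplicated marker name(s) in panel: ", paste(unique(dup), collapse = ", "))
  bad <- !panel$compartment %in% .compartments
  if (any(bad))
    stop("unknown compartment '", panel$compartment[which(bad)[1]],
         "' in panel row ", which(bad)[1],
         " (marker '", panel$marker[which(bad)[1]], "')")
  if (!any(panel$compartment == "dna"))
    stop("panel must contain at least one 'dna' channel")
  invisible(panel)
}

#' Default 23-marker mouse tumor-immune panel
#'
#' A panel typical of mouse tumor-microenvironment IMC studies: two iridium
#' DNA intercalator channels, nuclear-compartment markers (Ki67, Ly6G, B220,
#' F4/80, S100A8, S100A9, FoxP3) and membrane/cytoplasmic markers (T-cell,
#' myeloid, tumor/EMT and checkpoint markers).  Metal tags are illustrative.
#'
#' @return A `marker_panel` with 23 entries.
#' @export
default_panel <- function() {
  marker_panel(
    marker = c(
      "DNA1", "DNA2",
      "Ki67", "Ly6G", "B220", "F4/80", "S100A8", "S100A9", "FoxP3",
      "CD4", "CD8a", "CD11b", "CD11c", "CD44", "CD62L", "CD68", "CD127",
      "Ly6C", "CD86", "CD163", "PanCK", "Vimentin", "PD-L1", "PD-1"
    )[1:23],
    metal = c(
      "191Ir", "193Ir",
      "168Er", "141Pr", "176Yb", "146Nd", "160Gd", "161Dy", "165Ho",
      "145Nd", "153Eu", "148Nd", "142Nd", "171Yb", "149Sm", "159Tb", "150Nd",
      "154Sm", "156Gd", "147Sm", "144Nd", "163Dy", "175Lu", "152Sm"
    )[1:23],
    compartment = c(
      "dna", "dna",
      rep("nuclear", 7),
      rep("membrane", 14)
    )[1:23]
  )
}

#' Marker names belonging to a set of compartments
#'
#' @param panel A `marker_panel`.
#' @param compartment Character vector of compartment tokens.
#' @return Character vector of marker names, in panel order.
#' @export
panel_markers <- function(panel, compartment = .compartments) {
  validate_panel(panel)
  panel$marker[panel$compartment %in% compartment]
}

#' Read a marker panel from CSV
#'
#' Expects a header with columns `marker`, `metal`, `compartment`.  Row order
#' is preserved; duplicated marker names and unknown compartment tokens are
#' rejected with an error naming the offending entry.
#'
#' @param path Path to a CSV file.
#' @return A `marker_panel`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("marker", "metal", "compartment")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("panel CSV is missing column(s): ", paste(missing, collapse = ", "))
  marker_panel(tab$marker, tab$metal, tab$compartment)
}

#' Write a marker panel to CSV
#'
#' @param panel A `marker_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(as.data.frame(panel)[, c("marker", "metal", "compartment")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel with", nrow(x), "markers (",
      sum(x$compartment == "dna"), "dna,",
      sum(x$compartment == "nuclear"), "nuclear,",
      sum(x$compartment == "membrane"), "membrane,",
      sum(x$compartment == "excluded"), "excluded )\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
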