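#' @import methods
NULL

#' Specification of a synthetic microscopy field
#'
#' Parameters controlling the synthetic imaging generator: geometry of cells
#' and nuclei, the distribution of condensed foci (stress granules) per cell,
#' the mean photon levels of each compartment, additive read noise, and the
#' live-imaging time axis with the onset/offset of condensation.
#'
#' @slot imageSize integer of length 2, image height and width in pixels.
#' @slot nCells number of cells to place in the field.
#' @slot nucleusRadius numeric (mean, sd) nuclear radius in pixels.
#' @slot cellRadius numeric (mean, sd) whole-cell radius in pixels.
#' @slot fociPerCell Poisson mean of the per-cell focus count.
#' @slot focusRadius numeric (mean, sd) focus semi-major axis in pixels.
#' @slot focusAxisRatio minor/major semi-axis ratio in (0, 1]; controls the
#'   eccentricity sqrt(1 - ratio^2) of rendered foci.
#' @slot intensities named numeric with elements \code{background},
#'   \code{cytoplasm}, \code{nucleus}, \code{focus}: mean photon levels.
#' @slot noiseSd standard deviation of additive Gaussian read noise.
#' @slot timepoints numeric vector of acquisition times in minutes.
#' @slot condensationOnset time (minutes) at which foci first appear.
#' @slot condensationOffset time (minutes) after which foci have disassembled.
#'
#' @seealso [fieldSpec()] for the user constructor with realistic defaults,
#'   [generateField()], [generateTimecourse()].
#' @exportClass FieldSpec
setClass("FieldSpec",
  representation(
    imageSize = "integer",
    nCells = "integer",
    nucleusRadius = "numeric",
    cellRadius = "numeric",
    fociPerCell = "numeric",
    focusRadius = "numeric",
    focusAxisRatio = "numeric",
    intensities = "numeric",
    noiseSd = "numeric",
    timepoints = "numeric",
    condensationOnset = "numeric",
    condensationOffset = "numeric",
    fociExact = "logical"
  )
)

setValidity("FieldSpec", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be two integers >= 16")
  if (object@nCells < 0L)
    msg <- c(msg, "nCells must be >= 0")
  for (s in c("nucleusRadius", "cellRadius", "focusRadius")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] <= 0 || v[2] < 0)
      msg <- c(msg, sprintf("%s must be (mean > 0, sd >= 0)", s))
  }
  if (object@fociPerCell < 0)
    msg <- c(msg, "fociPerCell must be >= 0")
  if (object@focusAxisRatio <= 0 || object@focusAxisRatio > 1)
    msg <- c(msg, "focusAxisRatio must lie in (0, 1]")
  need <- c("background", "cytoplasm", "nucleus", "focus")
  if (!all(need %in% names(object@intensities)) ||
      any(object@intensities[need] < 0))
    msg <- c(msg, "intensities must contain nonnegative background/cytoplasm/nucleus/focus")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldSpec
#'
#' Defaults emulate a 20x widefield/confocal field of adherent U-2OS-like
#' cells: ~35 px cell radius, ~12 px nuclei, a handful of micron-scale
#' near-circular granules per stressed cell, bright puncta over a dimmer
#' cytoplasm, and a 10 h time axis sampled every 30 min with condensation
#' between 30 and 150 min.
#'
#' @param imageSize height and width in pixels.
#' @param nCells number of cells.
#' @param nucleusRadius,cellRadius,focusRadius (mean, sd) in pixels.
#' @param fociPerCell Poisson mean focus count per cell.
#' @param focusAxisRatio minor/major axis ratio in (0, 1].
#' @param intensities named photon levels (background, cytoplasm, nucleus,
#'   focus). The focus level is an increment added on top of the cytoplasm.
#' @param noiseSd Gaussian read-noise sd in photon units.
#' @param timepoints acquisition times, minutes.
#' @param condensationOnset,condensationOffset minutes bounding the window in
#'   which foci are present.
#' @param fociExact if TRUE every cell gets exactly \code{round(fociPerCell)}
#'   foci instead of a Poisson draw (useful for controlled fixtures).
#' @return A validated [FieldSpec-class] object.
#' @examples
#' spec <- fieldSpec(nCells = 5L)
#' spec
#' @export
fieldSpec <- function(imageSize = c(512L, 512L),
                      nCells = 20L,
                      nucleusRadius = c(12, 1.5),
                      cellRadius = c(35, 3),
                      fociPerCell = 3,
                      focusRadius = c(3, 0.4),
                      focusAxisRatio = 0.85,
                      intensities = c(background = 100, cytoplasm = 500,
                                      nucleus = 800, focus = 1500),
                      noiseSd = 25,
                      timepoints = seq(0, 600, by = 30),
                      condensationOnset = 30,
                      condensationOffset = 150,
                      fociExact = FALSE) {
  new("FieldSpec",
      imageSize = as.integer(imageSize), nCells = as.integer(nCells),
      nucleusRadius = as.numeric(nucleusRadius),
      cellRadius = as.numeric(cellRadius),
      fociPerCell = as.numeric(fociPerCell),
      focusRadius = as.numeric(focusRadius),
      focusAxisRatio = as.numeric(focusAxisRatio),
      intensities = intensities, noiseSd = as.numeric(noiseSd),
      timepoints = as.numeric(timepoints),
      condensationOnset = as.numeric(condensationOnset),
      condensationOffset = as.numeric(condensationOffset),
      fociExact = isTRUE(fociExact))
}

#' A rendered synthetic field with ground truth
#'
#' Two co-registered channels (nuclear stain and reporter) plus the exact
#' geometry tables used to render them. Truth areas are rasterized pixel
#' counts, so downstream measurements can be compared pixel-for-pixel.
#'
#' @slot nuclearChannel,reporterChannel numeric matrices (row, col), photon
#'   units.
#' @slot truthCells data.frame: cell_id, row, col, radius, nucleus_radius,
#'   reporter_mean, foci_count.
#' @slot truthFoci data.frame: focus_id, cell_id, row, col, a, b, theta,
#'   area, eccentricity.
#' @slot timepoint acquisition time in minutes.
#' @exportClass SyntheticField
setClass("SyntheticField",
  representation(
    nuclearChannel = "matrix",
    reporterChannel = "matrix",
    truthCells = "data.frame",
    truthFoci = "data.frame",
    timepoint = "numeric"
  )
)

setValidity("SyntheticField", function(object) {
  msg <- character()
  if (!identical(dim(object@nuclearChannel), dim(object@reporterChannel)))
    msg <- c(msg, "channels must share dimensions")
  if (nrow(object@truthFoci) &&
      !all(object@truthFoci$cell_id %in% object@truthCells$cell_id))
    msg <- c(msg, "every truth focus must belong to a truth cell")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticField", function(object) {
  d <- dim(object@nuclearChannel)
  cat(sprintf("SyntheticField %d x %d px, t = %g min\n", d[1], d[2],
              object@timepoint))
  cat(sprintf("  %d cells, %d foci\n", nrow(object@truthCells),
              nrow(object@truthFoci)))
})

#' @describeIn SyntheticField-class ground-truth cell table.
#' @param x a \code{SyntheticField}.
#' @export
truthCells <- function(x) x@truthCells

#' @describeIn SyntheticField-class ground-truth focus table.
#' @export
truthFoci <- function(x) x@truthFoci

#' @describeIn SyntheticField-class nuclear-channel intensity matrix.
#' @export
nuclearChannel <- function(x) x@nuclearChannel

#' @describeIn SyntheticField-class reporter-channel intensity matrix.
#' @export
reporterChannel <- function(x) x@reporterChannel

#' Labeled segmentation mask
#'
#' Integer label image where 0 is background and objects are labeled
#' contiguously 1..K, with the object kind recorded (nuclei, cells or foci).
#'
#' @slot labels integer matrix; 0 = background.
#' @slot kind one of "nuclei", "cells", "foci".
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "matrix", kind = "character")
)

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!object@kind %in% c("nuclei", "cells", "foci"))
    msg <- c(msg, "kind must be one of nuclei/cells/foci")
  labs <- object@labels
  if (any(labs < 0))
    msg <- c(msg, "labels must be nonnegative")
  u <- sort(unique(as.integer(labs[labs > 0])))
  if (length(u) && !identical(u, seq_len(max(u))))
    msg <- c(msg, "labels must be contiguous 1..K")
  if (length(msg)) msg else TRUE
})

labelMask <- function(labels, kind) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, kind = kind)
}

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask(%s) %d x %d px, %d objects\n", object@kind,
              nrow(object@labels), ncol(object@labels),
              nObjects(object)))
})

#' @describeIn LabelMask-class the integer label matrix.
#' @param x a \code{LabelMask}.
#' @export
labels2d <- function(x) x@labels

#' @describeIn LabelMask-class the number of labeled objects.
#' @export
nObjects <- function(x) max(0L, as.integer(x@labels))

#' @describeIn LabelMask-class the mask kind ("nuclei", "cells" or "foci").
#' @export
maskKind <- function(x) x@kind
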