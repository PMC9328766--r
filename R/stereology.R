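## Optical fractionator: a design-based estimate of total cell number
## from objects counted in systematically sampled 3D dissectors,
## N-hat = sum(Q-) * (1/ssf) * (1/asf) * (1/tsf), where the section
## sampling fraction ssf = 1/sectionInterval, the area sampling
## fraction asf = frameArea / (gridStepX * gridStepY), and the
## thickness sampling fraction tsf = dissectorHeight / sectionThickness.

#' Construct an optical fractionator sampling design
#'
#' Defaults mirror a standard midbrain dopamine-neuron design: every
#' sixth section, a 60 x 60 um^2 counting frame on a 150 x 150 um grid,
#' and a 10 um optical dissector placed 2 um below the section top. The
#' mounted section thickness is measured at the microscope and must be
#' supplied; the guard zone is metadata and does not enter the
#' estimator.
#'
#' @param sectionInterval sections between sampled sections (default 6).
#' @param frameArea counting frame area, um^2 (default 3600 = 60 x 60).
#' @param gridStep numeric(2), (x, y) sampling grid step in um
#'   (default c(150, 150)).
#' @param dissectorHeight optical dissector height, um (default 10).
#' @param meanSectionThickness mean mounted section thickness, um.
#' @param guardZone guard zone from the section top, um (default 2).
#' @return A [FractionatorDesign-class].
#' @export
fractionatorDesign <- function(sectionInterval = 6, frameArea = 3600,
                               gridStep = c(150, 150), dissectorHeight = 10,
                               meanSectionThickness, guardZone = 2) {
  new("FractionatorDesign", sectionInterval = sectionInterval,
      frameArea = frameArea, gridStep = as.numeric(gridStep),
      dissectorHeight = dissectorHeight,
      meanSectionThickness = meanSectionThickness, guardZone = guardZone)
}

#' Optical fractionator estimate of total cell number
#'
#' For each region, `N = rawCount * sectionInterval *
#' (gridStepX * gridStepY / frameArea) *
#' (meanSectionThickness / dissectorHeight)`; region estimates are
#' summed into a combined total (the estimator is linear in the
#' counts).
#'
#' @param counts a `data.frame` with columns `region` (e.g. `"SNc"`,
#'   `"VTA"`) and `rawCount` (sum of objects counted in dissectors,
#'   non-negative integers), or a named numeric vector of counts.
#' @param design a [FractionatorDesign-class].
#' @return A `data.frame` with one row per region plus a `"combined"`
#'   row, columns `region`, `rawCount`, `estimate`.
#' @examples
#' d <- fractionatorDesign(meanSectionThickness = 20)
#' estimateTotal(c(SNc = 40, VTA = 60), d)
#' @export
estimateTotal <- function(counts, design) {
  stopifnot(is(design, "FractionatorDesign"))
  validObject(design)
  if (is.numeric(counts)) {
    counts <- data.frame(region = names(counts), rawCount = as.numeric(counts))
  }
  if (!all(c("region", "rawCount") %in% names(counts)))
    stop("counts must supply columns 'region' and 'rawCount'")
  if (any(counts$rawCount < 0) || any(counts$rawCount != round(counts$rawCount)))
    stop("rawCount must be non-negative integers")
  invSSF <- design@sectionInterval
  invASF <- prod(design@gridStep) / design@frameArea
  invTSF <- design@meanSectionThickness / design@dissectorHeight
  est <- counts$rawCount * invSSF * invASF * invTSF
  out <- data.frame(region = as.character(counts$region),
                    rawCount = counts$rawCount, estimate = est)
  rbind(out, data.frame(region = "combined",
                        rawCount = sum(counts$rawCount),
                        estimate = sum(est)))
}
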