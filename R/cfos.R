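#' Estimate background fluorescence from image ROIs
#'
#' Mean and SD of pixel intensities over the union of rectangular ROIs.
#'
#' @param image numeric matrix (AU).
#' @param rois list of ROIs, each `c(x0, x1, y0, y1)` in pixel indices
#'   (1-based, inclusive).
#' @return object of class `background_estimate`: `mean`, `sd`, `n_pixels`.
#' @export
estimate_background <- function(image, rois) {
  if (length(rois) == 0L) stop_invalid("at least one background ROI required")
  dm <- dim(image)
  sel <- matrix(FALSE, dm[1], dm[2])
  for (r in rois) {
    if (length(r) != 4L) stop_invalid("each ROI must be c(x0, x1, y0, y1)")
    if (r[1] < 1 || r[3] < 1 || r[2] > dm[1] || r[4] > dm[2] ||
        r[1] > r[2] || r[3] > r[4]) {
      stop_invalid("ROI outside image bounds")
    }
    sel[r[1]:r[2], r[3]:r[4]] <- TRUE
  }
  px <- image[sel]
  structure(list(mean = mean(px), sd = stats::sd(px), n_pixels = length(px)),
            class = "background_estimate")
}

#' Classify a cell as cfos-positive
#'
#' Two class-specific rules: pyramidal cells are cfos+ when their mean
#' fluorescence exceeds `pyr_factor` (default 1.2) times the background
#' mean; chandelier cells are cfos+ when it exceeds the background mean
#' plus `chc_k` (default 2) background standard deviations. The
#' inequality is strict: a cell sitting exactly at threshold is negative.
#'
#' @param fluorescence mean cfos fluorescence of the cell, AU (>= 0).
#' @param cell_class `"pyramidal"` or `"chc"`.
#' @param background a [estimate_background()] result (or a list with
#'   `mean` and `sd`).
#' @param pyr_factor multiplicative threshold for pyramidal cells.
#' @param chc_k number of background SDs for chandelier cells.
#' @return `"positive"` or `"negative"`.
#' @export
#' @examples
#' bg <- list(mean = 100, sd = 10)
#' classify_cfos(125, "pyramidal", bg)  # "positive" (> 1.2 x 100)
#' classify_cfos(115, "chc", bg)        # "negative" (not > 100 + 2 x 10)
classify_cfos <- function(fluorescence, cell_class, background,
                          pyr_factor = 1.2, chc_k = 2) {
  if (fluorescence < 0) stop_invalid("fluorescence must be >= 0")
  if (background$sd < 0) stop_invalid("background sd must be >= 0")
  thr <- switch(cell_class,
    pyramidal = {
      if (background$mean <= 0) stop_invalid("pyramidal rule needs background mean > 0")
      pyr_factor * background$mean
    },
    chc = background$mean + chc_k * background$sd,
    stop_invalid("unknown cell class: ", cell_class)
  )
  if (fluorescence > thr) "positive" else "negative"
}
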