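# Nucleus segmentation: standard smoothing/threshold/labeling plumbing on
# top of EBImage.

#' Segment nuclei in a single frame
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, and connected
#' component labeling; components smaller than `min_area` are dropped.
#'
#' @param frame 2-D numeric matrix (one frame, one channel).
#' @param min_area minimum component size in pixels.
#' @param sigma smoothing sigma in pixels.
#' @return integer label matrix (0 = background); all-zero with a warning
#'   when no component reaches `min_area`.
#' @export
segment_nuclei <- function(frame, min_area = 200L, sigma = 2) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame)
  if (diff(rng) == 0) {
    warnf("constant image: no nuclei found")
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  norm <- (frame - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  bin <- EBImage::fillHull(sm > th)
  lab <- EBImage::bwlabel(bin)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) {
    warnf("no connected component reaches min_area = %d px", min_area)
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  out <- matrix(0L, nrow(frame), ncol(frame))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}
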