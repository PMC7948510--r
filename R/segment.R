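#' Segment nuclei from a DAPI channel
#'
#' Isolates nuclei from a nuclear-stain image by (i) global Otsu
#' binarization, (ii) hole filling and removal of connected components
#' smaller than `min_area`, and optionally (iii) a distance-transform
#' watershed that splits touching nuclei. Connected components use the
#' 4-connectivity convention of EBImage's labeller; for disk-shaped nuclei
#' this is indistinguishable from 8-connectivity.
#'
#' @param dapi numeric matrix of DAPI intensities (rows x columns), as
#'   produced by [simulate_nuclei_field()] or [read_channel_tiff()].
#' @param min_area minimum component area in pixels; smaller objects are
#'   treated as debris and removed.
#' @param split_touching if `TRUE`, apply a watershed on the distance
#'   transform of the binary mask to split touching nuclei. Off by default:
#'   with well-separated nuclei it can only oversegment.
#' @param bit_depth bit depth of the intensity scale (8 or 16).
#' @return An object of class `"nucleus_label_map"`: a list with `labels`
#'   (integer matrix; 0 = background, nuclei labelled 1..n contiguously) and
#'   `n_nuclei`. An image that binarizes to all background yields
#'   `n_nuclei = 0`, which is not an error here but is rejected by
#'   downstream scoring.
#' @export
#' @examples
#' fld <- simulate_nuclei_field(n_nuclei = 10, seed = 1)
#' seg <- segment_nuclei(fld$dapi)
#' seg$n_nuclei
segment_nuclei <- function(dapi, min_area = 30, split_touching = FALSE,
                           bit_depth = 16) {
  stopifnot(is.matrix(dapi), length(dapi) > 0, bit_depth %in% c(8L, 16L))
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                   n_nuclei = 0L),
              class = "nucleus_label_map")
  }
  if (diff(range(dapi)) == 0) return(empty())

  scaled <- dapi / (2^bit_depth - 1)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                       levels = 2^bit_depth)
  mask <- EBImage::fillHull(EBImage::Image(scaled > thr))
  if (split_touching) {
    lab <- EBImage::watershed(EBImage::distmap(mask))
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(dapi), ncol(dapi))
  if (max(lab) == 0L) return(empty())

  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(empty())
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  structure(list(labels = lab, n_nuclei = length(keep)),
            class = "nucleus_label_map")
}

#' Assign marker pixels to the nuclei they overlap
#'
#' Only marker pixels lying on a labelled nucleus are considered; background
#' pixels (label 0) are discarded. Each overlapping pixel belongs to the
#' nucleus it overlaps.
#'
#' @param marker numeric matrix of marker-channel intensities.
#' @param labels a `"nucleus_label_map"` from [segment_nuclei()], or an
#'   integer label matrix.
#' @return A named list, one numeric vector of marker intensities per
#'   nucleus label (names are the labels). Empty list if no nucleus.
#' @export
mask_marker_to_nuclei <- function(marker, labels) {
  lab <- label_matrix(labels)
  if (!identical(dim(marker), dim(lab)))
    stop("marker and label map have different dimensions")
  fg <- lab > 0L
  split(marker[fg], lab[fg])
}

#' Mean marker intensity per nucleus
#'
#' Arithmetic mean of the marker intensities over each nucleus's overlap
#' pixels, ordered by nucleus id. A labelled nucleus with no assigned pixels
#' (possible only with a hand-edited label map) gets mean 0 with a warning.
#'
#' @inheritParams mask_marker_to_nuclei
#' @return A data frame with columns `nucleus_id`, `n_pixels`, `mean_raw`.
#' @export
per_cell_mean_intensity <- function(marker, labels) {
  lab <- label_matrix(labels)
  n <- max(lab, 0L)
  if (n == 0L) stop("label map contains no nuclei")
  groups <- mask_marker_to_nuclei(marker, labels)
  ids <- seq_len(n)
  n_pixels <- integer(n)
  mean_raw <- numeric(n)
  present <- as.integer(names(groups))
  n_pixels[present] <- lengths(groups)
  mean_raw[present] <- vapply(groups, mean, numeric(1))
  if (any(n_pixels == 0L)) {
    warning("nuclei with no assigned pixels get mean_raw = 0: ",
            paste(ids[n_pixels == 0L], collapse = ", "))
  }
  data.frame(nucleus_id = ids, n_pixels = n_pixels, mean_raw = mean_raw)
}

# Accept a nucleus_label_map or a bare integer matrix.
label_matrix <- function(labels) {
  if (inherits(labels, "nucleus_label_map")) labels$labels
  else if (is.matrix(labels)) labels
  else stop("labels must be a nucleus_label_map or an integer matrix")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  cat(sprintf("nucleus_label_map: %d x %d px, %d nuclei\n",
              nrow(x$labels), ncol(x$labels), x$n_nuclei))
  invisible(x)
}
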