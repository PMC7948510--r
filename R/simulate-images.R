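#' Simulate a two-channel immunofluorescence field with known ground truth
#'
#' Generates a DAPI (nuclear) channel and a marker channel for a field of
#' `n_nuclei` non-overlapping disk-shaped nuclei. A known fraction of nuclei
#' carries elevated marker signal (`marker_fg_level`) while the rest, and the
#' background, sit at `marker_bg_level`. Both channels receive i.i.d. Gaussian
#' noise and are clipped to the valid intensity range of the stated bit depth.
#' The returned truth record makes downstream segmentation and
#' fraction-positive scoring testable against a known answer.
#'
#' Nucleus centers are placed by rejection sampling: candidate centers are
#' drawn uniformly inside the frame (with a margin so every disk lies fully
#' inside) and accepted only if farther than `2 * nucleus_radius + min_gap`
#' from every accepted center, so nuclei never overlap and, with the default
#' gap, never share adjacent pixels (adjacent disks would otherwise fuse into
#' one connected component and defeat count ground truth). Nuclei are hard
#' disks with constant interior intensity; there is no point-spread blurring.
#'
#' @param n_nuclei number of nuclei to place (0 allowed: the field is pure
#'   background noise and `truth$frac_positive` is `NaN`).
#' @param frac_positive requested fraction of marker-positive nuclei in
#'   `[0, 1]`. The realized fraction is `round(frac_positive * n_nuclei) /
#'   n_nuclei` and is what the truth record stores.
#' @param width,height frame size in pixels.
#' @param nucleus_radius nucleus radius in pixels.
#' @param dapi_level DAPI intensity inside nuclei (background is 0).
#' @param marker_fg_level marker intensity inside positive nuclei.
#' @param marker_bg_level marker intensity inside negative nuclei and in the
#'   background (models isotype-level nonspecific staining).
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units. Applied to both channels, then clipped to
#'   `[0, 2^bit_depth - 1]` (not wrapped).
#' @param bit_depth 8 or 16; sets the valid intensity range.
#' @param min_gap extra clearance in pixels between nucleus rims (centers
#'   are kept farther apart than `2 * nucleus_radius + min_gap`).
#' @param seed integer seed; identical parameter sets with identical seeds
#'   give bit-identical images.
#' @param max_tries total rejection-sampling attempts allowed before giving
#'   up on placing nuclei.
#'
#' @return An object of class `"nuclei_field"`: a list with numeric matrices
#'   `dapi` and `marker` (row = image row, column = image column) and `truth`,
#'   a list with `n_nuclei`, `positive_ids`, `frac_positive`, `centers`
#'   (n x 2 matrix of row/col coordinates), `nucleus_radius`, the intensity
#'   levels, `noise_sd`, `bit_depth` and `seed`.
#' @seealso [simulate_control_field()], [segment_nuclei()], [write_field()]
#' @export
#' @examples
#' fld <- simulate_nuclei_field(n_nuclei = 20, frac_positive = 0.5, seed = 1)
#' fld$truth$frac_positive
simulate_nuclei_field <- function(n_nuclei = 200, frac_positive = 0.5,
                                  width = 512, height = 512,
                                  nucleus_radius = 8,
                                  dapi_level = 30000,
                                  marker_fg_level = 20000,
                                  marker_bg_level = 2000,
                                  noise_sd = 800,
                                  bit_depth = 16,
                                  min_gap = 3,
                                  seed = 1,
                                  max_tries = 50000L) {
  stopifnot(n_nuclei >= 0, frac_positive >= 0, frac_positive <= 1,
            nucleus_radius >= 1, noise_sd >= 0, bit_depth %in% c(8L, 16L))
  max_int <- 2^bit_depth - 1
  if (any(c(dapi_level, marker_fg_level, marker_bg_level) > max_int))
    stop("intensity levels exceed the ", bit_depth, "-bit range")

  withr::with_seed(seed, {
    centers <- place_disks(n_nuclei, width, height, nucleus_radius,
                           min_gap, max_tries)
    n_pos <- if (n_nuclei > 0) as.integer(round(frac_positive * n_nuclei)) else 0L
    positive_ids <- if (n_pos > 0) sort(sample.int(n_nuclei, n_pos)) else integer(0)

    dapi <- matrix(0, nrow = height, ncol = width)
    marker <- matrix(marker_bg_level, nrow = height, ncol = width)
    if (n_nuclei > 0) {
      for (i in seq_len(n_nuclei)) {
        px <- disk_pixels(centers[i, 1], centers[i, 2], nucleus_radius,
                          height, width)
        dapi[px] <- dapi_level
        if (i %in% positive_ids) marker[px] <- marker_fg_level
      }
    }
    if (noise_sd > 0) {
      dapi <- dapi + matrix(stats::rnorm(height * width, 0, noise_sd),
                            height, width)
      marker <- marker + matrix(stats::rnorm(height * width, 0, noise_sd),
                                height, width)
    }
    dapi <- pmin(pmax(dapi, 0), max_int)
    marker <- pmin(pmax(marker, 0), max_int)

    truth <- list(
      n_nuclei = as.integer(n_nuclei),
      positive_ids = positive_ids,
      frac_positive = if (n_nuclei > 0) n_pos / n_nuclei else NaN,
      centers = centers,
      nucleus_radius = nucleus_radius,
      dapi_level = dapi_level,
      marker_fg_level = marker_fg_level,
      marker_bg_level = marker_bg_level,
      noise_sd = noise_sd,
      bit_depth = as.integer(bit_depth),
      seed = as.integer(seed)
    )
    structure(list(dapi = dapi, marker = marker, truth = truth),
              class = "nuclei_field")
  })
}

#' Simulate an isotype-control field
#'
#' Same generator as [simulate_nuclei_field()] with `frac_positive` forced to
#' zero: every nucleus carries only the nonspecific staining level of the
#' control antibody in the marker channel, emulating the isotype-control
#' image used to set the positivity threshold.
#'
#' The default `marker_bg_level` here (2600) is deliberately higher than the
#' experimental generator's negative background (2000): an isotype control is
#' chosen so that its nonspecific staining bounds true-negative signal from
#' above. This margin is what makes the threshold-at-control-average rule
#' identifiable — if the control staining equalled the negative-cell level
#' exactly, any symmetric noise would place about half the negative cells
#' above the control mean.
#'
#' @inheritParams simulate_nuclei_field
#' @param marker_bg_level nonspecific isotype staining level inside nuclei
#'   and in the background.
#' @param ... further arguments passed to [simulate_nuclei_field()]
#'   (`frac_positive` is not accepted).
#' @return A `"nuclei_field"` object with `truth$positive_ids` empty.
#' @export
simulate_control_field <- function(n_nuclei = 200, marker_bg_level = 2600,
                                   seed = 1, ...) {
  args <- list(...)
  if ("frac_positive" %in% names(args))
    stop("a control field has frac_positive = 0 by definition")
  do.call(simulate_nuclei_field,
          c(list(n_nuclei = n_nuclei, frac_positive = 0,
                 marker_bg_level = marker_bg_level, seed = seed), args))
}

# Rejection-sample n disk centers with pairwise distance > 2 * radius +
# min_gap and the whole disk inside the frame. Returns an n x 2 matrix of
# (row, col).
place_disks <- function(n, width, height, radius, min_gap, max_tries) {
  centers <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  if (n == 0) return(centers)
  margin <- radius + 1
  if (height - 2 * margin < 0 || width - 2 * margin < 0)
    stop("frame too small for nuclei of radius ", radius)
  centers <- matrix(NA_real_, nrow = n, ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  tries <- 0L
  min_d2 <- (2 * radius + min_gap)^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " non-overlapping nuclei of radius ",
           radius, " in a ", height, "x", width, " frame after ", max_tries,
           " tries: requested density too high")
    cand <- c(stats::runif(1, margin, height - margin),
              stats::runif(1, margin, width - margin))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) <= min_d2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Linear indices of pixels inside a disk, clipped to the frame.
disk_pixels <- function(r0, c0, radius, height, width) {
  rr <- max(1, floor(r0 - radius)):min(height, ceiling(r0 + radius))
  cc <- max(1, floor(c0 - radius)):min(width, ceiling(c0 + radius))
  inside <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= radius^2
  cbind(rep(rr, times = length(cc))[as.vector(inside)],
        rep(cc, each = length(rr))[as.vector(inside)])
}

#' @export
print.nuclei_field <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    "nuclei_field: %d x %d px, %d nuclei (radius %g px), frac_positive = %s, seed = %d\n",
    nrow(x$dapi), ncol(x$dapi), t$n_nuclei, t$nucleus_radius,
    format(t$frac_positive), t$seed))
  invisible(x)
}
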