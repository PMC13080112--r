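#' Generate a spherical EEG montage
#'
#' Builds a deterministic, approximately uniform electrode layout on the
#' unit sphere covering the scalp cap (polar angle up to ~115 degrees from
#' the vertex, roughly the extent of an extended 10-10 system). Coordinates
#' follow the RAS convention: x to the right ear, y to the nasion, z to the
#' vertex.
#'
#' @param n_channels number of electrodes (default 62).
#' @return an object of class `montage`: a list with `positions`
#'   (`n_channels` x 3 matrix of unit vectors) and `channel_names`.
#' @examples
#' m <- make_montage()
#' range(sqrt(rowSums(m$positions^2)))
#' @export
make_montage <- function(n_channels = 62L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 4L) stop_invalid("a montage needs at least 4 channels")
  # golden-angle spiral, uniform in cos(theta) over the cap
  cap <- cos(115 * pi / 180)
  i <- seq_len(n_channels)
  z <- 1 - (i - 0.5) / n_channels * (1 - cap)
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  pos <- pos / sqrt(rowSums(pos^2))
  names <- sprintf("E%02d", i)
  rownames(pos) <- names
  structure(list(positions = pos, channel_names = names),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels on the unit sphere\n",
              nrow(x$positions)))
  invisible(x)
}

#' Canonical microstate prototype topographies
#'
#' Reference maps for the four canonical microstate classes, used to give
#' fitted templates their A-D labels: A has a left-anterior/right-posterior
#' polarity axis, B its mirror image, C an anterior-posterior antisymmetry,
#' and D a fronto-central peak against an occipito-temporal surround. Each
#' map is a smooth dipolar field over the montage, average-referenced and
#' unit-normalized.
#'
#' @param montage a [make_montage()] object.
#' @return a 4 x n_channels matrix with rownames `A`-`D`.
#' @export
canonical_templates <- function(montage) {
  pos <- montage$positions
  unit <- function(v) v / sqrt(sum(v^2))
  gauss <- function(centre, width = 1.0) {
    d2 <- rowSums((pos - matrix(unit(centre), nrow(pos), 3,
                                byrow = TRUE))^2)
    exp(-d2 / (2 * width^2))
  }
  dipole <- function(p_pos, p_neg, width = 0.8)
    gauss(p_pos, width) - gauss(p_neg, width)
  maps <- rbind(
    A = dipole(c(-0.9, 0.45, 0.35), c(0.9, -0.45, 0.35)),
    B = dipole(c(0.9, 0.45, 0.35), c(-0.9, -0.45, 0.35)),
    C = dipole(c(0, 0.75, 0.65), c(0, -0.75, 0.65)),
    D = gauss(c(0, 0.35, 0.94), width = 0.7)
  )
  maps <- maps - rowMeans(maps)
  maps / sqrt(rowSums(maps^2))
}
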