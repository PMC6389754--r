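#' Standard 19-electrode 10-20 montage
#'
#' Idealized spherical positions of the 19 recording sites of the
#' international 10-20 system, projected to 2-D with an azimuthal-equidistant
#' projection (the vertex Cz maps to the origin; radial distance is
#' proportional to the inclination angle from the vertex).
#'
#' Positions are constructed from the classical 10/20 percentage scheme on a
#' sphere: the outer ring (Fp1/Fp2, F7/F8, T3/T4, T5/T6, O1/O2) lies at 72
#' degrees inclination; Fz, Cz, Pz, C3, C4 lie on the sagittal/coronal arcs at
#' 36 degree steps; F3/F4 and P3/P4 are spherical midpoints of (Fz, F7/F8) and
#' (Pz, T5/T6), as in the standard placement procedure.
#'
#' @param head_radius Scalp radius in mm for the projection (default 100).
#' @return An object of class `montage_layout`: a list with `labels` (19
#'   channel names), `xy` (19 x 2 matrix, mm; +x right, +y anterior) and
#'   `head_radius`.
#' @examples
#' lay <- montage_1020()
#' plot(lay)
#' @export
montage_1020 <- function(head_radius = 100) {
  stop_if_not_scalar_number(head_radius, "head_radius", lower = 0, strict = TRUE)
  deg <- pi / 180
  # (inclination from vertex, azimuth from +x axis counter-clockwise), degrees
  ring <- c(Fp1 = 108, Fp2 = 72, F7 = 144, F8 = 36, T3 = 180, T4 = 0,
            T5 = -144, T6 = -36, O1 = -108, O2 = -72)
  sph <- rbind(
    do.call(rbind, lapply(names(ring), function(l) c(72, ring[[l]]))),
    Fz = c(36, 90), Cz = c(0, 0), Pz = c(36, -90),
    C3 = c(36, 180), C4 = c(36, 0)
  )
  rownames(sph)[seq_along(ring)] <- names(ring)

  to_unit <- function(incl, az) {
    c(cos(az * deg) * sin(incl * deg),
      sin(az * deg) * sin(incl * deg),
      cos(incl * deg))
  }
  units <- lapply(rownames(sph), function(l) to_unit(sph[l, 1], sph[l, 2]))
  names(units) <- rownames(sph)
  # F3 midway between Fz and F7 on the sphere, etc.
  mid <- function(u, v) { m <- u + v; m / sqrt(sum(m^2)) }
  units$F3 <- mid(units$Fz, units$F7)
  units$F4 <- mid(units$Fz, units$F8)
  units$P3 <- mid(units$Pz, units$T5)
  units$P4 <- mid(units$Pz, units$T6)

  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
              "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  xy <- t(vapply(labels, function(l) {
    u <- units[[l]]
    incl <- acos(max(-1, min(1, u[3])))          # radians from vertex
    r <- head_radius * incl / (pi / 2)           # azimuthal equidistant
    az <- atan2(u[2], u[1])
    c(r * cos(az), r * sin(az))
  }, numeric(2)))
  colnames(xy) <- c("x", "y")
  structure(list(labels = labels, xy = xy, head_radius = head_radius),
            class = "montage_layout")
}

#' @export
print.montage_layout <- function(x, ...) {
  cat(sprintf("10-20 montage layout: %d electrodes, head radius %g mm\n",
              length(x$labels), x$head_radius))
  invisible(x)
}

#' @export
plot.montage_layout <- function(x, ...) {
  graphics::plot(x$xy, asp = 1, pch = 20, xlab = "x (mm)", ylab = "y (mm)",
                 xlim = c(-1, 1) * x$head_radius,
                 ylim = c(-1, 1) * x$head_radius, ...)
  theta <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(x$head_radius * cos(theta), x$head_radius * sin(theta),
                  col = "grey60")
  graphics::text(x$xy, labels = x$labels, pos = 3, cex = 0.7)
  invisible(x)
}

# canonical label lookup: case-insensitive, with modern/legacy temporal aliases
.label_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize channel labels to canonical 10-20 names
#'
#' Case-insensitive matching against the 19 canonical 10-20 labels, with the
#' modern temporal-chain aliases T7/T8/P7/P8 mapped to T3/T4/T5/T6.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of canonical labels.
#' @export
normalize_channel_labels <- function(labels) {
  canon <- montage_1020()$labels
  out <- vapply(labels, function(l) {
    l0 <- trimws(l)
    hit <- canon[toupper(canon) == toupper(l0)]
    if (length(hit) == 1L) return(hit)
    ali <- .label_aliases[toupper(names(.label_aliases)) == toupper(l0)]
    if (length(ali) == 1L) return(unname(ali))
    stop(sprintf("unknown channel label '%s'", l), call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
  out
}
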