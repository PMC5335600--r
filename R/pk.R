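## Pharmacokinetics: skin permeation and the egg-shaped HIA/BBB
## classification readout in the (TPSA, WLOGP) plane.

## Skin permeability (cm/h form), converted to cm/s on output.
KP_COEF_CMH <- c(intercept = -2.74, logp = 0.71, mw = -0.0061)

#' Skin permeability coefficient (log Kp)
#'
#' Linear QSPR in lipophilicity and molecular weight.  The regression is
#' defined in cm/h and converted to cm/s (subtracting log10 3600), the
#' unit in which the value is reported.  More negative means less skin
#' permeant.
#'
#' @param descriptors \code{adm_descriptors} (needs MW).
#' @param logp Lipophilicity value to plug in.
#' @return log10 of Kp in cm/s.
#' @export
skin_log_kp <- function(descriptors, logp) {
  stopifnot(descriptors$MW > 0)
  unname(KP_COEF_CMH["intercept"] +
           KP_COEF_CMH["logp"] * logp +
           KP_COEF_CMH["mw"] * descriptors$MW) - log10(3600)
}

#' Load egg classification geometry
#'
#' Reads the two-ellipse geometry (white = gastrointestinal absorption,
#' yolk = brain access) and plot range from a key-value text file.  The
#' packaged default is used when \code{path} is NULL.
#'
#' @param path Optional path to a geometry file.
#' @return Object of class \code{adm_egg_geometry}.
#' @export
load_egg_geometry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "egg_geometry.txt",
                                package = "admetk")
  if (!nzchar(path) || !file.exists(path)) {
    adm_error("adm_missing_geometry", "egg geometry file not found")
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- do.call(rbind, strsplit(lines, "[[:space:]]+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  ell <- function(prefix) {
    list(cx = vals[[paste0(prefix, ".cx")]],
         cy = vals[[paste0(prefix, ".cy")]],
         a = vals[[paste0(prefix, ".width")]] / 2,
         b = vals[[paste0(prefix, ".height")]] / 2,
         angle = vals[[paste0(prefix, ".angle")]] * pi / 180)
  }
  geom <- list(
    white = ell("white"),
    yolk = ell("yolk"),
    range = list(tpsa = c(vals[["range.tpsa_min"]], vals[["range.tpsa_max"]]),
                 wlogp = c(vals[["range.wlogp_min"]], vals[["range.wlogp_max"]]))
  )
  if (geom$white$a <= 0 || geom$white$b <= 0 ||
      geom$yolk$a <= 0 || geom$yolk$b <= 0) {
    adm_error("adm_missing_geometry", "ellipse axes must be positive")
  }
  structure(geom, class = "adm_egg_geometry")
}

#' Point-in-ellipse test
#'
#' @param x,y Point coordinates (TPSA, WLOGP).
#' @param ellipse List with centre \code{cx, cy}, semi-axes \code{a, b}
#'   and rotation \code{angle} (radians).
#' @return TRUE when the point lies inside or on the ellipse.
#' @export
in_ellipse <- function(x, y, ellipse) {
  dx <- x - ellipse$cx
  dy <- y - ellipse$cy
  ct <- cos(ellipse$angle)
  st <- sin(ellipse$angle)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / ellipse$a)^2 + (v / ellipse$b)^2 <= 1
}

#' Egg classification of one molecule
#'
#' Positions the molecule in the (TPSA, WLOGP) plane: inside the white
#' ellipse predicts high passive gastrointestinal absorption, inside the
#' yolk predicts brain access; the two are not mutually exclusive.
#' Points outside the plot range are flagged and classified negative for
#' both.
#'
#' @param tpsa_value TPSA in square Angstroms.
#' @param wlogp_value WLOGP (log-units).
#' @param geometry \code{adm_egg_geometry} (default: packaged geometry).
#' @return List with \code{hia}, \code{bbb}, \code{in_plot_range}.
#' @examples
#' g <- load_egg_geometry()
#' boiled_egg(60, 2, g)    # inside the white
#' @export
boiled_egg <- function(tpsa_value, wlogp_value, geometry = load_egg_geometry()) {
  if (!inherits(geometry, "adm_egg_geometry")) {
    adm_error("adm_missing_geometry", "geometry must be adm_egg_geometry")
  }
  in_range <- tpsa_value >= geometry$range$tpsa[1] &&
    tpsa_value <= geometry$range$tpsa[2] &&
    wlogp_value >= geometry$range$wlogp[1] &&
    wlogp_value <= geometry$range$wlogp[2]
  if (!in_range) {
    return(list(hia = FALSE, bbb = FALSE, in_plot_range = FALSE))
  }
  list(
    hia = in_ellipse(tpsa_value, wlogp_value, geometry$white),
    bbb = in_ellipse(tpsa_value, wlogp_value, geometry$yolk),
    in_plot_range = TRUE
  )
}
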