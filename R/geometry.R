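# Centerline airway geometry: stations (arc position, cross-sectional area,
# wetted perimeter, 3D point, region) plus the model-variant transforms.

#' Anatomical region labels, in flow order
#'
#' The olfactory recess is a blind side chamber and is excluded from the main
#' respiratory flow path; the tracheal extension is artificial plumbing added
#' downstream of the choana.
#' @export
AIRWAY_REGIONS <- c("vestibule", "cnp", "olfactory_recess",
                    "nasopharyngeal_duct", "tracheal_extension")

MAIN_PATH_ORDER <- c("vestibule", "cnp", "nasopharyngeal_duct",
                     "tracheal_extension")

#' Construct a centerline airway
#'
#' An airway is an ordered table of stations along the duct centerline.  All
#' internal units are SI (m, m^2); reporting helpers convert to mm.
#'
#' @param stations data.frame with columns `s` (arc-length position, m),
#'   `area` (cross-sectional area, m^2), `perimeter` (wetted perimeter, m),
#'   `x`, `y`, `z` (centerline point, m) and `region` (one of
#'   [AIRWAY_REGIONS]).
#' @param name airway name.
#' @param variant one of `"BB"`, `"ST"`, `"basic"`, `"straightened"`,
#'   `"custom"`.
#' @param validate check invariants (positive sections, isoperimetric bound,
#'   strictly increasing arc length, chord <= arc, anatomical region order).
#' @return object of class `airway` (a data.frame).
#' @export
airway <- function(stations, name = "airway", variant = "custom",
                   validate = TRUE) {
  stopifnot(is.data.frame(stations))
  need <- c("s", "area", "perimeter", "x", "y", "z", "region")
  miss <- setdiff(need, names(stations))
  if (length(miss) > 0L)
    stop("missing station columns: ", paste(miss, collapse = ", "))
  variant <- match.arg(variant, c("BB", "ST", "basic", "straightened",
                                  "custom"))
  out <- as.data.frame(stations)[need]
  out$region <- as.character(out$region)
  rownames(out) <- NULL
  class(out) <- c("airway", "data.frame")
  attr(out, "name") <- name
  attr(out, "variant") <- variant
  if (validate) validate_airway(out)
  out
}

#' Validate airway invariants
#'
#' @param x an [airway()].
#' @return `x`, invisibly; errors mention the offending station row.
#' @export
validate_airway <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("an airway needs at least 2 stations")
  bad <- which(!(x$region %in% AIRWAY_REGIONS))
  if (length(bad) > 0L)
    stop("unknown region at row ", bad[1L], ": '", x$region[bad[1L]], "'")
  bad <- which(x$area <= 0 | !is.finite(x$area))
  if (length(bad) > 0L) stop("non-positive area at row ", bad[1L])
  bad <- which(x$perimeter <= 0 | !is.finite(x$perimeter))
  if (length(bad) > 0L) stop("non-positive perimeter at row ", bad[1L])
  # no closed cross section has less perimeter than the circle of equal area
  bad <- which(x$perimeter < 2 * sqrt(pi * x$area) * (1 - 1e-9))
  if (length(bad) > 0L)
    stop("perimeter below isoperimetric minimum at row ", bad[1L])
  if (x$s[1L] < 0) stop("arc length must start at 0")
  ds <- diff(x$s)
  bad <- which(ds <= 0)
  if (length(bad) > 0L)
    stop("arc length not strictly increasing at row ", bad[1L] + 1L)
  chord <- sqrt(diff(x$x)^2 + diff(x$y)^2 + diff(x$z)^2)
  bad <- which(chord > ds * (1 + 1e-6) + 1e-12)
  if (length(bad) > 0L)
    stop("chord exceeds arc length between rows ", bad[1L], " and ",
         bad[1L] + 1L)
  # main-path regions must appear in anatomical order
  main <- x$region[x$region %in% MAIN_PATH_ORDER]
  idx <- match(main, MAIN_PATH_ORDER)
  if (any(diff(idx) < 0))
    stop("regions out of anatomical order (vestibule -> cnp -> ",
         "nasopharyngeal_duct -> tracheal_extension)")
  invisible(x)
}

airway_name <- function(x) attr(x, "name")
airway_variant <- function(x) attr(x, "variant")

#' @export
print.airway <- function(x, ...) {
  cat(sprintf("<airway '%s' (%s): %d stations, %.1f mm, regions: %s>\n",
              airway_name(x), airway_variant(x), nrow(x),
              1000 * (max(x$s) - min(x$s)),
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' Stations on the main respiratory flow path
#'
#' Drops the olfactory recess (blind side chamber) and, by default, the
#' artificial tracheal extension.
#'
#' @param x an [airway()].
#' @param include_trachea keep the tracheal extension?
#' @export
main_path <- function(x, include_trachea = FALSE) {
  drop <- "olfactory_recess"
  if (!include_trachea) drop <- c(drop, "tracheal_extension")
  out <- x[!(x$region %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hydraulic diameter of a cross section
#'
#' `Dh = 4 A / P`, the characteristic length for non-circular ducts.
#'
#' @param area cross-sectional area (m^2).
#' @param perimeter wetted perimeter (m).
#' @return hydraulic diameter (m); vectorised.
#' @export
hydraulic_diameter <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("invalid geometry: area and perimeter must be positive")
  4 * area / perimeter
}

# trapezoid integral of y over x
trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

subset_region <- function(x, region) {
  region <- match.arg(region, AIRWAY_REGIONS)
  out <- x[x$region == region, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("region '", region, "' absent from airway '", airway_name(x), "'")
  out
}

#' Mean airway caliber
#'
#' Arc-length-weighted mean hydraulic diameter, in mm.  The weighting follows
#' the trapezoid rule over the station grid, so a uniform tube returns its
#' diameter exactly.
#'
#' @param x an [airway()].
#' @param region optional region label; default averages over all stations.
#' @return mean caliber (mm).
#' @export
mean_caliber <- function(x, region = NULL) {
  sub <- if (is.null(region)) x else subset_region(x, region)
  if (nrow(sub) < 2L) stop("need at least 2 stations to average caliber")
  dh <- hydraulic_diameter(sub$area, sub$perimeter)
  1000 * trapz(sub$s, dh) / (max(sub$s) - min(sub$s))
}

#' Per-region length, volume and tortuosity
#'
#' Length is the arc-length span of the region, volume the trapezoidal
#' integral of area over arc length, and tortuosity the ratio of arc length
#' to the straight-line distance between the region end points (>= 1).
#'
#' @param x an [airway()].
#' @param region region label.
#' @return list with `length_mm`, `volume_mm3`, `tortuosity`.
#' @export
region_metrics <- function(x, region) {
  sub <- subset_region(x, region)
  if (nrow(sub) < 2L) stop("region '", region, "' has fewer than 2 stations")
  arc <- max(sub$s) - min(sub$s)
  n <- nrow(sub)
  chord <- sqrt((sub$x[n] - sub$x[1L])^2 + (sub$y[n] - sub$y[1L])^2 +
                  (sub$z[n] - sub$z[1L])^2)
  list(length_mm = 1000 * arc,
       volume_mm3 = 1e9 * trapz(sub$s, sub$area),
       tortuosity = if (chord > 0) arc / chord else Inf)
}

#' Discrete centerline curvature
#'
#' Menger (circumscribed-circle) curvature over consecutive point triples;
#' end points copy their neighbours.
#'
#' @param x an [airway()] or a 3-column matrix of points (m).
#' @return curvature per station (1/m).
#' @export
centerline_curvature <- function(x) {
  pts <- if (is.data.frame(x)) cbind(x$x, x$y, x$z) else as.matrix(x)
  n <- nrow(pts)
  if (n < 3L) return(rep(0, n))
  kappa <- numeric(n)
  for (i in 2:(n - 1L)) {
    a <- pts[i - 1L, ]; b <- pts[i, ]; c <- pts[i + 1L, ]
    ab <- b - a; ac <- c - a; bc <- c - b
    cross <- c(ab[2] * ac[3] - ab[3] * ac[2],
               ab[3] * ac[1] - ab[1] * ac[3],
               ab[1] * ac[2] - ab[2] * ac[1])
    area2 <- sqrt(sum(cross^2))                 # 2 * triangle area
    denom <- sqrt(sum(ab^2)) * sqrt(sum(bc^2)) * sqrt(sum(ac^2))
    kappa[i] <- if (denom > 0) 2 * area2 / denom else 0
  }
  kappa[1L] <- kappa[2L]
  kappa[n] <- kappa[n - 1L]
  kappa
}

#' Total integrated curvature of a region (radians)
#' @param x an [airway()].
#' @param region region label, default `"vestibule"`.
#' @export
total_curvature <- function(x, region = "vestibule") {
  sub <- subset_region(x, region)
  trapz(sub$s, centerline_curvature(sub))
}

typical_spacing <- function(sub) stats::median(diff(sub$s))

# interval-weighted means of area and perimeter over a station block
section_means <- function(sub) {
  list(area = trapz(sub$s, sub$area) / (max(sub$s) - min(sub$s)),
       perimeter = trapz(sub$s, sub$perimeter) / (max(sub$s) - min(sub$s)))
}

#' Shorten the vestibule to the straight nostril-to-CNP path ("basic" variant)
#'
#' Replaces the vestibule by a straight segment from the nostril end point to
#' the entry of the cavum nasi proprium, holding the cross section at the
#' source vestibule's mean caliber.  Downstream regions are unchanged.  The
#' fractional length reduction `(L_orig - L_straight) / L_orig` is attached as
#' attribute `"length_reduction"`.
#'
#' @param x an [airway()] with vestibule and cnp regions.
#' @return the shortened airway, variant `"basic"`.
#' @export
make_basic <- function(x) {
  vest <- subset_region(x, "vestibule")
  cnp <- subset_region(x, "cnp")
  p0 <- as.numeric(vest[1L, c("x", "y", "z")])
  entry <- as.numeric(cnp[1L, c("x", "y", "z")])
  d_chord <- sqrt(sum((entry - p0)^2))
  if (d_chord <= 0) stop("degenerate geometry: nostril coincides with CNP entry")
  i_entry <- which(x$region == "cnp")[1L]
  # connecting interval between the last vestibule station and the CNP entry
  gap_s <- x$s[i_entry] - max(vest$s)
  l_new <- d_chord - gap_s
  if (l_new <= 0) stop("degenerate geometry: vestibule gap exceeds chord")
  l_old <- max(vest$s) - min(vest$s)
  spacing <- typical_spacing(vest)
  nseg <- max(1L, round(l_new / spacing))
  s_new <- seq(0, l_new, length.out = nseg + 1L)
  u <- (entry - p0) / d_chord
  sm <- section_means(vest)
  vest_new <- data.frame(
    s = s_new,
    area = sm$area, perimeter = sm$perimeter,
    x = p0[1L] + s_new * u[1L],
    y = p0[2L] + s_new * u[2L],
    z = p0[3L] + s_new * u[3L],
    region = "vestibule")
  down <- x[seq(i_entry, nrow(x)), , drop = FALSE]
  down$s <- down$s - x$s[i_entry] + l_new + gap_s
  out <- airway(rbind(vest_new, down), name = airway_name(x),
                variant = "basic")
  attr(out, "length_reduction") <- (l_old - l_new) / l_old
  out
}

#' Remove vestibule curvature at constant length ("straightened" variant)
#'
#' Re-lays the vestibule centerline along a straight line while preserving
#' every station's arc position, area and perimeter exactly; downstream
#' regions are rigidly translated to stay attached.
#'
#' @param x an [airway()] with a vestibule.
#' @return the straightened airway, variant `"straightened"`.
#' @export
make_straightened <- function(x) {
  vest_idx <- which(x$region == "vestibule")
  if (length(vest_idx) == 0L) stop("region 'vestibule' absent")
  vest <- x[vest_idx, , drop = FALSE]
  p0 <- as.numeric(vest[1L, c("x", "y", "z")])
  after <- x[-vest_idx, , drop = FALSE]
  target <- if (nrow(after) > 0L) {
    as.numeric(after[1L, c("x", "y", "z")])
  } else {
    as.numeric(vest[nrow(vest), c("x", "y", "z")])
  }
  u <- target - p0
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0, 0)
  s_rel <- vest$s - vest$s[1L]
  old_end <- as.numeric(vest[nrow(vest), c("x", "y", "z")])
  vest$x <- p0[1L] + s_rel * u[1L]
  vest$y <- p0[2L] + s_rel * u[2L]
  vest$z <- p0[3L] + s_rel * u[3L]
  new_end <- as.numeric(vest[nrow(vest), c("x", "y", "z")])
  shift <- new_end - old_end
  if (nrow(after) > 0L) {
    after$x <- after$x + shift[1L]
    after$y <- after$y + shift[2L]
    after$z <- after$z + shift[3L]
  }
  out <- rbind(vest, after)
  out <- out[order(out$s), , drop = FALSE]
  airway(out, name = airway_name(x), variant = "straightened")
}

#' Soft-tissue caliber correction ("ST" variant)
#'
#' Scales cross sections shape-preservingly (area by k^2, perimeter by k, one
#' global k) so the mean vestibule caliber equals `target_caliber_mm`,
#' emulating the mucosal lining that narrows bony-bounded fossil airways.  The
#' centerline and the artificial tracheal extension are left untouched.
#'
#' @param x an [airway()] (typically variant `"BB"`).
#' @param target_caliber_mm target mean vestibule hydraulic diameter (mm),
#'   default 10 (the upper limit observed across extant amniotes).
#' @return the corrected airway, variant `"ST"`; the applied factor is
#'   attached as attribute `"caliber_scale"`.
#' @export
soft_tissue_correct <- function(x, target_caliber_mm = 10) {
  if (!is.numeric(target_caliber_mm) || target_caliber_mm <= 0)
    stop("target caliber must be positive")
  k <- target_caliber_mm / mean_caliber(x, "vestibule")
  idx <- x$region != "tracheal_extension"
  x$area[idx] <- x$area[idx] * k^2
  x$perimeter[idx] <- x$perimeter[idx] * k
  out <- airway(x, name = airway_name(x), variant = "ST")
  attr(out, "caliber_scale") <- k
  out
}
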