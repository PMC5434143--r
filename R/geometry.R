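# Visual-angle geometry, stimulus layout and AOI maps.
#
# All analysis happens in degrees of visual angle relative to the screen
# centre, +x right, +y up. Raw gaze files use pixels with the origin at the
# top-left corner and +y down; pixel_to_degree() performs the flip.

#' Display geometry
#'
#' Physical description of the monitor and viewing position. Defaults match
#' the experiment this package models: a 33.7 x 27.3 cm monitor at
#' 1280 x 1024 px viewed from 54 cm.
#'
#' @param screen_width_cm,screen_height_cm Physical screen size in cm.
#' @param resolution_x,resolution_y Screen resolution in pixels.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#'
#' @return An object of class `display_geometry` (a named list).
#' @export
#' @examples
#' geom <- display_geometry()
#' extent_to_angle(geom$screen_width_cm, geom$viewing_distance_cm)
display_geometry <- function(screen_width_cm = 33.7,
                             screen_height_cm = 27.3,
                             resolution_x = 1280L,
                             resolution_y = 1024L,
                             viewing_distance_cm = 54) {
  vals <- c(screen_width_cm, screen_height_cm, resolution_x, resolution_y,
            viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid geometry: all display_geometry fields must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(
      screen_width_cm = screen_width_cm,
      screen_height_cm = screen_height_cm,
      resolution_x = resolution_x,
      resolution_y = resolution_y,
      viewing_distance_cm = viewing_distance_cm
    ),
    class = "display_geometry"
  )
}

#' Visual angle subtended by a physical extent
#'
#' Converts a physical extent on the screen to degrees of visual angle via
#' `2 * atan(extent / (2 * distance))`.
#'
#' @param extent_cm Extent on the screen in cm (>= 0). Vectorised.
#' @param distance_cm Viewing distance in cm (> 0).
#'
#' @return Angle in degrees.
#' @export
#' @examples
#' extent_to_angle(14.22, 54) # ~15 degrees
#' extent_to_angle(0.30, 54)  # ~0.32 degrees
extent_to_angle <- function(extent_cm, distance_cm) {
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("invalid geometry: viewing distance must be strictly positive",
         call. = FALSE)
  }
  if (any(extent_cm < 0)) {
    stop("invalid geometry: extent must be non-negative", call. = FALSE)
  }
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

# Signed position helpers: offset from the screen-centre normal, so the
# angle of a point at physical offset `offset_cm` is atan(offset/distance).
.offset_to_deg <- function(offset_cm, distance_cm) {
  atan(offset_cm / distance_cm) * 180 / pi
}

.deg_to_offset <- function(deg, distance_cm) {
  tan(deg * pi / 180) * distance_cm
}

#' Half-extents of the screen in degrees
#'
#' @param geometry A [display_geometry()].
#' @return Named numeric vector with elements `x` and `y` (degrees).
#' @export
screen_half_extent_deg <- function(geometry = display_geometry()) {
  c(
    x = .offset_to_deg(geometry$screen_width_cm / 2, geometry$viewing_distance_cm),
    y = .offset_to_deg(geometry$screen_height_cm / 2, geometry$viewing_distance_cm)
  )
}

#' Convert pixel coordinates to degrees relative to screen centre
#'
#' Takes a data frame with pixel coordinates (origin top-left, +y down, as
#' written by the eye tracker) and appends `x_deg` / `y_deg` columns in the
#' analysis frame (origin at screen centre, +y up). Points slightly outside
#' the physical screen (tracker overshoot) are converted as-is; AOI
#' classification later maps them to "no AOI".
#'
#' @param data Data frame with pixel coordinate columns.
#' @param geometry A [display_geometry()].
#' @param x_col,y_col Names of the pixel coordinate columns.
#'
#' @return `data` as a tibble with `x_deg` and `y_deg` appended.
#' @export
#' @examples
#' pixel_to_degree(data.frame(x_px = 640, y_px = 512))
pixel_to_degree <- function(data, geometry = display_geometry(),
                            x_col = "x_px", y_col = "y_px") {
  stopifnot(is.data.frame(data))
  if (!all(c(x_col, y_col) %in% names(data))) {
    stop("pixel columns `", x_col, "`, `", y_col, "` not found", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  pitch_x <- geometry$screen_width_cm / geometry$resolution_x
  pitch_y <- geometry$screen_height_cm / geometry$resolution_y
  dx_cm <- (out[[x_col]] - geometry$resolution_x / 2) * pitch_x
  dy_cm <- (geometry$resolution_y / 2 - out[[y_col]]) * pitch_y # flip y
  out$x_deg <- .offset_to_deg(dx_cm, geometry$viewing_distance_cm)
  out$y_deg <- .offset_to_deg(dy_cm, geometry$viewing_distance_cm)
  out
}

#' Convert degree coordinates back to pixels
#'
#' Inverse of [pixel_to_degree()]; used by the gaze generator.
#'
#' @inheritParams pixel_to_degree
#' @param data Data frame with `x_deg` and `y_deg` columns.
#' @return `data` as a tibble with `x_px` and `y_px` appended.
#' @export
degree_to_pixel <- function(data, geometry = display_geometry()) {
  stopifnot(is.data.frame(data), all(c("x_deg", "y_deg") %in% names(data)))
  out <- tibble::as_tibble(data)
  pitch_x <- geometry$screen_width_cm / geometry$resolution_x
  pitch_y <- geometry$screen_height_cm / geometry$resolution_y
  dx_cm <- .deg_to_offset(out$x_deg, geometry$viewing_distance_cm)
  dy_cm <- .deg_to_offset(out$y_deg, geometry$viewing_distance_cm)
  out$x_px <- geometry$resolution_x / 2 + dx_cm / pitch_x
  out$y_px <- geometry$resolution_y / 2 - dy_cm / pitch_y
  out
}

#' Stimulus layout for one gap condition
#'
#' Two rows of three digits, one atop the other, vertically centred on the
#' screen. In the standard condition the rows are separated by a 0.32 deg
#' gap; in the far condition by 15 deg. Row centres sit at
#' +/-(gap/2 + row_height/2) on the vertical midline.
#'
#' @param gap_condition `"standard"` or `"far"`.
#' @param row_width_deg,row_height_deg Angular size of one digit row.
#' @param gap_deg Vertical gap between the rows' inner edges, in degrees.
#'   Defaults to 0.32 (standard) or 15 (far).
#'
#' @return An object of class `stimulus_layout`.
#' @export
#' @examples
#' stimulus_layout("far")$top_row_center
stimulus_layout <- function(gap_condition = c("standard", "far"),
                            row_width_deg = 0.94,
                            row_height_deg = 0.34,
                            gap_deg = NULL) {
  gap_condition <- match.arg(gap_condition)
  if (is.null(gap_deg)) {
    gap_deg <- if (gap_condition == "far") 15 else 0.32
  }
  stopifnot(gap_deg > 0, row_width_deg > 0, row_height_deg > 0)
  yc <- gap_deg / 2 + row_height_deg / 2
  structure(
    list(
      gap_condition = gap_condition,
      row_width_deg = row_width_deg,
      row_height_deg = row_height_deg,
      gap_deg = gap_deg,
      top_row_center = c(x = 0, y = yc),
      bottom_row_center = c(x = 0, y = -yc)
    ),
    class = "stimulus_layout"
  )
}

#' Row centre lookup
#' @param layout A [stimulus_layout()].
#' @param row `"top"` or `"bottom"` (vectorised).
#' @return 2-column matrix of row-centre coordinates (degrees).
#' @export
row_center <- function(layout, row) {
  stopifnot(all(row %in% c("top", "bottom")))
  cbind(
    x = rep(0, length(row)),
    y = ifelse(row == "top", layout$top_row_center[["y"]],
               layout$bottom_row_center[["y"]])
  )
}

#' AOI map constructor
#'
#' An AOI map is a tibble of six axis-aligned rectangles in screen degrees,
#' half-open on their max edges (`[min, max)` on both axes), so every point
#' belongs to at most one region and a point on a shared horizontal boundary
#' belongs to the upper region. Regions are ordered top to bottom.
#'
#' @param regions Data frame with columns `label`, `x_min`, `x_max`, `y_min`,
#'   `y_max` and `stimulus_row` (`"top"`, `"bottom"` or `NA` when the region
#'   holds no stimulus).
#' @param gap_condition `"standard"` or `"far"`.
#'
#' @return A tibble of class `aoi_map`.
#' @export
aoi_map <- function(regions, gap_condition = c("standard", "far")) {
  gap_condition <- match.arg(gap_condition)
  regions <- tibble::as_tibble(regions)
  needed <- c("label", "x_min", "x_max", "y_min", "y_max", "stimulus_row")
  if (!all(needed %in% names(regions))) {
    stop("invalid map: regions need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(regions) != 6L) {
    stop("invalid map: an AOI map has exactly six regions", call. = FALSE)
  }
  if (anyDuplicated(regions$label)) {
    stop("invalid map: AOI labels must be unique", call. = FALSE)
  }
  if (any(regions$x_max <= regions$x_min) || any(regions$y_max <= regions$y_min)) {
    stop("invalid map: degenerate region bounds", call. = FALSE)
  }
  # pairwise overlap under half-open semantics
  for (i in seq_len(nrow(regions) - 1L)) {
    for (j in seq(i + 1L, nrow(regions))) {
      ox <- regions$x_min[i] < regions$x_max[j] && regions$x_min[j] < regions$x_max[i]
      oy <- regions$y_min[i] < regions$y_max[j] && regions$y_min[j] < regions$y_max[i]
      if (ox && oy) {
        stop("invalid map: regions ", regions$label[i], " and ",
             regions$label[j], " overlap", call. = FALSE)
      }
    }
  }
  regions <- regions[order(-(regions$y_min + regions$y_max) / 2), ]
  structure(regions, gap_condition = gap_condition,
            class = c("aoi_map", class(tibble::tibble())))
}

#' Default AOI maps
#'
#' The published region bounds are not available, so the default maps are
#' constructed programmatically as six full-width horizontal bands, symmetric
#' about the vertical midline of the screen.
#'
#' * **far** (15 deg gap): six equal-height bands labelled `T1`, `T2`, `T3`,
#'   `B3`, `B2`, `B1` top to bottom; the stimulus rows fall inside `T2` and
#'   `B2`.
#' * **standard** (0.32 deg gap): bands `ST1`, `ST2`, `ST3`, `SB3`, `SB2`,
#'   `SB1`, with boundaries placed so that the `ST2`/`SB2` midpoints sit
#'   3.75 deg and the `ST1`/`SB1` midpoints 10 deg from the nearer stimulus
#'   row; both stimulus rows fall inside `ST3`/`SB3`.
#'
#' @param gap_condition `"standard"` or `"far"`.
#' @param geometry A [display_geometry()].
#' @param layout A [stimulus_layout()]; defaults to the layout matching
#'   `gap_condition`.
#' @param d_mid_deg,d_outer_deg Standard-condition distance anchors for the
#'   middle and outer band midpoints (degrees from the nearer stimulus row).
#'
#' @return An `aoi_map`.
#' @export
#' @examples
#' default_aoi_map("far")
default_aoi_map <- function(gap_condition = c("standard", "far"),
                            geometry = display_geometry(),
                            layout = NULL,
                            d_mid_deg = 3.75,
                            d_outer_deg = 10) {
  gap_condition <- match.arg(gap_condition)
  if (is.null(layout)) layout <- stimulus_layout(gap_condition)
  half <- screen_half_extent_deg(geometry)
  xmax <- half[["x"]]
  ymax <- half[["y"]]

  if (gap_condition == "far") {
    bounds <- seq(ymax, -ymax, length.out = 7L)
    labels <- c("T1", "T2", "T3", "B3", "B2", "B1")
  } else {
    yc <- layout$top_row_center[["y"]]
    b2 <- 2 * (d_outer_deg + yc) - ymax    # ST1 midpoint d_outer from top row
    b1 <- 2 * (d_mid_deg + yc) - b2        # ST2 midpoint d_mid from top row
    if (!(0 < b1 && b1 < b2 && b2 < ymax)) {
      stop("invalid map: distance anchors incompatible with screen extent",
           call. = FALSE)
    }
    bounds <- c(ymax, b2, b1, 0, -b1, -b2, -ymax)
    labels <- c("ST1", "ST2", "ST3", "SB3", "SB2", "SB1")
  }

  regions <- tibble::tibble(
    label = labels,
    x_min = -xmax, x_max = xmax,
    y_min = bounds[-1L], y_max = bounds[-7L],
    stimulus_row = NA_character_
  )
  for (row in c("top", "bottom")) {
    yr <- row_center(layout, row)[1, "y"]
    inside <- regions$y_min <= yr & yr < regions$y_max
    if (sum(inside) != 1L) {
      stop("invalid map: the ", row, " stimulus row must fall in exactly one region",
           call. = FALSE)
    }
    regions$stimulus_row[inside] <- row
  }
  aoi_map(regions, gap_condition)
}

#' Classify points into AOIs
#'
#' @param data Data frame with `x_deg` / `y_deg` columns (or a pair of
#'   numeric vectors via `x`, `y`).
#' @param map An [aoi_map()].
#' @param x,y Optional numeric vectors used instead of `data`.
#'
#' @return Character vector of AOI labels, `NA` where no region contains the
#'   point.
#' @export
#' @examples
#' m <- default_aoi_map("far")
#' assign_aoi(x = 0, y = 7.7, map = m) # "T2"
assign_aoi <- function(data = NULL, map, x = NULL, y = NULL) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data), all(c("x_deg", "y_deg") %in% names(data)))
    x <- data$x_deg
    y <- data$y_deg
  }
  stopifnot(length(x) == length(y))
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(map))) {
    hit <- !is.na(x) & !is.na(y) &
      map$x_min[i] <= x & x < map$x_max[i] &
      map$y_min[i] <= y & y < map$y_max[i]
    out[hit] <- map$label[i]
  }
  out
}

#' Angular distance from AOI midpoints to a stimulus row
#'
#' Euclidean distance in degrees between each region's midpoint and the
#' centre of the target row. For a region that contains the target stimulus
#' itself the distance is defined as exactly 0 (the stimulus is embedded in
#' the region, so the midpoint offset is not meaningful there).
#'
#' @param map An [aoi_map()].
#' @param target_row `"top"` or `"bottom"`.
#' @param layout A [stimulus_layout()] in the same coordinate frame.
#'
#' @return Tibble with columns `label`, `target_row`, `distance_deg`.
#' @export
aoi_distances <- function(map, target_row = c("top", "bottom"),
                          layout = stimulus_layout(attr(map, "gap_condition"))) {
  target_row <- match.arg(target_row)
  ctr <- row_center(layout, target_row)[1, ]
  mx <- (map$x_min + map$x_max) / 2
  my <- (map$y_min + map$y_max) / 2
  d <- sqrt((mx - ctr[["x"]])^2 + (my - ctr[["y"]])^2)
  d[!is.na(map$stimulus_row) & map$stimulus_row == target_row] <- 0
  tibble::tibble(label = map$label, target_row = target_row, distance_deg = d)
}

#' Serialize / read an AOI configuration
#'
#' The configuration bundles display geometry, stimulus layout and AOI
#' regions as a single JSON document, so custom maps can replace the
#' programmatic defaults.
#'
#' @param map An [aoi_map()].
#' @param geometry A [display_geometry()].
#' @param layout A [stimulus_layout()].
#' @param path File path.
#' @return `write_aoi_config()` returns `path` invisibly;
#'   `read_aoi_config()` returns a list with elements `geometry`, `layout`
#'   and `map`.
#' @export
write_aoi_config <- function(map, geometry, layout, path) {
  cfg <- list(
    geometry = unclass(geometry),
    layout = list(
      gap_condition = layout$gap_condition,
      row_width_deg = layout$row_width_deg,
      row_height_deg = layout$row_height_deg,
      gap_deg = layout$gap_deg
    ),
    regions = as.data.frame(map)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_aoi_config
#' @export
read_aoi_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  geometry <- do.call(display_geometry, cfg$geometry)
  layout <- stimulus_layout(
    gap_condition = cfg$layout$gap_condition,
    row_width_deg = cfg$layout$row_width_deg,
    row_height_deg = cfg$layout$row_height_deg,
    gap_deg = cfg$layout$gap_deg
  )
  map <- aoi_map(cfg$regions, gap_condition = cfg$layout$gap_condition)
  list(geometry = geometry, layout = layout, map = map)
}
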