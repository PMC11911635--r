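#' Zone geometries
#'
#' Zones are closed point sets on the arena floor: a sample on the boundary
#' counts as inside, which gives a deterministic tie-break for boundary
#' frames. Rectangles use arena-local coordinates with the origin at the
#' lower-left corner; discs and quadrants are defined around a center point
#' (the arena center for circular mazes).
#'
#' @param x0,y0,x1,y1 Rectangle corners (cm), `x0 < x1`, `y0 < y1`.
#' @param cx,cy Center of a disc or quadrant (cm).
#' @param radius Disc/quadrant radius (cm).
#' @param which Quadrant label: one of `"NE"`, `"NW"`, `"SW"`, `"SE"`.
#' @param zone,within For [zone_complement()]: the zone to exclude and the
#'   enclosing zone.
#' @return A `phenocage_zone` object.
#' @examples
#' z <- zone_disc(0, 0, 10)
#' zone_contains(z, c(0, 10, 11), c(0, 0, 0))
#' @name zones
NULL

new_zone <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "phenocage_zone")
}

#' @rdname zones
#' @export
zone_rect <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) stop_input("degenerate rectangle zone")
  new_zone("rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' @rdname zones
#' @export
zone_disc <- function(cx, cy, radius) {
  check_pos(radius, "radius")
  new_zone("disc", cx = cx, cy = cy, radius = radius)
}

#' @rdname zones
#' @export
zone_quadrant <- function(cx, cy, radius, which = c("NE", "NW", "SW", "SE")) {
  which <- match.arg(which)
  check_pos(radius, "radius")
  new_zone("quadrant", cx = cx, cy = cy, radius = radius, which = which)
}

#' @rdname zones
#' @export
zone_complement <- function(zone, within) {
  stopifnot(inherits(zone, "phenocage_zone"), inherits(within, "phenocage_zone"))
  new_zone("complement", inner = zone, outer = within)
}

#' Zone membership
#'
#' @param zone A `phenocage_zone`.
#' @param x,y Coordinate vectors (cm).
#' @return Logical vector, `TRUE` where the point lies in the (closed) zone.
#' @export
zone_contains <- function(zone, x, y) {
  switch(zone$kind,
    rect = x >= zone$x0 & x <= zone$x1 & y >= zone$y0 & y <= zone$y1,
    disc = (x - zone$cx)^2 + (y - zone$cy)^2 <= zone$radius^2,
    quadrant = {
      # half-open at the axes so the four quadrants exactly partition the
      # disc (a boundary sample belongs to one quadrant, deterministically)
      dx <- x - zone$cx
      dy <- y - zone$cy
      inside <- dx^2 + dy^2 <= zone$radius^2
      inside & switch(zone$which,
        NE = dx >= 0 & dy >= 0,
        NW = dx < 0 & dy >= 0,
        SW = dx < 0 & dy < 0,
        SE = dx >= 0 & dy < 0
      )
    },
    complement = zone_contains(zone$outer, x, y) & !zone_contains(zone$inner, x, y),
    stop_input("unknown zone kind '%s'", zone$kind)
  )
}

# Shortest distance from points to the zone boundary region used by
# interaction scoring: 0 when inside the zone.
zone_distance <- function(zone, x, y) {
  switch(zone$kind,
    disc = pmax(0, sqrt((x - zone$cx)^2 + (y - zone$cy)^2) - zone$radius),
    rect = {
      dx <- pmax(zone$x0 - x, 0, x - zone$x1)
      dy <- pmax(zone$y0 - y, 0, y - zone$y1)
      sqrt(dx^2 + dy^2)
    },
    stop_input("proximity scoring supports disc and rect zones")
  )
}

#' Arena geometries
#'
#' Constructors for the standard test arenas. Dimensions are the common ones
#' for these apparatus: a 50x50 cm open field with a centered 40x40 cm inner
#' zone, a 120 cm Barnes disc with 12 holes of 10.5 cm diameter set 12 cm in
#' from the rim, a 120 cm water-maze pool with an 11 cm platform about 27 cm
#' from the edge and four NE/NW/SW/SE quadrants, and a 30x30 cm home cage
#' with a 10x10 cm shelter in one corner.
#'
#' @param kind Arena kind.
#' @param shelter Optionally override the home-cage shelter zone.
#' @return A `phenocage_arena`: list with `kind`, `bounds` zone, and named
#'   `zones`.
#' @examples
#' a <- arena_geometry("open_field")
#' names(a$zones)
#' @export
arena_geometry <- function(kind = c("open_field", "phenotyper", "barnes",
                                    "water_maze", "three_chamber", "t_maze",
                                    "darklight"),
                           shelter = NULL) {
  kind <- match.arg(kind)
  geo <- switch(kind,
    open_field = {
      inner <- zone_rect(5, 5, 45, 45)
      bounds <- zone_rect(0, 0, 50, 50)
      list(bounds = bounds,
           zones = list(inner = inner, outer = zone_complement(inner, bounds)))
    },
    phenotyper = {
      bounds <- zone_rect(0, 0, 30, 30)
      sh <- if (is.null(shelter)) zone_rect(0, 20, 10, 30) else shelter
      list(bounds = bounds, zones = list(shelter = sh))
    },
    barnes = {
      bounds <- zone_disc(0, 0, 60)
      ang <- 2 * pi * (0:11) / 12
      holes <- lapply(ang, function(a) zone_disc(48 * cos(a), 48 * sin(a), 10.5 / 2))
      names(holes) <- paste0("hole_", 1:12)
      quads <- lapply(c("NE", "NW", "SW", "SE"), function(q) zone_quadrant(0, 0, 60, q))
      names(quads) <- c("NE", "NW", "SW", "SE")
      list(bounds = bounds, zones = c(holes, quads))
    },
    water_maze = {
      bounds <- zone_disc(0, 0, 60)
      quads <- lapply(c("NE", "NW", "SW", "SE"), function(q) zone_quadrant(0, 0, 60, q))
      names(quads) <- c("NE", "NW", "SW", "SE")
      # platform center 27 cm in from the edge, in the NE quadrant diagonal
      d <- (60 - 27) / sqrt(2)
      list(bounds = bounds,
           zones = c(list(platform = zone_disc(d, d, 11 / 2)), quads))
    },
    three_chamber = {
      bounds <- zone_rect(0, 0, 63, 42)
      list(bounds = bounds,
           zones = list(left = zone_rect(0, 0, 21, 42),
                        middle = zone_rect(21, 0, 42, 42),
                        right = zone_rect(42, 0, 63, 42)))
    },
    t_maze = {
      bounds <- zone_rect(0, 0, 80, 45)
      list(bounds = bounds,
           zones = list(start = zone_rect(35, 0, 45, 35),
                        left = zone_rect(0, 35, 35, 45),
                        right = zone_rect(45, 35, 80, 45)))
    },
    darklight = {
      bounds <- zone_rect(0, 0, 100, 25)
      list(bounds = bounds,
           zones = list(dark = zone_rect(0, 0, 50, 25),
                        light = zone_rect(50, 0, 100, 25)))
    }
  )
  structure(list(kind = kind, bounds = geo$bounds, zones = geo$zones),
            class = "phenocage_arena")
}

#' Light cycle
#'
#' A 12:12 dark-light schedule with lights on 07:00-19:00 by default (two
#' switches per 24 h). `t0` is the clock time at which the recording starts;
#' home-cage analysis conventionally starts at the first lights-off.
#'
#' @param lights_on,lights_off Clock times `"HH:MM"`.
#' @param t0 Clock time of trace time zero (default `"19:00"`, the start of
#'   the first dark phase).
#' @return A `phenocage_lightcycle`.
#' @examples
#' lc <- light_cycle()
#' light_phase(lc, c(0, 6 * 3600, 13 * 3600))
#' @export
light_cycle <- function(lights_on = "07:00", lights_off = "19:00", t0 = "19:00") {
  parse_clock <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(p) != 2L || anyNA(p)) stop_input("clock time must be 'HH:MM', got '%s'", s)
    3600 * p[1] + 60 * p[2]
  }
  on <- parse_clock(lights_on); off <- parse_clock(lights_off)
  if (on == off) stop_input("lights_on and lights_off must differ")
  structure(list(on = on, off = off, t0 = parse_clock(t0)),
            class = "phenocage_lightcycle")
}

#' Phase lookup for trace times
#'
#' @param lc A [light_cycle()].
#' @param t Trace times in seconds since recording start.
#' @return Character vector `"light"`/`"dark"`.
#' @export
light_phase <- function(lc, t) {
  stopifnot(inherits(lc, "phenocage_lightcycle"))
  clock <- (lc$t0 + t) %% 86400
  lit <- if (lc$on < lc$off) {
    clock >= lc$on & clock < lc$off
  } else {
    clock >= lc$on | clock < lc$off
  }
  ifelse(lit, "light", "dark")
}

# Phase windows [start, end) covering [0, total): tibble with phase,
# phase_index (1-based per phase kind), start, end. Assumes t0 lies on a
# switch (the supported home-cage design).
phase_windows <- function(lc, total) {
  stopifnot(inherits(lc, "phenocage_lightcycle"))
  starts <- seq(0, total, by = 43200)
  starts <- starts[starts < total]
  ph <- light_phase(lc, starts)
  tibble::tibble(
    phase = ph,
    phase_index = stats::ave(seq_along(ph), ph, FUN = seq_along),
    start = starts,
    end = pmin(starts + 43200, total)
  )
}
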