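#' Area-of-interest constructors
#'
#' AOIs are the pre-drawn stimulus regions used to bin gaze events: an
#' ellipse for an embedded face target, polygons for noise patches.
#' Coordinates are screen pixels with the origin at the top-left corner and
#' y increasing downward.
#'
#' @param label AOI label, `"target"` or `"noise"`.
#' @param cx,cy Ellipse centre, px.
#' @param rx,ry Ellipse semi-axes, px (must be positive).
#' @param rotation_deg Ellipse rotation, degrees counter-clockwise.
#' @return A list of class `aoi` with a `shape` field (`"ellipse"` or
#'   `"polygon"`).
#' @export
aoi_ellipse <- function(label, cx, cy, rx, ry, rotation_deg = 0) {
  stopifnot(label %in% c("target", "noise"), rx > 0, ry > 0)
  structure(list(label = label, shape = "ellipse",
                 cx = cx, cy = cy, rx = rx, ry = ry,
                 rotation_deg = rotation_deg),
            class = "aoi")
}

#' @rdname aoi_ellipse
#' @param x,y Polygon vertex coordinates, px, in order (the closing edge back
#'   to the first vertex is implicit). The polygon must be simple.
#' @export
aoi_polygon <- function(label, x, y) {
  stopifnot(label %in% c("target", "noise"),
            length(x) == length(y), length(x) >= 3)
  if (polygon_self_intersects(x, y))
    stop("polygon is self-intersecting")
  structure(list(label = label, shape = "polygon", x = x, y = y),
            class = "aoi")
}

# Segment-intersection scan over non-adjacent edge pairs; n is small
# (stimulus AOIs have < 20 vertices) so the quadratic scan is fine.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip adjacent (wrap) pair
    for (j in js) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-AOI membership tests
#'
#' The ellipse test de-rotates the point into the ellipse frame and checks
#' the normalised quadratic form \eqn{(x/r_x)^2 + (y/r_y)^2 \le 1}. The
#' polygon test uses even-odd ray casting with a horizontal ray.
#'
#' @param px,py Point coordinates (vectors of equal length), screen px.
#' @param aoi An [aoi_ellipse()] or [aoi_polygon()].
#' @return Logical vector.
#' @export
point_in_aoi <- function(px, py, aoi) {
  stopifnot(inherits(aoi, "aoi"))
  if (aoi$shape == "ellipse") {
    th <- -aoi$rotation_deg * pi / 180
    dx <- px - aoi$cx; dy <- py - aoi$cy
    u <- dx * cos(th) - dy * sin(th)
    v <- dx * sin(th) + dy * cos(th)
    (u / aoi$rx)^2 + (v / aoi$ry)^2 <= 1
  } else {
    point_in_polygon(px, py, aoi$x, aoi$y)
  }
}

# Even-odd ray casting, vectorised over query points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign a gaze point to an AOI
#'
#' Returns the index and label of the first AOI containing the point. The
#' stimulus-set generator guarantees AOIs are disjoint, so ties cannot occur
#' for generated stimuli; for hand-built overlapping AOIs the first listed
#' wins.
#'
#' @param px,py Point coordinates, screen px (scalars).
#' @param aois List of AOI objects.
#' @return A list with `index` (integer or `NA`) and `label` (character or
#'   `NA`); `NA` means the point lies in no AOI.
#' @export
assign_aoi <- function(px, py, aois) {
  for (i in seq_along(aois)) {
    if (point_in_aoi(px, py, aois[[i]]))
      return(list(index = i, label = aois[[i]]$label))
  }
  list(index = NA_integer_, label = NA_character_)
}

# Vectorised AOI index per point; 0 = outside all AOIs.
assign_aoi_index <- function(px, py, aois) {
  idx <- integer(length(px))
  unassigned <- rep(TRUE, length(px))
  for (i in seq_along(aois)) {
    if (!any(unassigned)) break
    hit <- unassigned & point_in_aoi(px, py, aois[[i]])
    idx[hit] <- i
    unassigned <- unassigned & !hit
  }
  idx
}

#' Write / read AOI definitions as JSON
#'
#' One entry per stimulus: a list of `{label, shape, params}` records, the
#' interchange format the pipeline reads.
#'
#' @param stimulus_set A `stimulus_set` from [generate_stimulus_set()], or
#'   any named list of AOI lists.
#' @param path Output file.
#' @export
write_aoi_json <- function(stimulus_set, path) {
  payload <- lapply(stimulus_set, function(stim) {
    lapply(stim$aois, function(a) {
      if (a$shape == "ellipse")
        list(label = a$label, shape = "ellipse",
             params = list(cx = a$cx, cy = a$cy, rx = a$rx, ry = a$ry,
                           rotation_deg = a$rotation_deg))
      else
        list(label = a$label, shape = "polygon",
             params = list(x = a$x, y = a$y))
    })
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_aoi_json
#' @export
read_aoi_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(stim) {
    aois <- lapply(stim, function(a) {
      p <- a$params
      if (a$shape == "ellipse")
        aoi_ellipse(a$label, p$cx, p$cy, p$rx, p$ry, p$rotation_deg)
      else
        aoi_polygon(a$label, unlist(p$x), unlist(p$y))
    })
    list(aois = aois)
  })
}
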