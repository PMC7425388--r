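#' Generate a synthetic NPT stimulus set with AOIs
#'
#' Builds `n_images` stimuli on a 700x700 px canvas, mirroring the test
#' layout: the first `n_face_images` carry exactly one off-centre ellipse
#' AOI labelled `target` (the embedded two-tone face), and every image
#' carries one or more polygon AOIs labelled `noise`. Shapes are placed in
#' disjoint cells of a 3x3 grid with an inset margin, so AOIs never overlap
#' and always lie inside the stimulus area; face-image order is shuffled
#' into the set so targets are not clustered at the start.
#'
#' @param n_images Number of stimuli (default 80).
#' @param n_face_images Number of stimuli with an embedded face target
#'   (default 20).
#' @param seed Integer RNG seed.
#' @param canvas_px Side length of the square stimulus area, px.
#' @return A `stimulus_set`: a list of stimuli, each a list with `id`,
#'   `face_present` and `aois` (list of [aoi_ellipse()]/[aoi_polygon()]).
#' @export
generate_stimulus_set <- function(n_images = 80, n_face_images = 20,
                                  seed = 1L, canvas_px = 700) {
  if (n_images < 0 || n_face_images < 0)
    stop("image counts must be non-negative")
  if (n_face_images > n_images)
    stop("n_face_images must not exceed n_images")
  local_rng(seed)
  if (n_images == 0) return(structure(list(), class = "stimulus_set"))

  face_flags <- rep(FALSE, n_images)
  face_flags[sample.int(n_images, n_face_images)] <- TRUE

  ncell <- 3L
  cell <- canvas_px / ncell
  margin <- 0.12 * cell
  cell_centre <- function(k) {
    row <- (k - 1L) %/% ncell; col <- (k - 1L) %% ncell
    c((col + 0.5) * cell, (row + 0.5) * cell)
  }

  stimuli <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cells <- sample.int(ncell * ncell)
    aois <- list()
    used <- 0L
    if (face_flags[i]) {
      # off-centre target: never the central cell 5
      k <- cells[cells != 5L][1L]
      cc <- cell_centre(k)
      half <- cell / 2 - margin
      aois[[length(aois) + 1L]] <-
        aoi_ellipse("target",
                    cx = cc[1] + runif(1, -0.1, 0.1) * cell,
                    cy = cc[2] + runif(1, -0.1, 0.1) * cell,
                    rx = runif(1, 0.55, 0.8) * half,
                    ry = runif(1, 0.55, 0.8) * half,
                    rotation_deg = runif(1, 0, 180))
      cells <- setdiff(cells, k)
      used <- used + 1L
    }
    n_noise <- sample(1:3, 1L)
    for (j in seq_len(n_noise)) {
      k <- cells[j]
      cc <- cell_centre(k)
      half <- cell / 2 - margin
      nv <- sample(5:8, 1L)
      # one vertex per equal angular sector keeps every gap under 180
      # degrees, so the star polygon is simple by construction
      ang <- 2 * pi * (seq_len(nv) - 1 + runif(nv, 0.05, 0.95)) / nv
      rad <- runif(nv, 0.45, 0.95) * half
      aois[[length(aois) + 1L]] <-
        aoi_polygon("noise", cc[1] + rad * cos(ang), cc[2] + rad * sin(ang))
    }
    stimuli[[i]] <- list(id = sprintf("img%03d", i),
                         face_present = face_flags[i], aois = aois)
  }
  structure(stimuli, class = "stimulus_set")
}
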