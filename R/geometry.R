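#' Circular stimulus layout
#'
#' Places `n_locations` dot locations evenly around central fixation on a
#' circle of the given radius. Polar angles are measured clockwise from the
#' vertical meridian and start at half the angular step, so the default
#' 8-location layout sits at 22.5, 67.5, ..., 337.5 degrees.
#'
#' @param radius Eccentricity of the dot centres in degrees visual angle.
#' @param n_locations Number of equally spaced locations (>= 2).
#' @param dot_diameter Dot diameter in dva (metadata only).
#' @return An object of class `stimulus_layout` with fields `radius`,
#'   `angles` (degrees, clockwise from vertical), `dot_diameter`, and the
#'   Cartesian coordinates `x`, `y` (y up, clockwise angles).
#' @export
build_layout <- function(radius = 7, n_locations = 8, dot_diameter = 1.2) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("`radius` must be a single positive number")
  if (!is.numeric(n_locations) || length(n_locations) != 1 || n_locations < 2)
    stop("`n_locations` must be >= 2")
  n_locations <- as.integer(n_locations)
  step <- 360 / n_locations
  angles <- step / 2 + step * (seq_len(n_locations) - 1)
  theta <- angles * pi / 180
  structure(
    list(
      radius = radius,
      angles = angles,
      dot_diameter = dot_diameter,
      # clockwise from vertical: x = r sin(theta), y = r cos(theta)
      x = radius * sin(theta),
      y = radius * cos(theta)
    ),
    class = "stimulus_layout"
  )
}

n_locations <- function(layout) length(layout$angles)

check_location_index <- function(layout, i) {
  if (!is.numeric(i) || any(i < 1) || any(i > n_locations(layout)) ||
      any(i != round(i)))
    stop("location index out of range")
  as.integer(i)
}

#' Euclidean (chord) distance between two dot centres
#'
#' The straight-line distance between locations `i` and `j` on the stimulus
#' circle: 2 r sin(delta/2) where delta is the absolute polar-angle
#' difference folded to \[0, 180\] degrees.
#'
#' @param layout A [build_layout()] object.
#' @param i,j Location indices (1-based).
#' @return Distance in dva.
#' @export
chord_distance <- function(layout, i, j) {
  i <- check_location_index(layout, i)
  j <- check_location_index(layout, j)
  delta <- abs(layout$angles[i] - layout$angles[j]) %% 360
  delta <- ifelse(delta > 180, 360 - delta, delta)
  2 * layout$radius * sin(delta * pi / 360)
}

#' Enumerate the constrained four-dot sequences
#'
#' Each of the 8 locations serves once as starting location A. The sequence
#' construction rules are: B is 180 degrees clockwise from A, C is 90
#' degrees clockwise from B, and D is 180 degrees from C. Every quadrant is
#' stimulated exactly once and no two sequence locations are neighbours
#' (45 degrees apart), which decouples temporal order from spatial distance.
#'
#' @param layout An 8-location [build_layout()] object.
#' @return A list of 8 `sequence_spec` objects, one per starting location,
#'   each with `sequence_indices` (A, B, C, D) and `control_indices`.
#' @export
enumerate_sequences <- function(layout) {
  n <- n_locations(layout)
  if (n != 8)
    stop("sequence construction is defined for 8-location layouts only")
  lapply(seq_len(n), function(a) {
    # +180 deg = +4 steps, +90 deg = +2 steps (clockwise index order)
    b <- (a - 1 + 4) %% 8 + 1
    c_ <- (b - 1 + 2) %% 8 + 1
    d <- (c_ - 1 + 4) %% 8 + 1
    seq_idx <- as.integer(c(a, b, c_, d))
    structure(
      list(
        sequence_indices = seq_idx,
        control_indices = setdiff(seq_len(8), seq_idx)
      ),
      class = "sequence_spec"
    )
  })
}

#' Signed temporal distance within the sequence
#'
#' Sequence positions are labelled by the letters A-D or by position numbers
#' 1-4. The distance is `j - i` in sequence order: positive values are
#' successors, negative values predecessors.
#'
#' @param spec A `sequence_spec` (used only for validation; the distance is
#'   a property of the positions).
#' @param i,j Sequence positions: integers 1..4 or letters "A".."D".
#' @return Signed integer number of sequence steps.
#' @export
temporal_distance <- function(spec, i, j) {
  pos <- function(p) {
    if (is.character(p)) p <- match(toupper(p), c("A", "B", "C", "D"))
    if (any(is.na(p)) || any(p < 1) || any(p > 4) || any(p != round(p)))
      stop("sequence position must be in A..D (1..4)")
    as.integer(p)
  }
  pos(j) - pos(i)
}

#' Map sequence positions to lag matrix
#'
#' 4x4 matrix of signed temporal distances between sequence positions, rows
#' indexing the shown (partial-trial) item and columns the probed item.
#' @keywords internal
lag_matrix <- function() {
  outer(1:4, 1:4, function(i, j) j - i)
}
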