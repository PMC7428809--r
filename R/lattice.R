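#' Hexagonal lattice neighbors
#'
#' Crypt slots live on an axial-coordinate parallelogram: columns
#' `q = 0 ... grid_cols - 1`, rows `r = 0 ... grid_rows - 1`, with the six
#' axial neighbor offsets (+1,0), (-1,0), (0,+1), (0,-1), (+1,-1), (-1,+1).
#' The tissue is flat (non-periodic): offsets falling outside the grid are
#' simply dropped, so interior slots have six neighbors and the two acute
#' corners (0,0) and (grid_cols-1, grid_rows-1) have two.
#'
#' @param q,r Axial coordinate of a slot (0-based, within the grid).
#' @param grid_rows,grid_cols Grid dimensions.
#' @return A two-column integer matrix of in-grid neighbor coordinates
#'   (columns `q`, `r`); zero rows on a 1x1 grid.
#' @examples
#' nrow(hex_neighbors(2, 2, 5, 5))  # interior: 6
#' nrow(hex_neighbors(0, 0, 5, 5))  # acute corner: 2
#' @export
hex_neighbors <- function(q, r, grid_rows, grid_cols) {
  if (q < 0 || q >= grid_cols || r < 0 || r >= grid_rows) {
    stop("coordinate (", q, ", ", r, ") outside the grid")
  }
  dq <- c(1L, -1L, 0L, 0L, 1L, -1L)
  dr <- c(0L, 0L, 1L, -1L, -1L, 1L)
  nq <- q + dq
  nr <- r + dr
  keep <- nq >= 0 & nq < grid_cols & nr >= 0 & nr < grid_rows
  cbind(q = nq[keep], r = nr[keep])
}

#' Hexagonal lattice distance
#'
#' Axial hex distance `(|dq| + |dr| + |dq + dr|) / 2`: the number of lattice
#' steps between two slots. Vectorized over coordinates.
#'
#' @param q1,r1,q2,r2 Axial coordinates.
#' @return Integer distance(s); 0 iff the coordinates coincide.
#' @examples
#' hex_distance(0, 0, 1, 0)   # adjacent: 1
#' hex_distance(0, 0, 2, -1)  # 2
#' @export
hex_distance <- function(q1, r1, q2, r2) {
  dq <- q2 - q1
  dr <- r2 - r1
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}
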