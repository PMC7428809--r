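#' Crypt and tissue containers (reference semantics in plain R)
#'
#' These light-weight list structures mirror the state kept by the compiled
#' event engine and expose the crypt-lifecycle operations -- extinction with
#' dead-neighbor release, and bifurcation into an adjacent dead slot -- for
#' direct inspection and testing. [run_simulation()] performs the same
#' transitions internally.
#'
#' @param cells A list of [stem_cell()] objects (non-empty for a living
#'   crypt).
#' @param coordinate Axial coordinate `c(q, r)` of the crypt's slot.
#' @param created_time Day the crypt came into existence.
#' @return `new_crypt()` returns an object of class `crypt`.
#' @export
new_crypt <- function(cells, coordinate, created_time = 0) {
  structure(list(cells = cells,
                 coordinate = as.integer(coordinate),
                 alive = length(cells) > 0,
                 created_time = created_time,
                 extinct_time = NULL),
            class = "crypt")
}

#' Initialize a tissue of crypts
#'
#' Creates the full `grid_rows x grid_cols` lattice with every slot holding
#' a living crypt of `crypt_size` unmutated stem cells.
#'
#' @param p A [sim_params()] object.
#' @return An object of class `tissue`: a list with `params`, `slots` (a
#'   list of [new_crypt()] objects indexed `q * grid_rows + r + 1`),
#'   `current_time`, and a `turnover` log data frame.
#' @export
new_tissue <- function(p) {
  slots <- vector("list", p$grid_rows * p$grid_cols)
  id <- 0L
  for (q in seq_len(p$grid_cols) - 1L) {
    for (r in seq_len(p$grid_rows) - 1L) {
      cells <- lapply(seq_len(p$crypt_size), function(i) {
        stem_cell(unique_id = id + i)
      })
      id <- id + p$crypt_size
      slots[[q * p$grid_rows + r + 1L]] <- new_crypt(cells, c(q, r))
    }
  }
  structure(list(params = p, slots = slots, current_time = 0,
                 turnover = data.frame(event = character(0), time = numeric(0),
                                       q = integer(0), r = integer(0),
                                       parent_q = integer(0),
                                       parent_r = integer(0),
                                       lifespan = numeric(0))),
            class = "tissue")
}

.slot_index <- function(tissue, coordinate) {
  p <- tissue$params
  q <- coordinate[1]; r <- coordinate[2]
  if (q < 0 || q >= p$grid_cols || r < 0 || r >= p$grid_rows) {
    stop("coordinate (", q, ", ", r, ") outside the grid")
  }
  as.integer(q) * p$grid_rows + as.integer(r) + 1L
}

#' Count the dead neighbor slots of a crypt
#'
#' @param tissue A [new_tissue()] object.
#' @param coordinate Axial coordinate `c(q, r)`.
#' @return Number of adjacent slots whose crypt is dead.
#' @export
n_dead_neighbors <- function(tissue, coordinate) {
  p <- tissue$params
  nb <- hex_neighbors(coordinate[1], coordinate[2], p$grid_rows, p$grid_cols)
  if (nrow(nb) == 0) return(0L)
  sum(vapply(seq_len(nrow(nb)), function(i) {
    !tissue$slots[[.slot_index(tissue, nb[i, ])]]$alive
  }, logical(1)))
}

#' Mark a crypt extinct and release its neighbors
#'
#' Flags the crypt at `coordinate` as dead (it must have no living stem
#' cells), records its lifespan in the turnover log, and thereby releases
#' the homeostatic inhibition on its living neighbors: their dead-neighbor
#' counts, as reported by [n_dead_neighbors()], increase by one.
#'
#' @inheritParams n_dead_neighbors
#' @param time Event time in days.
#' @return The updated tissue.
#' @export
mark_extinct <- function(tissue, coordinate, time) {
  i <- .slot_index(tissue, coordinate)
  crypt <- tissue$slots[[i]]
  if (length(crypt$cells) > 0) {
    stop("cannot mark a crypt with living stem cells extinct")
  }
  crypt$alive <- FALSE
  crypt$extinct_time <- time
  tissue$slots[[i]] <- crypt
  tissue$current_time <- max(tissue$current_time, time)
  tissue$turnover <- rbind(tissue$turnover, data.frame(
    event = "crypt_death", time = time,
    q = crypt$coordinate[1], r = crypt$coordinate[2],
    parent_q = NA_integer_, parent_r = NA_integer_,
    lifespan = time - crypt$created_time))
  tissue
}

#' Attempt crypt bifurcation into an adjacent dead slot
#'
#' If the crypt at `coordinate` has grown to at least
#' `bifurcation_factor * crypt_size` stem cells and at least one adjacent
#' slot is dead, a uniformly chosen dead neighbor slot receives a new crypt
#' holding a uniformly chosen half (`floor(n/2)`) of the parent's stem
#' cells, states intact: the cells are partitioned, never copied or lost.
#' Otherwise the tissue is returned unchanged.
#'
#' @inheritParams mark_extinct
#' @return A list with `tissue` (possibly updated) and `daughter`, the new
#'   crypt's coordinate or `NULL` if no bifurcation happened.
#' @export
try_bifurcate <- function(tissue, coordinate, time = tissue$current_time) {
  p <- tissue$params
  i <- .slot_index(tissue, coordinate)
  crypt <- tissue$slots[[i]]
  if (!crypt$alive) stop("cannot bifurcate a dead crypt")
  n <- length(crypt$cells)
  if (n < p$bifurcation_factor * p$crypt_size) {
    return(list(tissue = tissue, daughter = NULL))
  }
  nb <- hex_neighbors(coordinate[1], coordinate[2], p$grid_rows, p$grid_cols)
  dead <- which(vapply(seq_len(nrow(nb)), function(k) {
    !tissue$slots[[.slot_index(tissue, nb[k, ])]]$alive
  }, logical(1)))
  if (length(dead) == 0) {
    return(list(tissue = tissue, daughter = NULL))
  }
  target <- nb[dead[sample.int(length(dead), 1)], ]
  moving <- sample.int(n, n %/% 2)
  daughter <- new_crypt(crypt$cells[moving], target, created_time = time)
  crypt$cells <- crypt$cells[-moving]
  tissue$slots[[i]] <- crypt
  tissue$slots[[.slot_index(tissue, target)]] <- daughter
  tissue$current_time <- max(tissue$current_time, time)
  tissue$turnover <- rbind(tissue$turnover, data.frame(
    event = "crypt_birth", time = time,
    q = as.integer(target[[1]]), r = as.integer(target[[2]]),
    parent_q = as.integer(coordinate[1]), parent_r = as.integer(coordinate[2]),
    lifespan = NA_real_))
  list(tissue = tissue, daughter = as.integer(target))
}
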