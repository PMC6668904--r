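## Toroidal grid world: food growth/division/consumption and the two
## food-removal challenge schedules. The world is a mutable environment; food
## energies and organism counts are stored as width x height matrices indexed
## [x, y], addressed internally by linear cell index (y - 1) * width + x.

MOORE8 <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))

wrap1 <- function(v, n) ((v - 1L) %% n) + 1L

#' Create a toroidal grid world
#'
#' @param width,height Grid dimensions in cells.
#' @param n_food Number of initial food sources, placed on distinct uniform
#'   random cells with energies drawn uniformly from `energy_range`.
#' @param energy_range Storage range of a food source (energy units).
#' @param growth Energy gained by every source per step.
#' @return A world environment with fields `width`, `height`, `food`
#'   (energy matrix; 0 means no source), `occ` (organism count matrix),
#'   `energy_max`, `growth`.
#' @export
make_world <- function(width, height, n_food = 0L,
                       energy_range = c(10000, 20000), growth = 300) {
  stopifnot(width >= 1L, height >= 1L, n_food <= width * height)
  ## parent is baseenv(), not emptyenv(): the in-place mutation helpers
  ## evaluate subassignment calls inside this environment
  w <- new.env(parent = baseenv())
  w$width <- as.integer(width)
  w$height <- as.integer(height)
  w$food <- matrix(0, nrow = width, ncol = height)
  w$occ <- matrix(0L, nrow = width, ncol = height)
  w$energy_max <- energy_range[2]
  w$growth <- growth
  w$nbhd_cache <- list()
  if (n_food > 0L) {
    cells <- sample.int(width * height, n_food)
    w$food[cells] <- runif(n_food, energy_range[1], energy_range[2])
  }
  w
}

cell_index <- function(world, x, y) (y - 1L) * world$width + x

## Single-cell mutation helpers. Compiled code copies the whole matrix on
## `world$m[i] <- v` whenever the value's reference count exceeds one;
## interpreted subassignment via evalq() in the world environment stays on
## the in-place path, which matters at ~10^5 updates per simulation.
food_write <- function(world, ci, v) {
  world$.ci <- ci
  world$.v <- v
  evalq(food[.ci] <- .v, world)
  invisible(NULL)
}

occ_shift <- function(world, x, y, d) {
  world$.ci <- (y - 1L) * world$width + x
  world$.v <- d
  evalq(occ[.ci] <- occ[.ci] + .v, world)
  invisible(NULL)
}

## linear indices of the Moore neighborhood of radius r around (x, y),
## torus-wrapped; cells are deduplicated when the window exceeds the grid.
nbhd_index <- function(world, x, y, radius) {
  x <- as.integer(x); y <- as.integer(y); radius <- as.integer(radius)
  key <- as.character(radius)
  off <- world$nbhd_cache[[key]]
  if (is.null(off)) {
    d <- (-radius):radius
    off <- list(dx = rep(d, times = 2L * radius + 1L),
                dy = rep(d, each = 2L * radius + 1L))
    world$nbhd_cache[[key]] <- off
  }
  nx <- wrap1(x + off$dx, world$width)
  ny <- wrap1(y + off$dy, world$height)
  idx <- (ny - 1L) * world$width + nx
  if (2L * radius + 1L > min(world$width, world$height)) idx <- unique(idx)
  idx
}

#' Advance food dynamics by one step
#'
#' Every source gains the growth amount (default 300 units), clipped at the
#' storage maximum (20,000). Any source at the maximum divides: parent and
#' child each keep half the maximum (10,000), with the child placed in a
#' uniformly chosen food-free Moore-neighbour cell. If all eight neighbours
#' already hold food the division is deferred to a later step. Full sources
#' are processed in increasing cell-index order.
#'
#' @param world World environment.
#' @return The world, invisibly.
#' @export
step_food <- function(world) {
  idx <- which(world$food > 0)
  if (!length(idx)) return(invisible(world))
  world$food[idx] <- pmin(world$food[idx] + world$growth, world$energy_max)
  full <- idx[world$food[idx] >= world$energy_max]
  if (length(full)) {
    W <- world$width; H <- world$height
    half <- world$energy_max / 2
    for (ci in full) {
      x <- ((ci - 1L) %% W) + 1L
      y <- ((ci - 1L) %/% W) + 1L
      nx <- wrap1(x + MOORE8[, "dx"], W)
      ny <- wrap1(y + MOORE8[, "dy"], H)
      nidx <- (ny - 1L) * W + nx
      free <- nidx[world$food[nidx] <= 0]
      if (length(free)) {
        child <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
        food_write(world, ci, half)
        food_write(world, child, half)
      }
    }
  }
  invisible(world)
}

#' Create a food-removal schedule
#'
#' `dynamic`: once the total population has reached `pop_trigger` the
#' schedule arms permanently; thereafter, at every step that is a multiple
#' of `period`, a fraction of the current food sources is removed.
#' `fixed`: a single removal at step `fixed_step`. `none`: no removals.
#'
#' @param mode One of `"none"`, `"dynamic"`, `"fixed"`.
#' @param fraction Fraction of current sources removed per event, in \[0,1\].
#' @param period Steps between dynamic removals (default 60).
#' @param pop_trigger Population size that arms the dynamic schedule.
#' @param fixed_step Step of the single fixed removal (default 300).
#' @return A schedule environment.
#' @export
make_schedule <- function(mode = c("none", "dynamic", "fixed"), fraction = 0,
                          period = 60L, pop_trigger = 1000L, fixed_step = 300L) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1, period >= 1L)
  s <- new.env(parent = emptyenv())
  s$mode <- mode
  s$fraction <- fraction
  s$period <- as.integer(period)
  s$pop_trigger <- as.integer(pop_trigger)
  s$fixed_step <- as.integer(fixed_step)
  s$armed <- FALSE
  s$fired <- FALSE
  s
}

#' Apply scheduled food removal
#'
#' Removes `floor(fraction * N)` of the `N` current sources, chosen
#' uniformly without replacement, whenever the schedule calls for a removal
#' at this step (see [make_schedule()]).
#'
#' @param world World environment.
#' @param schedule Schedule environment.
#' @param step Current step index.
#' @param population_size Current total population (polyploids plus
#'   non-polyploids), used by the dynamic trigger.
#' @return Number of sources removed.
#' @export
remove_food <- function(world, schedule, step, population_size) {
  fire <- FALSE
  if (schedule$mode == "dynamic") {
    if (!schedule$armed && population_size >= schedule$pop_trigger) {
      schedule$armed <- TRUE
    }
    fire <- schedule$armed && step %% schedule$period == 0L
  } else if (schedule$mode == "fixed") {
    if (!schedule$fired && step == schedule$fixed_step) {
      schedule$fired <- TRUE
      fire <- TRUE
    }
  }
  if (!fire) return(0L)
  idx <- which(world$food > 0)
  k <- floor(schedule$fraction * length(idx))
  if (k > 0L) {
    sel <- if (length(idx) == 1L) idx else sample(idx, k)
    world$food[sel] <- 0
  }
  as.integer(k)
}

#' Consume the food source on a cell
#'
#' If a source occupies the cell its full energy is returned and the source
#' is removed; otherwise `NULL`.
#'
#' @param world World environment.
#' @param position Integer `c(x, y)` cell (1-based).
#' @return Energy units, or `NULL` when the cell is empty.
#' @export
consume_food_at <- function(world, position) {
  ci <- cell_index(world, as.integer(position[1]), as.integer(position[2]))
  e <- world$food[ci]
  if (e <= 0) return(NULL)
  food_write(world, ci, 0)
  e
}

#' Query the Moore neighborhood of a cell
#'
#' Returns the food sources and the organism count within Chebyshev radius
#' `radius` of `position` under toroidal wrap-around.
#'
#' @param world World environment.
#' @param position Integer `c(x, y)` cell.
#' @param radius Non-negative sensing radius (radius 0 is the cell itself).
#' @param exclude_self If `TRUE`, one organism on the centre cell (the
#'   querying organism) is excluded from the count.
#' @return List with `food` (data.frame `x`, `y`, `energy`) and `n_dos`
#'   (organism count).
#' @export
neighborhood <- function(world, position, radius, exclude_self = FALSE) {
  stopifnot(radius >= 0)
  idx <- nbhd_index(world, position[1], position[2], radius)
  e <- world$food[idx]
  has <- e > 0
  fi <- idx[has]
  food <- data.frame(
    x = ((fi - 1L) %% world$width) + 1L,
    y = ((fi - 1L) %/% world$width) + 1L,
    energy = e[has]
  )
  n_dos <- sum(world$occ[idx]) - if (exclude_self) 1L else 0L
  list(food = food, n_dos = n_dos)
}

#' Count food sources in the world
#'
#' @param world World environment.
#' @return Number of cells currently holding a food source.
#' @export
n_food_sources <- function(world) sum(world$food > 0)

#' Snapshot the world's food state
#'
#' Returns the current food sources as a tidy table (one row per source),
#' suitable for CSV export and debugging figures.
#'
#' @param world World environment.
#' @param step Optional step index recorded in the `step` column.
#' @return Data.frame with columns `step`, `x`, `y`, `energy`.
#' @export
food_snapshot <- function(world, step = NA_integer_) {
  idx <- which(world$food > 0)
  data.frame(
    step = rep.int(as.integer(step), length(idx)),
    x = ((idx - 1L) %% world$width) + 1L,
    y = ((idx - 1L) %/% world$width) + 1L,
    energy = world$food[idx]
  )
}
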