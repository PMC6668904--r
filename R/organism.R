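## The digital organism: a mutable environment holding genome, compiled GRN,
## concentration state, energy and position. Movement and replication are
## decided by the relative concentrations of the opposing structural gene
## products; exact ties fall to a fair coin.

#' Create a digital organism
#'
#' @param id Unique integer id.
#' @param genome Integer digit vector.
#' @param x,y Grid position (1-based).
#' @param energy Initial energy units.
#' @param ploidy Ploidy level (1 = non-polyploid).
#' @param decay_table Per-identity decay table (shared by the simulation).
#' @param parent_id Id of the parent, or `NA` for founders.
#' @param birth_step Step at which the organism was created.
#' @param genes Optional pre-parsed gene table (parsed from the genome when
#'   omitted).
#' @param grn Optional pre-compiled GRN structure (for clones sharing a
#'   genome).
#' @param bootstrap_value Initial concentration of the bootstrap TFs.
#' @param compile_grn If `FALSE` the genome is not parsed and no GRN is
#'   attached (used by the selection-free mode, where behaviour is
#'   irrelevant).
#' @return An organism environment.
#' @export
make_organism <- function(id, genome, x, y, energy, ploidy = 1L,
                          decay_table = NULL, parent_id = NA_integer_,
                          birth_step = 0L, genes = NULL, grn = NULL,
                          bootstrap_value = 10, compile_grn = TRUE) {
  o <- new.env(parent = emptyenv())
  o$id <- as.integer(id)
  o$parent_id <- as.integer(parent_id)
  o$genome <- genome
  o$ploidy <- as.integer(ploidy)
  o$energy <- energy
  o$x <- as.integer(x)
  o$y <- as.integer(y)
  o$birth_step <- as.integer(birth_step)
  o$alive <- TRUE
  o$stgd <- 0
  o$ltgd <- 0
  o$ed <- 0
  o$n_stable <- 0L
  if (compile_grn) {
    if (is.null(grn)) {
      if (is.null(genes)) genes <- scan_genes(genome)
      if (is.null(decay_table)) decay_table <- make_decay_table()
      grn <- grn_compile(genes, decay_table)
    }
    o$grn <- grn
    o$conc <- grn_init_conc(grn, bootstrap_value)
    o$mean_conc <- if (grn$m) mean(o$conc) else 0
  } else {
    o$grn <- NULL
    o$conc <- numeric(0)
    o$mean_conc <- 0
  }
  o
}

#' Read an organism's sensors
#'
#' Fills the fixed sensor vector (see [sensor_names()]): own energy, the
#' number of food sources and of *other* organisms within the Moore sensing
#' radius; reserved slots read zero.
#'
#' @param do Organism environment.
#' @param world World environment.
#' @param radius Sensing radius in cells.
#' @return Named numeric sensor vector.
#' @export
sense <- function(do, world, radius) {
  idx <- nbhd_index(world, do$x, do$y, radius)
  s <- numeric(WGD_N_SENSORS)
  s[1] <- do$energy
  s[2] <- sum(world$food[idx] > 0)
  s[3] <- sum(world$occ[idx]) - 1L
  names(s) <- sensor_names()
  s
}

conc_sum <- function(do, idx) if (length(idx)) sum(do$conc[idx]) else 0

#' Movement actuator
#'
#' The organism moves iff the summed concentration of movement-promoting
#' products exceeds that of movement-repressing products (fair coin on an
#' exact tie). The destination is the Moore neighbour nearest (by toroidal
#' shortest path) to the highest-energy food source within the sensing
#' radius, or a uniformly random neighbour when no food is sensed. A move
#' costs 70 energy units; not moving costs nothing.
#'
#' @param do Organism environment.
#' @param world World environment.
#' @param radius Sensing radius.
#' @param move_cost Energy cost per move.
#' @param idx Optional precomputed neighbourhood cell index (internal fast
#'   path; must match `radius`).
#' @return `TRUE` if the organism moved.
#' @export
act_move <- function(do, world, radius, move_cost = 70, idx = NULL) {
  cp <- conc_sum(do, do$grn$move_plus)
  cm <- conc_sum(do, do$grn$move_minus)
  go <- if (cp > cm) TRUE else if (cp < cm) FALSE else runif(1) < 0.5
  if (!go) return(FALSE)
  if (is.null(idx)) idx <- nbhd_index(world, do$x, do$y, radius)
  e <- world$food[idx]
  if (any(e > 0)) {
    ti <- idx[which.max(e)]
    tx <- ((ti - 1L) %% world$width) + 1L
    ty <- ((ti - 1L) %/% world$width) + 1L
    sx <- as.integer(sign(torus_delta(tx - do$x, world$width)))
    sy <- as.integer(sign(torus_delta(ty - do$y, world$height)))
    if (sx == 0L && sy == 0L) return(FALSE)
  } else {
    k <- sample.int(8L, 1L)
    sx <- MOORE8[k, "dx"]; sy <- MOORE8[k, "dy"]
  }
  occ_shift(world, do$x, do$y, -1L)
  do$x <- wrap1(do$x + sx, world$width)
  do$y <- wrap1(do$y + sy, world$height)
  occ_shift(world, do$x, do$y, 1L)
  do$energy <- do$energy - move_cost
  TRUE
}

## signed shortest displacement on a circle of size n
torus_delta <- function(d, n) {
  d <- d %% n
  ifelse(d > n / 2, d - n, d)
}

#' Feeding actuator
#'
#' If a food source occupies the organism's cell its full energy is
#' assimilated and the source is removed.
#'
#' @param do Organism environment.
#' @param world World environment.
#' @return Energy gained (0 when the cell was empty).
#' @export
act_eat <- function(do, world) {
  e <- consume_food_at(world, c(do$x, do$y))
  if (is.null(e)) return(0)
  do$energy <- do$energy + e
  e
}

#' Replication decision
#'
#' Replication requires the adaptation threshold (20,000 energy units by
#' default); above it, the decision follows the relative concentration of
#' the replication-promoting and -repressing structural products, with a
#' 50% chance on an exact tie.
#'
#' @param do Organism environment.
#' @param threshold Energy threshold.
#' @return Logical.
#' @export
decide_replicate <- function(do, threshold = 20000) {
  if (do$energy < threshold) return(FALSE)
  cp <- conc_sum(do, do$grn$repl_plus)
  cm <- conc_sum(do, do$grn$repl_minus)
  if (cp > cm) TRUE else if (cp < cm) FALSE else runif(1) < 0.5
}

#' Create the WGD operator state
#'
#' While active, every replication gives the offspring a `rate` chance of
#' whole-genome duplication. The operator is permanently removed once the
#' polyploid subpopulation has caught up with the non-polyploid one.
#'
#' @param rate WGD probability per replication (default 0.40).
#' @return A WGD-operator environment with fields `rate` and `active`.
#' @export
make_wgd_state <- function(rate = 0.4) {
  s <- new.env(parent = emptyenv())
  s$rate <- rate
  s$active <- TRUE
  s
}

#' Update the WGD operator
#'
#' Deactivates the operator, irreversibly, the first time the polyploid
#' count reaches the non-polyploid count (with at least one polyploid).
#'
#' @param wgd_state WGD operator environment.
#' @param n_polyploid,n_nonpolyploid Current subpopulation sizes.
#' @return `TRUE` if the operator is still active.
#' @export
update_wgd_operator <- function(wgd_state, n_polyploid, n_nonpolyploid) {
  stopifnot(n_polyploid >= 0, n_nonpolyploid >= 0)
  if (wgd_state$active && n_polyploid > 0 && n_polyploid >= n_nonpolyploid) {
    wgd_state$active <- FALSE
  }
  wgd_state$active
}

#' Replicate an organism
#'
#' The offspring inherits the parent's genome, first passing (while the WGD
#' operator is active) a Bernoulli draw at the WGD rate that duplicates the
#' whole genome and doubles ploidy, then the per-digit substitution
#' operator over the (possibly doubled) genome. The parent's energy is
#' split evenly between parent and offspring (or copied, under the
#' `"copy"` policy). The offspring is placed on a uniformly random Moore
#' neighbour cell, its GRN is compiled and bootstrapped, and its short- and
#' long-term genetic distances are recorded against the parent and the
#' founder genome.
#'
#' @param do Parent organism environment.
#' @param wgd_state WGD operator environment.
#' @param substitution_rate Per-digit substitution probability.
#' @param world World environment.
#' @param id Id to assign to the offspring.
#' @param decay_table Shared per-identity decay table.
#' @param founder Founder genome at time 0 (for the long-term distance).
#' @param step Current step (recorded as the offspring's birth step).
#' @param offspring_energy `"split"` (conserving, the default) or `"copy"`
#'   (the offspring duplicates the parent's energy).
#' @param bootstrap_value Bootstrap TF concentration.
#' @param compile_grn Passed to [make_organism()].
#' @return The offspring organism environment.
#' @export
replicate_organism <- function(do, wgd_state, substitution_rate, world, id,
                               decay_table = NULL, founder = NULL, step = 0L,
                               offspring_energy = c("split", "copy"),
                               bootstrap_value = 10, compile_grn = TRUE) {
  offspring_energy <- match.arg(offspring_energy)
  g <- do$genome
  ploidy <- do$ploidy
  if (wgd_state$active && runif(1) < wgd_state$rate) {
    g <- whole_genome_duplicate(g)
    ploidy <- ploidy * 2L
  }
  mut <- apply_substitutions(g, substitution_rate)
  g <- mut$genome

  if (offspring_energy == "split") {
    e <- do$energy / 2
    do$energy <- e
  } else {
    e <- do$energy
  }

  k <- sample.int(8L, 1L)
  nx <- wrap1(do$x + MOORE8[k, "dx"], world$width)
  ny <- wrap1(do$y + MOORE8[k, "dy"], world$height)

  child <- make_organism(
    id = id, genome = g, x = nx, y = ny, energy = e, ploidy = ploidy,
    decay_table = decay_table, parent_id = do$id, birth_step = step,
    bootstrap_value = bootstrap_value, compile_grn = compile_grn
  )
  child$stgd <- stgd(g, do$genome)
  if (!is.null(founder)) child$ltgd <- ltgd(g, founder)
  occ_shift(world, nx, ny, 1L)
  child
}
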