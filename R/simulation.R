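## Simulation orchestration: configuration, seeded sub-streams, the per-step
## loop (food growth -> scheduled removal -> shuffled agent updates -> WGD
## operator check -> metric logging -> stopping rules) and replicate
## experiment grids.

#' Build a simulation configuration
#'
#' Defaults are the full-scale study conditions: a 1000 x 1000 toroidal
#' grid, 200 clonal founders with 100 kb genomes, WGD rate 0.40,
#' substitution rate 1e-4 per digit per replication, movement cost 70,
#' replication threshold 20,000, population cap 20,000 and up to 2000
#' steps. See [desk_profile()] for the scaled-down preset.
#'
#' @param grid Integer `c(width, height)`.
#' @param n_do_init Number of clonal founder organisms.
#' @param n_food_init Number of initial food sources.
#' @param genome_length Founder genome length in digits.
#' @param wgd_rate WGD probability per replication while the operator is
#'   active.
#' @param substitution_rate Per-digit substitution probability per
#'   replication.
#' @param move_cost Energy cost of one move.
#' @param replication_threshold Energy needed to be allowed to replicate.
#' @param scenario Removal schedule: list with `mode`
#'   (`"none"`/`"dynamic"`/`"fixed"`), `fraction`, `period`, `pop_trigger`,
#'   `fixed_step`.
#' @param max_steps Maximum number of steps.
#' @param population_cap Population size at which a run is declared
#'   computationally intractable and stopped.
#' @param sensing_radius Moore sensing radius in cells.
#' @param grn_threshold Translation threshold on expression level.
#' @param grn_cap Concentration cap.
#' @param decay_range Uniform range of per-identity decay rates.
#' @param stability_window Consecutive low-ED steps required for stability
#'   (W).
#' @param ed_threshold Instability threshold on ED.
#' @param food_energy_range Storage range of food sources.
#' @param food_growth Food energy gain per step.
#' @param init_energy Founder energy.
#' @param offspring_energy `"split"` or `"copy"`.
#' @param bootstrap_tf_count,bootstrap_tf_value Bootstrap TF set size and
#'   initial concentration.
#' @param selection_free If `TRUE`, runs the neutral-drift mode: no world,
#'   no GRN, no energy bookkeeping; every organism replicates with
#'   probability 1/2 per step (the tie rule) until the cap. Used to check
#'   that mutation accumulation alone does not differ between ploidy
#'   classes.
#' @param stop_on_class_extinction End the run when one ploidy class goes
#'   extinct (armed only after the WGD operator has been removed, since the
#'   polyploid class is empty by construction at the start).
#' @param stop_at_equalization End the run at the first step where the
#'   polyploid count reaches the non-polyploid count.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @return A `wgd_config` list.
#' @export
sim_config <- function(grid = c(1000L, 1000L),
                       n_do_init = 200L,
                       n_food_init = 100L,
                       genome_length = 100000L,
                       wgd_rate = 0.4,
                       substitution_rate = 1e-4,
                       move_cost = 70,
                       replication_threshold = 20000,
                       scenario = list(mode = "none", fraction = 0,
                                       period = 60L, pop_trigger = 1000L,
                                       fixed_step = 300L),
                       max_steps = 2000L,
                       population_cap = 20000L,
                       sensing_radius = 5L,
                       grn_threshold = 1,
                       grn_cap = 100,
                       decay_range = c(0.05, 0.25),
                       stability_window = 10L,
                       ed_threshold = 0.3,
                       food_energy_range = c(10000, 20000),
                       food_growth = 300,
                       init_energy = 10000,
                       offspring_energy = "split",
                       bootstrap_tf_count = 12L,
                       bootstrap_tf_value = 10,
                       selection_free = FALSE,
                       stop_on_class_extinction = TRUE,
                       stop_at_equalization = FALSE,
                       master_seed = 1L) {
  scen_defaults <- list(mode = "none", fraction = 0, period = 60L,
                        pop_trigger = 1000L, fixed_step = 300L)
  scenario <- modifyList(scen_defaults, as.list(scenario))
  cfg <- list(
    grid = as.integer(grid), n_do_init = as.integer(n_do_init),
    n_food_init = as.integer(n_food_init),
    genome_length = as.integer(genome_length),
    wgd_rate = wgd_rate, substitution_rate = substitution_rate,
    move_cost = move_cost, replication_threshold = replication_threshold,
    scenario = scenario, max_steps = as.integer(max_steps),
    population_cap = as.integer(population_cap),
    sensing_radius = as.integer(sensing_radius),
    grn_threshold = grn_threshold, grn_cap = grn_cap,
    decay_range = decay_range,
    stability_window = as.integer(stability_window),
    ed_threshold = ed_threshold,
    food_energy_range = food_energy_range, food_growth = food_growth,
    init_energy = init_energy, offspring_energy = offspring_energy,
    bootstrap_tf_count = as.integer(bootstrap_tf_count),
    bootstrap_tf_value = bootstrap_tf_value,
    selection_free = isTRUE(selection_free),
    stop_on_class_extinction = isTRUE(stop_on_class_extinction),
    stop_at_equalization = isTRUE(stop_at_equalization),
    master_seed = as.integer(master_seed)
  )
  class(cfg) <- "wgd_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `wgd_config` list.
#' @return The config, invisibly; errors on invalid values.
#' @export
validate_config <- function(config) {
  stopifnot(
    length(config$grid) == 2L, all(config$grid >= 1L),
    config$n_do_init >= 1L, config$n_food_init >= 0L,
    config$genome_length >= 1L,
    config$wgd_rate >= 0, config$wgd_rate <= 1,
    config$substitution_rate >= 0, config$substitution_rate <= 1,
    config$move_cost >= 0, config$replication_threshold > 0,
    config$max_steps >= 0L, config$population_cap >= 1L,
    config$sensing_radius >= 0L, config$grn_cap > 0,
    length(config$decay_range) == 2L,
    config$decay_range[1] > 0, config$decay_range[2] < 1,
    config$stability_window >= 1L, config$ed_threshold >= 0,
    config$offspring_energy %in% c("split", "copy")
  )
  sc <- config$scenario
  stopifnot(sc$mode %in% c("none", "dynamic", "fixed"),
            sc$fraction >= 0, sc$fraction <= 1,
            sc$period >= 1L, sc$pop_trigger >= 1L, sc$fixed_step >= 0L)
  invisible(config)
}

#' Scaled-down desk preset
#'
#' The desk profile used for routine runs and tests: a 500 x 500 grid,
#' 20 kb founder genomes, a 2000-organism cap and up to 1000 steps, with
#' all other study conditions unchanged. The grid is sized so that the
#' sensing neighbourhoods of a trigger-sized population (1000 organisms,
#' radius 5) cover only about half the grid: food can then keep outgrowing
#' consumption through the removal trigger, preserving the full-scale
#' regime in which food persists in stable environments and scarcity is
#' introduced only by the removal schedule.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `wgd_config` list.
#' @export
desk_profile <- function(...) {
  dots <- list(...)
  base <- list(grid = c(500L, 500L), population_cap = 2000L,
               max_steps = 1000L, genome_length = 20000L)
  do.call(sim_config, modifyList(base, dots))
}

#' Read and write configuration files
#'
#' Configurations serialize to a YAML document mirroring the
#' [sim_config()] field names; unknown keys are rejected on read.
#'
#' @param config A `wgd_config` list.
#' @param path File path.
#' @return `read_config` returns a `wgd_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, x)
}

## ---------------------------------------------------------------------------
## Named random sub-streams: the master seed derives one stream per
## subsystem (genome generation, world, agents, scheduler) so that, e.g.,
## extra world randomness never perturbs agent trajectories.

make_streams <- function(master_seed, names = c("genome", "world", "agents",
                                                "scheduler", "experiment")) {
  prev <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(prev))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  st <- new.env(parent = emptyenv())
  st$streams <- list()
  for (i in seq_along(names)) {
    set.seed(seeds[i])
    st$streams[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  st
}

restore_seed <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", prev, envir = globalenv())
  }
}

with_stream <- function(st, name, expr) {
  prev <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", st$streams[[name]], envir = globalenv())
  on.exit({
    st$streams[[name]] <- get(".Random.seed", envir = globalenv())
    restore_seed(prev)
  })
  expr
}

## ---------------------------------------------------------------------------

#' Run one simulation
#'
#' Executes the per-step loop -- food growth, scheduled removal, shuffled
#' agent updates (sense, GRN step, eat, move, replication), WGD-operator
#' check, metric logging -- until a stopping rule fires: all steps done,
#' total extinction, one-class extinction (once the WGD operator has been
#' removed), or the population cap. Fully deterministic given
#' `config$master_seed`.
#'
#' @param config A `wgd_config` from [sim_config()] or [desk_profile()].
#' @param record If `TRUE`, collect one step record per living organism per
#'   step (position, ploidy class, energy, STGD, LTGD, ED, adapted/stable
#'   flags).
#' @param out_dir Optional directory; when given, the step records and
#'   per-step class counts are written as `records.csv` and `counts.csv`.
#' @param grn_trace Optional file path; when given, one JSON line per
#'   living organism per step is appended with its non-zero product
#'   concentrations (`{"step":..,"do_id":..,"conc":{"<identity>":value}}`).
#'   Tracing never consumes randomness, so it cannot perturb trajectories.
#' @return A `wgd_run` list: `end_step`, `end_cause`, `n_polyploid`,
#'   `n_nonpolyploid`, `equalization_step` (first step with polyploids at
#'   least as numerous as non-polyploids, or `NA`), `wgd_removed_step`,
#'   `counts` (per-step data.frame), `records` (step records or `NULL`),
#'   `founder` (the time-0 genome), `config`, `paths`.
#' @export
run_simulation <- function(config, record = TRUE, out_dir = NULL,
                           grn_trace = NULL) {
  validate_config(config)
  st <- make_streams(config$master_seed)
  trace_con <- NULL
  if (!is.null(grn_trace)) {
    trace_con <- file(grn_trace, open = "wt")
    on.exit(close(trace_con), add = TRUE)
  }

  ## --- initialization -----------------------------------------------------
  genome_init <- with_stream(st, "genome", {
    decay_table <- make_decay_table(range = config$decay_range)
    founder <- random_viable_genome(
      config$genome_length,
      requirements = default_viability_requirements(config$genome_length)
    )
    list(decay_table = decay_table, founder = founder)
  })
  decay_table <- genome_init$decay_table
  founder <- genome_init$founder

  world <- with_stream(st, "world", {
    make_world(config$grid[1], config$grid[2], n_food = config$n_food_init,
               energy_range = config$food_energy_range,
               growth = config$food_growth)
  })
  schedule <- make_schedule(config$scenario$mode, config$scenario$fraction,
                            config$scenario$period, config$scenario$pop_trigger,
                            config$scenario$fixed_step)
  wgd_state <- make_wgd_state(config$wgd_rate)

  light <- config$selection_free
  founder_genes <- if (!light) scan_genes(founder) else NULL
  founder_grn <- if (!light) grn_compile(founder_genes, decay_table) else NULL

  cap <- config$population_cap
  pop <- new.env(parent = emptyenv())
  pop$dos <- vector("list", max(256L, config$n_do_init))
  pop$n <- 0L
  pop$alive <- integer(0)

  add_organism <- function(o) {
    if (pop$n == length(pop$dos)) {
      pop$dos <- c(pop$dos, vector("list", length(pop$dos)))
    }
    pop$n <- pop$n + 1L
    pop$dos[[pop$n]] <- o
    pop$alive <- c(pop$alive, pop$n)
    o
  }

  with_stream(st, "agents", {
    for (i in seq_len(config$n_do_init)) {
      x <- sample.int(world$width, 1L)
      y <- sample.int(world$height, 1L)
      o <- make_organism(
        id = i, genome = founder, x = x, y = y,
        energy = config$init_energy, ploidy = 1L,
        genes = founder_genes, grn = founder_grn,
        bootstrap_value = config$bootstrap_tf_value,
        compile_grn = !light
      )
      occ_shift(world, x, y, 1L)
      add_organism(o)
    }
  })

  ## --- bookkeeping --------------------------------------------------------
  radius <- config$sensing_radius
  thr <- config$grn_threshold
  ccap <- config$grn_cap
  repl_thr <- config$replication_threshold
  ed_thr <- config$ed_threshold
  W_stable <- config$stability_window

  records <- if (record) vector("list", config$max_steps) else NULL
  counts <- matrix(0L, nrow = config$max_steps, ncol = 4L,
                   dimnames = list(NULL, c("step", "n_polyploid",
                                           "n_nonpolyploid", "n_food")))
  eq_step <- NA_integer_
  wgd_removed_step <- NA_integer_
  end_cause <- "max_steps"
  end_step <- 0L

  alive_idx <- function() pop$alive

  sensor_buf <- numeric(WGD_N_SENSORS)

  update_one <- function(o, n_alive_now) {
    idx <- nbhd_index(world, o$x, o$y, radius)
    sensors <- sensor_buf
    sensors[1] <- o$energy
    sensors[2] <- sum(world$food[idx] > 0)
    sensors[3] <- sum(world$occ[idx]) - 1L
    conc <- grn_step_fast(o$grn, o$conc, sensors, thr, ccap)
    m_t <- if (length(conc)) mean(conc) else 0
    o$ed <- ed_from_means(m_t, o$mean_conc)
    o$mean_conc <- m_t
    o$conc <- conc
    o$n_stable <- if (o$ed <= ed_thr) o$n_stable + 1L else 0L
    act_eat(o, world)
    act_move(o, world, radius, config$move_cost, idx = idx)
    if (o$energy < 0) {
      kill_organism(o, world)
      pop$alive <- pop$alive[pop$alive != o$id]
      return(0L)
    }
    if (n_alive_now < cap && decide_replicate(o, repl_thr)) {
      child <- replicate_organism(
        o, wgd_state, config$substitution_rate, world,
        id = pop$n + 1L, decay_table = decay_table, founder = founder,
        step = step_now, offspring_energy = config$offspring_energy,
        bootstrap_value = config$bootstrap_tf_value
      )
      add_organism(child)
      return(1L)
    }
    0L
  }

  update_one_light <- function(o, n_alive_now) {
    ## neutral-drift mode: replication only, at the tie probability
    if (n_alive_now < cap && runif(1) < 0.5) {
      child <- replicate_organism(
        o, wgd_state, config$substitution_rate, world,
        id = pop$n + 1L, decay_table = decay_table, founder = founder,
        step = step_now, offspring_energy = "copy",
        compile_grn = FALSE
      )
      add_organism(child)
      return(1L)
    }
    0L
  }

  step_now <- 0L

  ## --- main loop ----------------------------------------------------------
  for (t in seq_len(config$max_steps)) {
    step_now <- t
    alive <- alive_idx()
    n_alive <- length(alive)

    if (!light) {
      with_stream(st, "world", {
        step_food(world)
        remove_food(world, schedule, t, n_alive)
      })
    }

    ord <- with_stream(st, "scheduler", {
      if (n_alive > 1L) alive[sample.int(n_alive)] else alive
    })

    with_stream(st, "agents", {
      n_now <- n_alive
      for (i in ord) {
        o <- pop$dos[[i]]
        if (is.null(o) || !o$alive) next
        n_now <- n_now +
          if (light) update_one_light(o, n_now) else update_one(o, n_now)
      }
    })

    alive <- alive_idx()
    ploidy <- vapply(pop$dos[alive], function(o) o$ploidy, integer(1))
    n_poly <- sum(ploidy >= 2L)
    n_nonpoly <- length(ploidy) - n_poly

    update_wgd_operator(wgd_state, n_poly, n_nonpoly)
    if (!wgd_state$active && is.na(wgd_removed_step)) wgd_removed_step <- t
    if (is.na(eq_step) && n_poly > 0L && n_poly >= n_nonpoly) eq_step <- t

    counts[t, ] <- c(t, n_poly, n_nonpoly, n_food_sources(world))

    if (record) records[[t]] <- step_records(pop, alive, t, repl_thr, W_stable)
    if (!is.null(trace_con)) writeLines(grn_trace_lines(pop, alive, t), trace_con)

    end_step <- t
    if (length(alive) == 0L) { end_cause <- "extinction_all"; break }
    if (config$stop_on_class_extinction && !wgd_state$active &&
        (n_poly == 0L || n_nonpoly == 0L)) {
      end_cause <- "extinction_one_class"; break
    }
    if (length(alive) >= cap) { end_cause <- "population_explosion"; break }
    if (config$stop_at_equalization && !is.na(eq_step)) {
      end_cause <- "equalization"; break
    }
  }

  alive <- alive_idx()
  ploidy <- vapply(pop$dos[alive], function(o) o$ploidy, integer(1))
  res <- list(
    end_step = end_step,
    end_cause = end_cause,
    n_polyploid = sum(ploidy >= 2L),
    n_nonpolyploid = sum(ploidy == 1L),
    equalization_step = eq_step,
    wgd_removed_step = wgd_removed_step,
    counts = as.data.frame(counts[seq_len(end_step), , drop = FALSE]),
    records = if (record && end_step > 0L) {
      do.call(rbind, records[seq_len(end_step)])
    } else if (record) {
      step_records(pop, alive, 0L, repl_thr, W_stable)[0, ]
    } else NULL,
    founder = founder,
    config = config,
    paths = NULL
  )
  class(res) <- "wgd_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(counts = file.path(out_dir, "counts.csv"))
    write.csv(res$counts, paths$counts, row.names = FALSE)
    if (record) {
      paths$records <- file.path(out_dir, "records.csv")
      write.csv(res$records, paths$records, row.names = FALSE)
    }
    res$paths <- paths
  }
  res
}

kill_organism <- function(o, world) {
  o$alive <- FALSE
  occ_shift(world, o$x, o$y, -1L)
  ## release the heavy per-organism state; scalar fields stay for the logs
  o$genome <- NULL
  o$grn <- NULL
  o$conc <- NULL
}

step_records <- function(pop, alive, step, repl_thr, W_stable) {
  n <- length(alive)
  id <- integer(n); parent <- integer(n); ploidy <- integer(n)
  x <- integer(n); y <- integer(n); energy <- numeric(n)
  stgd_v <- numeric(n); ltgd_v <- numeric(n); ed <- numeric(n)
  nst <- integer(n)
  for (j in seq_len(n)) {
    o <- pop$dos[[alive[j]]]
    id[j] <- o$id; parent[j] <- o$parent_id; ploidy[j] <- o$ploidy
    x[j] <- o$x; y[j] <- o$y; energy[j] <- o$energy
    stgd_v[j] <- o$stgd; ltgd_v[j] <- o$ltgd; ed[j] <- o$ed
    nst[j] <- o$n_stable
  }
  data.frame(
    step = rep.int(step, n), do_id = id, parent_id = parent,
    ploidy = ploidy,
    ploidy_class = ifelse(ploidy >= 2L, "polyploid", "non_polyploid"),
    x = x, y = y,
    energy = energy, stgd = stgd_v, ltgd = ltgd_v, ed = ed,
    adapted = energy >= repl_thr, stable = nst >= W_stable
  )
}

grn_trace_lines <- function(pop, alive, step) {
  lines <- character(length(alive))
  for (j in seq_along(alive)) {
    o <- pop$dos[[alive[j]]]
    body <- ""
    if (!is.null(o$grn)) {
      nz <- which(o$conc > 0)
      if (length(nz)) {
        body <- paste0('"', o$grn$ids[nz], '":',
                       formatC(o$conc[nz], format = "g", digits = 15),
                       collapse = ",")
      }
    }
    lines[j] <- paste0('{"step":', step, ',"do_id":', o$id,
                       ',"conc":{', body, '}}')
  }
  lines
}

#' Print a simulation result
#'
#' @param x A `wgd_run`.
#' @param ... Ignored.
#' @export
print.wgd_run <- function(x, ...) {
  cat("<wgd_run> ", x$end_step, " steps (", x$end_cause, "); ",
      x$n_polyploid, " polyploid / ", x$n_nonpolyploid,
      " non-polyploid organisms alive",
      if (!is.na(x$equalization_step)) {
        paste0("; ploidy classes equalized at step ", x$equalization_step)
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' First step at which the ploidy classes equalize
#'
#' Scans a per-step class-count table for the first step at which the
#' polyploid count reaches the non-polyploid count (with at least one
#' polyploid alive).
#'
#' @param counts Data.frame with columns `step`, `n_polyploid`,
#'   `n_nonpolyploid`, as in the `counts` element of a `wgd_run`.
#' @return Step index, or `NA` if the classes never equalize.
#' @export
equalization_step <- function(counts) {
  hit <- which(counts$n_polyploid > 0L &
               counts$n_polyploid >= counts$n_nonpolyploid)
  if (length(hit)) counts$step[hit[1]] else NA_integer_
}

#' Run a replicate experiment grid
#'
#' Runs `n_replicates` simulations at each food-reduction level and
#' tabulates the end states into outcome fractions (the layout of the
#' dynamic- and fixed-scenario summary tables).
#'
#' @param config Base configuration; each run gets `scenario$fraction` set
#'   to the level and its own master seed.
#' @param reduction_levels Numeric vector of removal fractions.
#' @param n_replicates Replicates per level.
#' @param seeds Optional integer matrix/vector of per-run seeds
#'   (`length(reduction_levels) * n_replicates`); derived from
#'   `config$master_seed` when omitted.
#' @param record Forwarded to [run_simulation()] (step records are dropped
#'   from the returned object either way; set `keep_runs = TRUE` to retain
#'   full results).
#' @param keep_runs Keep the individual `wgd_run` objects.
#' @return List with `runs` (one row per simulation: level, seed, end step
#'   and cause, final counts, equalization step), `summary` (from
#'   [summarize_experiment()]) and optionally `results`.
#' @export
run_experiment <- function(config, reduction_levels, n_replicates,
                           seeds = NULL, record = FALSE, keep_runs = FALSE) {
  stopifnot(n_replicates >= 1L, length(reduction_levels) >= 1L)
  n_total <- length(reduction_levels) * n_replicates
  if (is.null(seeds)) {
    st <- make_streams(config$master_seed)
    seeds <- with_stream(st, "experiment",
                         sample.int(.Machine$integer.max - 1L, n_total))
  }
  stopifnot(length(seeds) == n_total)

  rows <- vector("list", n_total)
  results <- if (keep_runs) vector("list", n_total) else NULL
  k <- 0L
  for (lv in reduction_levels) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      cfg <- config
      cfg$scenario$fraction <- lv
      cfg$master_seed <- seeds[k]
      res <- tryCatch(run_simulation(cfg, record = record),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[k]] <- data.frame(
          reduction = lv, replicate = r, seed = seeds[k],
          end_step = NA_integer_, end_cause = "run_failure",
          n_polyploid = NA_integer_, n_nonpolyploid = NA_integer_,
          equalization_step = NA_integer_,
          error = conditionMessage(res)
        )
        next
      }
      if (keep_runs) results[[k]] <- res
      rows[[k]] <- data.frame(
        reduction = lv, replicate = r, seed = seeds[k],
        end_step = res$end_step, end_cause = res$end_cause,
        n_polyploid = res$n_polyploid, n_nonpolyploid = res$n_nonpolyploid,
        equalization_step = res$equalization_step,
        error = NA_character_
      )
    }
  }
  runs <- do.call(rbind, rows)
  ok <- runs$end_cause != "run_failure"
  summary <- if (any(ok)) summarize_experiment(runs[ok, , drop = FALSE]) else NULL
  out <- list(runs = runs, summary = summary)
  if (keep_runs) out$results <- results
  out
}
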