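tiny_config <- function(...) {
  args <- modifyList(
    list(grid = c(40L, 40L), n_do_init = 20L, n_food_init = 10L,
         genome_length = 8000L, population_cap = 200L,
         max_steps = 30L, master_seed = 42L),
    list(...)
  )
  do.call(desk_profile, args)
}

test_that("configurations validate, serialize and reject unknown keys", {
  cfg <- desk_profile(master_seed = 9L)
  expect_s3_class(cfg, "wgd_config")
  expect_identical(cfg$grid, c(500L, 500L))
  expect_identical(cfg$genome_length, 20000L)
  expect_identical(cfg$population_cap, 2000L)

  expect_error(sim_config(wgd_rate = 1.4))
  expect_error(sim_config(substitution_rate = -1))
  expect_error(sim_config(scenario = list(mode = "sometimes")))
  expect_error(sim_config(offspring_energy = "duplicate"))

  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)

  bad <- yaml::read_yaml(path)
  bad$frobnicate <- 1
  yaml::write_yaml(bad, path)
  expect_error(read_config(path), "unknown configuration keys")
})

test_that("a zero-step run returns the initial population untouched", {
  cfg <- tiny_config(max_steps = 0L)
  res <- run_simulation(cfg)
  expect_identical(res$end_step, 0L)
  expect_identical(res$end_cause, "max_steps")
  expect_identical(res$n_nonpolyploid, 20L)
  expect_identical(res$n_polyploid, 0L)
  expect_identical(nrow(res$counts), 0L)
})

test_that("identical master seeds reproduce a run exactly", {
  cfg <- tiny_config(max_steps = 25L)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$founder, r2$founder)
  expect_identical(r1$end_cause, r2$end_cause)

  r3 <- run_simulation(tiny_config(max_steps = 25L, master_seed = 43L))
  expect_false(identical(r1$records, r3$records))
})

test_that("starvation without food drives the population extinct, not instantly", {
  cfg <- tiny_config(n_food_init = 0L, init_energy = 350, move_cost = 70,
                     max_steps = 400L, master_seed = 7L)
  res <- run_simulation(cfg)
  expect_identical(res$end_cause, "extinction_all")
  expect_identical(res$n_polyploid + res$n_nonpolyploid, 0L)
  ## nobody can die before spending the whole store: >= ceiling(350/70) steps
  expect_gte(res$end_step, 5L)
})

test_that("every living organism logs exactly one record per step", {
  cfg <- tiny_config(max_steps = 20L, master_seed = 11L)
  res <- run_simulation(cfg)
  per_step <- table(res$records$step)
  by_counts <- res$counts$n_polyploid + res$counts$n_nonpolyploid
  expect_identical(as.integer(per_step), by_counts[by_counts > 0])
  ## no organism appears twice in a step
  expect_false(any(duplicated(res$records[c("step", "do_id")])))
  ## adapted flag mirrors the energy threshold
  expect_identical(res$records$adapted, res$records$energy >= 20000)
})

test_that("equalization is the first step where polyploids draw level", {
  counts <- data.frame(step = 1:3, n_polyploid = c(0L, 50L, 100L),
                       n_nonpolyploid = c(200L, 150L, 100L))
  expect_identical(equalization_step(counts), 3L)
  none <- data.frame(step = 1:3, n_polyploid = c(0L, 0L, 0L),
                     n_nonpolyploid = c(200L, 150L, 100L))
  expect_identical(equalization_step(none), NA_integer_)
  ## an extinct population does not count as equalized
  dead <- data.frame(step = 1:2, n_polyploid = c(0L, 0L),
                     n_nonpolyploid = c(5L, 0L))
  expect_identical(equalization_step(dead), NA_integer_)
})

test_that("the neutral-drift mode grows a mixed-ploidy population to the cap", {
  cfg <- tiny_config(selection_free = TRUE, population_cap = 150L,
                     max_steps = 25L, master_seed = 13L)
  res <- run_simulation(cfg)
  expect_identical(res$end_cause, "population_explosion")
  expect_gte(res$n_polyploid + res$n_nonpolyploid, 150L)
  expect_gt(res$n_polyploid, 0L)
  born <- res$records[res$records$do_id > 20L, ]
  expect_gt(nrow(born), 0L)
  expect_true(all(born$stgd >= 0))
  ## ploidy is a power of two
  expect_true(all(bitwAnd(res$records$ploidy, res$records$ploidy - 1L) == 0L))
})

test_that("the GRN trace writes one parseable JSON line per organism per step", {
  skip_if_not_installed("jsonlite")
  cfg <- tiny_config(max_steps = 8L, master_seed = 19L)
  tr <- tempfile(fileext = ".jsonl")
  res <- run_simulation(cfg, record = TRUE, grn_trace = tr)
  lines <- readLines(tr)
  expect_identical(length(lines), nrow(res$records))
  one <- jsonlite::fromJSON(lines[1])
  expect_identical(one$step, 1L)
  expect_true(all(unlist(one$conc) >= 0))
  ## identities are valid keys
  expect_true(all(as.integer(names(one$conc)) %in% 0:999))

  ## tracing does not perturb the trajectory
  res2 <- run_simulation(cfg, record = TRUE)
  expect_identical(res$records, res2$records)
})

test_that("the population log carries lineage and position columns", {
  cfg <- tiny_config(max_steps = 10L, master_seed = 23L)
  res <- run_simulation(cfg)
  expect_true(all(c("step", "do_id", "parent_id", "ploidy", "ploidy_class",
                    "x", "y", "energy", "stgd", "ltgd", "ed", "adapted",
                    "stable") %in% names(res$records)))
  founders <- res$records[res$records$do_id <= 20L, ]
  expect_true(all(is.na(founders$parent_id)))
  expect_true(all(res$records$x >= 1L & res$records$x <= 40L))

  ## the food snapshot mirrors the world state
  w <- make_world(10L, 10L)
  w$food[5, 7] <- 12345
  snap <- food_snapshot(w, step = 3L)
  expect_identical(snap$x, 5L)
  expect_identical(snap$y, 7L)
  expect_identical(snap$energy, 12345)
  expect_identical(snap$step, 3L)
})

test_that("replicate experiments tabulate outcome fractions per level", {
  cfg <- tiny_config(max_steps = 10L)
  ex <- run_experiment(cfg, reduction_levels = c(0, 0.5), n_replicates = 2L)
  expect_identical(nrow(ex$runs), 4L)
  expect_identical(ex$summary$n_simulations, c(2L, 2L))
  expect_equal(rowSums(ex$summary[, c("extinction", "polyploid_larger",
                                      "non_polyploid_larger", "tie")]),
               c(1, 1), ignore_attr = TRUE)
  ## distinct seeds produce distinct trajectories in general
  expect_false(identical(ex$runs$seed[1], ex$runs$seed[2]))
})
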