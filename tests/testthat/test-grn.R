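## a toy genome with n distinct regulatory genes plus a polymerase
reg_panel_genome <- function(n_reg) {
  payloads <- sprintf("%s0", vapply(seq_len(n_reg) - 1L, int_to_word, character(1)))
  genes <- vapply(payloads, function(p) build_gene("regulatory", payload = p),
                  character(1))
  as_digits(paste(genes, collapse = ""), build_gene("polymerase"))
}

test_that("bootstrap activates the first 12 regulatory products only", {
  g20 <- reg_panel_genome(20L)
  genes <- scan_genes(g20)
  conc <- bootstrap_tfs(genes, value = 10)
  expect_identical(sum(conc > 0), 12L)
  expect_true(all(conc[conc > 0] == 10))
  reg_ids <- genes$identity[genes$kind == "regulatory"]
  expect_setequal(names(conc)[conc > 0], as.character(reg_ids[1:12]))

  ## fewer than 12 regulatory genes: all of them activate
  g3 <- reg_panel_genome(3L)
  conc3 <- bootstrap_tfs(scan_genes(g3), value = 10)
  expect_identical(sum(conc3 > 0), 3L)

  ## no regulatory genes: nothing activates
  g0 <- as_digits(build_gene("polymerase"))
  conc0 <- bootstrap_tfs(scan_genes(g0), value = 10)
  expect_true(all(conc0 == 0))

  ## deterministic
  expect_identical(bootstrap_tfs(genes, 10), bootstrap_tfs(genes, 10))
})

test_that("signaling equations floor and reduce their weighted sums mod 1000", {
  sensors <- c(2, 3, 0, 0, 0, 0, 0, 0)
  eq <- cbind(addr = c(0L, 1L, 0L), weight = c(5L, 2L, 1L))
  expect_identical(evaluate_signaling(list(eq), sensors), 18L)

  zero <- cbind(addr = c(0L, 1L, 2L), weight = c(0L, 0L, 0L))
  expect_identical(evaluate_signaling(list(zero), sensors), 0L)

  ## overflow wraps: 1023 -> 23; negatives wrap into 0..999
  big <- cbind(addr = 0L, weight = 1L)
  expect_identical(evaluate_signaling(list(big), c(1023, rep(0, 7))), 23L)
  neg <- cbind(addr = 0L, weight = -1L)
  expect_identical(evaluate_signaling(list(neg), c(1, rep(0, 7))), 999L)

  ## fractional sums are floored before reduction
  expect_identical(evaluate_signaling(list(big), c(17.9, rep(0, 7))), 17L)
})

test_that("signaling increments add one unit per hit to encoded products", {
  conc <- setNames(c(5, 0, 2), c("18", "44", "700"))
  encoded <- c(18L, 44L, 700L)
  expect_identical(apply_signaling(conc, 18L, encoded)[["18"]], 6)
  ## unknown identity leaves the table unchanged
  expect_identical(apply_signaling(conc, 999L, encoded), conc)
  ## repeated hits accumulate
  expect_identical(apply_signaling(conc, c(44L, 44L), encoded)[["44"]], 2)
  ## the cap binds
  expect_identical(apply_signaling(conc, 18L, encoded, cap = 5.5)[["18"]], 5.5)
})

test_that("expression level is the polymerase-gated signed sum of bound TFs", {
  specs <- data.frame(
    identity = c(10L, 20L, 30L),
    kind = c("regulatory", "regulatory", "polymerase"),
    sign = c(1L, -1L, NA),
    target = c(word_value_of("2231"), word_value_of("0120"), NA),
    decay = c(0.1, 0.1, 0.1)
  )
  gene_act <- list(cis = word_value_of("2231"))

  conc <- setNames(c(5, 7, 1), c("10", "20", "30"))
  expect_identical(expression_level(gene_act, conc, specs), 5)

  ## no polymerase product present: gated to zero
  conc0 <- setNames(c(5, 7, 0), c("10", "20", "30"))
  expect_identical(expression_level(gene_act, conc0, specs), 0)

  ## activator 5 and repressor 7 on one promoter: net -2
  gene_both <- list(cis = c(word_value_of("2231"), word_value_of("0120")))
  expect_identical(expression_level(gene_both, conc, specs), -2)

  ## repeated cis words count with multiplicity
  gene_rep <- list(cis = rep(word_value_of("2231"), 3))
  expect_identical(expression_level(gene_rep, conc, specs), 15)
})

test_that("the GRN step decays, increments, expresses and translates in order", {
  ## pure decay: no genes expressed, one product at 10 with decay 0.1
  specs <- data.frame(identity = 7L, kind = "signaling", sign = NA_integer_,
                      target = NA_integer_, decay = 0.1)
  genes <- scan_genes(integer(0))
  st <- list(conc = setNames(10, "7"), step = 0L)
  out <- step_grn(genes, st, numeric(8), specs)
  expect_equal(out$conc[["7"]], 9.0)
  expect_identical(out$step, 1L)

  ## a gene whose level stays below threshold only decays
  g <- as_digits(build_gene("polymerase"), build_tf_gene("2231"))
  gt <- scan_genes(g)
  dt <- rep(0.2, 1000)
  sp <- product_specs(gt, dt)
  st <- list(conc = bootstrap_tfs(gt, 0), step = 0L)
  out <- step_grn(gt, st, numeric(8), sp)
  expect_true(all(out$conc == 0))
})

test_that("constant expression converges to the level/decay fixed point", {
  ## one target gene with an activator cis; TF and polymerase concentrations
  ## are replenished externally every step, so the level is constant at 10
  g <- as_digits(build_gene("movement", cis = rep("2231", 5), payload = "13210"),
                 build_tf_gene("2231"), build_gene("polymerase"))
  genes <- scan_genes(g)
  dt <- rep(0.2, 1000)
  specs <- product_specs(genes, dt)
  tf_id <- as.character(genes$identity[genes$kind == "regulatory"])
  poly_id <- as.character(genes$identity[genes$kind == "polymerase"])
  target_id <- as.character(genes$identity[genes$kind == "movement"])
  st <- list(conc = bootstrap_tfs(genes, 0), step = 0L)
  for (i in 1:200) {
    ## replenished to 2.5, decayed to 2.0 before the expression stage,
    ## so the level is constant at 5 cis words * 2.0 = 10
    st$conc[tf_id] <- 2.5
    st$conc[poly_id] <- 1
    st <- step_grn(genes, st, numeric(8), specs)
  }
  ## fixed point c* = L / d = 10 / 0.2 = 50
  expect_equal(unname(st$conc[target_id]), 10 / 0.2, tolerance = 1e-6)
})

test_that("concentrations stay within [0, cap] and decay-only states never rise", {
  set.seed(301)
  for (i in 1:5) {
    g <- random_genome(4000)
    genes <- scan_genes(g)
    dt <- make_decay_table()
    grn <- wgdsim:::grn_compile(genes, dt)
    conc <- wgdsim:::grn_init_conc(grn, 10)
    for (t in 1:50) {
      sensors <- c(runif(1, 0, 30000), sample(0:5, 1), sample(0:5, 1), rep(0, 5))
      conc <- wgdsim:::grn_step_fast(grn, conc, sensors, 1, 100)
      expect_true(all(conc >= 0 & conc <= 100))
    }
  }

  ## decay-only: strip signaling genes, keep polymerase off
  g <- as_digits(build_tf_gene("2231"), build_tf_gene("0120", FALSE))
  genes <- scan_genes(g)
  dt <- make_decay_table()
  grn <- wgdsim:::grn_compile(genes, dt)
  conc <- wgdsim:::grn_init_conc(grn, 10)
  for (t in 1:20) {
    nxt <- wgdsim:::grn_step_fast(grn, conc, numeric(8), 1, 100)
    expect_true(all(nxt <= conc))
    conc <- nxt
  }
})

test_that("the fast simulation kernel matches the reference GRN operations", {
  set.seed(302)
  for (i in 1:8) {
    g <- random_genome(5000)
    genes <- scan_genes(g)
    if (!nrow(genes)) next
    dt <- make_decay_table()
    specs <- product_specs(genes, dt)
    grn <- wgdsim:::grn_compile(genes, dt)

    ref_state <- list(conc = bootstrap_tfs(genes, 10), step = 0L)
    fast_conc <- wgdsim:::grn_init_conc(grn, 10)
    expect_equal(unname(fast_conc), unname(ref_state$conc[as.character(grn$ids)]))

    for (t in 1:10) {
      sensors <- c(runif(1, 0, 25000), sample(0:4, 1), sample(0:4, 1), rep(0, 5))
      ref_state <- step_grn(genes, ref_state, sensors, specs)
      fast_conc <- wgdsim:::grn_step_fast(grn, fast_conc, sensors, 1, 100)
      expect_equal(unname(fast_conc), unname(ref_state$conc[as.character(grn$ids)]),
                   tolerance = 1e-12)
    }
  }
})
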