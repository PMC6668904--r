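## GRN engine: sensor-driven signaling, expression, translation and decay.
##
## Concentration tables are named numeric vectors keyed by product identity
## ("0".."999"); an absent key means concentration zero. The per-step update
## order is decay -> signaling increments -> expression levels -> translation,
## each stage synchronous.

#' Draw the per-identity decay-rate table
#'
#' Decay rates are drawn once per simulation, one per possible product
#' identity, uniformly in `range`. A product's concentration is multiplied
#' by `1 - decay` each step.
#'
#' @param n Number of identities (1000).
#' @param range Length-2 numeric, the uniform range of decay rates.
#' @return Numeric vector of length `n`.
#' @export
make_decay_table <- function(n = WGD_N_IDENTITIES, range = c(0.05, 0.25)) {
  stopifnot(length(range) == 2L, range[1] > 0, range[2] < 1, range[1] <= range[2])
  runif(n, range[1], range[2])
}

#' Product specification table of a genome
#'
#' One row per distinct product identity encoded by the genome, in order of
#' first occurrence. When several genes share an identity (a hash collision
#' or a duplicated gene), the first gene in genome order defines the
#' product's kind, sign and binding word.
#'
#' @param genes Gene table from [scan_genes()].
#' @param decay_table Per-identity decay rates from [make_decay_table()].
#' @return `data.frame` with columns `identity`, `kind`, `sign`, `target`
#'   (the TF's bound cis word, `NA` for non-regulatory products) and
#'   `decay`.
#' @export
product_specs <- function(genes, decay_table = make_decay_table()) {
  first <- !duplicated(genes$identity)
  data.frame(
    identity = genes$identity[first],
    kind = genes$kind[first],
    sign = genes$sign[first],
    target = genes$target[first],
    decay = decay_table[genes$identity[first] + 1L],
    stringsAsFactors = FALSE
  )
}

conc_table <- function(identities, values = 0) {
  setNames(rep_len(as.numeric(values), length(identities)),
           as.character(identities))
}

#' Bootstrap transcription factors of a new organism
#'
#' On initialization the products of the first 12 regulatory genes in genome
#' order are set to `value` concentration units (all of them if the genome
#' encodes fewer than 12 regulatory genes); everything else starts at zero.
#'
#' @param genes Gene table from [scan_genes()].
#' @param value Initial concentration (default 10 units).
#' @param n_tfs Number of regulatory genes to activate (default 12).
#' @return Concentration table (named numeric vector over the genome's
#'   distinct product identities).
#' @export
bootstrap_tfs <- function(genes, value = 10, n_tfs = 12L) {
  ids <- genes$identity[!duplicated(genes$identity)]
  conc <- conc_table(ids)
  reg <- genes$identity[genes$kind == "regulatory"]
  act <- unique(head(reg, n_tfs))
  conc[as.character(act)] <- value
  conc
}

#' Evaluate signaling equations against sensor readings
#'
#' Each equation is a weighted sum of sensor readings; the result is floored
#' and reduced modulo 1000, naming the product identity whose expression the
#' pathway activates.
#'
#' @param equations List of two-column integer matrices (`addr`, `weight`),
#'   as parsed into the `equation` column of [scan_genes()].
#' @param sensors Numeric sensor vector (addresses index it 0-based).
#' @return Integer vector of identities, one per equation.
#' @export
evaluate_signaling <- function(equations, sensors) {
  vapply(equations, function(eq) {
    out <- sum(eq[, "weight"] * sensors[eq[, "addr"] + 1L])
    as.integer(floor(out) %% WGD_N_IDENTITIES)
  }, integer(1))
}

#' Apply signaling increments to a concentration table
#'
#' Every computed identity that is encoded by the genome has its product
#' concentration increased by one unit (repeats accumulate); identities not
#' encoded are ignored.
#'
#' @param conc Concentration table (named numeric vector).
#' @param identities Integer identities from [evaluate_signaling()].
#' @param encoded Integer vector of identities encoded by the genome.
#' @param cap Concentration cap.
#' @return Updated concentration table.
#' @export
apply_signaling <- function(conc, identities, encoded, cap = 100) {
  hits <- identities[identities %in% encoded]
  if (length(hits)) {
    tb <- table(hits)
    keys <- names(tb)
    conc[keys] <- pmin(conc[keys] + as.numeric(tb), cap)
  }
  conc
}

#' Expression level of one gene
#'
#' The level is the signed sum, over the gene's promoter cis words (with
#' multiplicity), of the concentrations of the transcription factors bound
#' to each word: activators contribute positively, repressors negatively.
#' Expression requires the polymerase: if no polymerase product has positive
#' concentration the level is zero regardless of bound TFs.
#'
#' @param gene A single-row gene table (or list) with a `cis` word vector.
#' @param conc Concentration table.
#' @param specs Product specification table from [product_specs()] (used to
#'   look up which TF binds each cis word, TF signs, and the polymerase
#'   products).
#' @return Numeric expression level.
#' @export
expression_level <- function(gene, conc, specs) {
  poly <- specs$identity[specs$kind == "polymerase"]
  if (!length(poly) || !any(conc[as.character(poly)] > 0)) return(0)
  cis <- if (is.data.frame(gene)) gene$cis[[1]] else gene$cis
  if (!length(cis)) return(0)
  tf <- specs[specs$kind == "regulatory", , drop = FALSE]
  if (!nrow(tf)) return(0)
  lvl <- 0
  for (w in cis) {
    b <- tf$target == w
    if (any(b)) {
      lvl <- lvl + sum(tf$sign[b] * conc[as.character(tf$identity[b])])
    }
  }
  lvl
}

#' Advance the GRN of one organism by one time step
#'
#' Applies the staged, synchronous update: (1) every product decays
#' multiplicatively by its decay rate; (2) signaling equations are evaluated
#' against the sensors and each resulting encoded identity gains one unit;
#' (3) expression levels are computed from the post-decay, post-signaling
#' table; (4) every gene whose level reaches the translation threshold adds
#' its level to its product's concentration (the dosage equals the
#' expression level), clipped at the cap.
#'
#' @param genes Gene table from [scan_genes()].
#' @param state List with elements `conc` (concentration table) and `step`.
#' @param sensors Numeric sensor vector.
#' @param specs Product specification table.
#' @param threshold Minimum level for translation (default 1).
#' @param cap Concentration cap (default 100).
#' @return New state: list with `conc`, `expression_levels` (numeric, one
#'   per gene) and incremented `step`.
#' @export
step_grn <- function(genes, state, sensors, specs, threshold = 1, cap = 100) {
  conc <- state$conc
  ## (1) decay
  conc <- conc * (1 - specs$decay[match(as.integer(names(conc)), specs$identity)])
  ## (2) signaling
  eqs <- genes$equation[genes$kind == "signaling"]
  if (length(eqs)) {
    ids <- evaluate_signaling(eqs, sensors)
    conc <- apply_signaling(conc, ids, specs$identity, cap)
  }
  ## (3) expression levels from a snapshot of the table
  levels <- vapply(seq_len(nrow(genes)), function(i) {
    expression_level(list(cis = genes$cis[[i]]), conc, specs)
  }, numeric(1))
  ## (4) translation
  sel <- which(levels >= threshold)
  for (i in sel) {
    key <- as.character(genes$identity[i])
    conc[key] <- min(conc[key] + levels[i], cap)
  }
  conc <- pmax(conc, 0)
  list(conc = conc, expression_levels = levels, step = (state$step %||% 0L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Compiled per-genome GRN structure used by the simulation loop. Same
## semantics as the reference operations above (asserted by a property test),
## expressed as small dense matrix kernels.

grn_compile <- function(genes, decay_table, n_sensors = WGD_N_SENSORS,
                        n_tfs = 12L) {
  n_genes <- nrow(genes)
  first <- !duplicated(genes$identity)
  ids <- genes$identity[first]
  m <- length(ids)
  kind <- genes$kind[first]
  sign <- genes$sign[first]
  target <- genes$target[first]

  pos1000 <- integer(WGD_N_IDENTITIES)
  pos1000[ids + 1L] <- seq_len(m)

  keep <- 1 - decay_table[ids + 1L]

  ## binding matrix: level = B %*% conc
  B <- matrix(0, nrow = n_genes, ncol = m)
  reg <- which(kind == "regulatory")
  if (n_genes && length(reg)) {
    for (t in reg) {
      tw <- target[t]
      cnt <- vapply(genes$cis, function(v) sum(v == tw), numeric(1))
      if (any(cnt > 0)) B[, t] <- B[, t] + sign[t] * cnt
    }
  }

  ## translation matrix: conc gain = Tm %*% gated_levels
  Tm <- matrix(0, nrow = m, ncol = n_genes)
  if (n_genes) Tm[cbind(pos1000[genes$identity + 1L], seq_len(n_genes))] <- 1

  ## signaling weight matrix: one row per equation
  eqs <- genes$equation[genes$kind == "signaling"]
  n_eq <- length(eqs)
  W <- matrix(0, nrow = n_eq, ncol = n_sensors)
  for (e in seq_len(n_eq)) {
    eq <- eqs[[e]]
    for (r in seq_len(nrow(eq))) {
      W[e, eq[r, "addr"] + 1L] <- W[e, eq[r, "addr"] + 1L] + eq[r, "weight"]
    }
  }

  boot <- unique(head(genes$identity[genes$kind == "regulatory"], n_tfs))

  list(
    ids = ids, m = m, n_genes = n_genes,
    keep = keep, B = B, Tm = Tm, W = W, n_eq = n_eq,
    pos1000 = pos1000,
    poly = which(kind == "polymerase"),
    move_plus = which(kind == "movement" & !is.na(sign) & sign > 0L),
    move_minus = which(kind == "movement" & !is.na(sign) & sign < 0L),
    repl_plus = which(kind == "replication" & !is.na(sign) & sign > 0L),
    repl_minus = which(kind == "replication" & !is.na(sign) & sign < 0L),
    boot_idx = pos1000[boot + 1L]
  )
}

grn_init_conc <- function(grn, value = 10) {
  conc <- numeric(grn$m)
  if (length(grn$boot_idx)) conc[grn$boot_idx] <- value
  conc
}

grn_step_fast <- function(grn, conc, sensors, threshold = 1, cap = 100) {
  conc <- conc * grn$keep
  if (grn$n_eq > 0L) {
    out <- floor(grn$W %*% sensors) %% WGD_N_IDENTITIES
    hit <- grn$pos1000[as.integer(out) + 1L]
    hit <- hit[hit > 0L]
    if (length(hit)) {
      conc <- pmin(conc + tabulate(hit, nbins = grn$m), cap)
    }
  }
  if (length(grn$poly) && any(conc[grn$poly] > 0)) {
    lev <- as.numeric(grn$B %*% conc)
    lev[lev < threshold] <- 0
    if (any(lev != 0)) {
      conc <- pmin(conc + as.numeric(grn$Tm %*% lev), cap)
    }
  }
  pmax(conc, 0)
}
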