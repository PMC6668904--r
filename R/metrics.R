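## Lineage and expression metrics: short-term genetic distance (STGD, vs the
## direct parent), long-term genetic distance (LTGD, vs the time-0 founder),
## both in substitutions per 10 kb, and the expression distance (ED), the
## relative change of the mean gene-product concentration between steps.

#' Short-term genetic distance
#'
#' Substitutions per 10 kb between an organism and its direct parent. For
#' equal lengths this is the Hamming distance scaled by 10,000 / length. At
#' a WGD generation (child exactly twice the parent's length) each child
#' half is compared against the whole parent -- the halves are positionally
#' homologous to the parent by construction -- and the summed distance is
#' scaled by the child length.
#'
#' @param child,parent Integer digit vectors; `length(child)` must equal
#'   `length(parent)` or twice it.
#' @return Distance in substitutions per 10 kb.
#' @export
stgd <- function(child, parent) {
  lc <- length(child); lp <- length(parent)
  if (lc == 0L && lp == 0L) return(0)
  if (lc == lp) {
    h <- sum(child != parent)
  } else if (lc == 2L * lp) {
    h <- sum(child[1:lp] != parent) + sum(child[(lp + 1L):lc] != parent)
  } else {
    stop("incompatible genome lengths for STGD: child must match the parent ",
         "or be its whole-genome duplicate", call. = FALSE)
  }
  h * 1e4 / lc
}

#' Long-term genetic distance
#'
#' Substitutions per 10 kb between an organism and the simulation's time-0
#' ancestor. The genome (of length `2^k` times the ancestor's, after `k`
#' WGDs) is partitioned into ancestor-length blocks; the summed block-wise
#' Hamming distance is scaled by 10,000 / genome length.
#'
#' @param genome,ancestor Integer digit vectors.
#' @return Distance in substitutions per 10 kb.
#' @export
ltgd <- function(genome, ancestor) {
  lg <- length(genome); la <- length(ancestor)
  if (lg == 0L && la == 0L) return(0)
  if (la == 0L || lg %% la != 0L) {
    stop("incompatible genome lengths for LTGD", call. = FALSE)
  }
  k <- lg %/% la
  if (bitwAnd(k, k - 1L) != 0L) {
    stop("genome length must be a power of two times the ancestor length",
         call. = FALSE)
  }
  h <- sum(matrix(genome, nrow = la) != ancestor)
  h * 1e4 / lg
}

#' Expression distance between consecutive steps
#'
#' The relative change of the mean gene-product concentration: means are
#' taken over all product identities encoded by the genome (zeros
#' included), and `ed = |m_t - m_prev| / m_prev`. Both means zero gives 0; a
#' zero previous mean with a positive current one gives `Inf`. An organism
#' is called unstable when ED exceeds 0.30 (strictly).
#'
#' @param conc_t,conc_prev Concentration tables (numeric vectors over the
#'   encoded identities) at the current and previous step.
#' @return Non-negative expression distance (possibly `Inf`).
#' @export
expression_distance <- function(conc_t, conc_prev) {
  m_t <- if (length(conc_t)) mean(conc_t) else 0
  m_p <- if (length(conc_prev)) mean(conc_prev) else 0
  ed_from_means(m_t, m_p)
}

ed_from_means <- function(m_t, m_p) {
  if (m_p == 0) {
    if (m_t == 0) 0 else Inf
  } else {
    abs(m_t - m_p) / m_p
  }
}

#' Extract the adapted, expression-stable subpopulation
#'
#' Returns the ids of organisms whose last `window` consecutive ED values
#' are all at most `ed_threshold` and whose current energy has reached the
#' adaptation threshold.
#'
#' @param records Step-record data.frame with columns `do_id`, `step`,
#'   `energy`, `ed`.
#' @param window Number of trailing consecutive steps required (W >= 1).
#' @param ed_threshold Stability threshold on ED (default 0.30).
#' @param energy_threshold Adaptation threshold (default 20,000).
#' @return Integer vector of organism ids.
#' @export
extract_adapted_stable <- function(records, window = 10L, ed_threshold = 0.3,
                                   energy_threshold = 20000) {
  stopifnot(window >= 1L)
  keep <- vapply(split(records, records$do_id), function(r) {
    r <- r[order(r$step), , drop = FALSE]
    n <- nrow(r)
    if (n < window) return(FALSE)
    tail_ed <- r$ed[(n - window + 1L):n]
    all(tail_ed <= ed_threshold) && r$energy[n] >= energy_threshold
  }, logical(1))
  as.integer(names(keep)[keep])
}

#' Classify the end state of one simulation
#'
#' @param n_polyploid,n_nonpolyploid Final subpopulation sizes.
#' @return One of `"extinction"`, `"polyploid_larger"`,
#'   `"non_polyploid_larger"`, `"tie"`.
#' @export
classify_outcome <- function(n_polyploid, n_nonpolyploid) {
  if (n_polyploid == 0L && n_nonpolyploid == 0L) return("extinction")
  if (n_polyploid > n_nonpolyploid) return("polyploid_larger")
  if (n_nonpolyploid > n_polyploid) return("non_polyploid_larger")
  "tie"
}

#' Summarize replicate simulations into outcome fractions
#'
#' Produces the fraction of replicate simulations per food-reduction level
#' that ended in total extinction, with the polyploid subpopulation larger,
#' with the non-polyploid subpopulation larger, or tied. Fractions are
#' exact rational counts over the replicate number.
#'
#' @param final_states Data.frame with one row per simulation: columns
#'   `reduction`, `n_polyploid`, `n_nonpolyploid`.
#' @return Data.frame with one row per reduction level and columns
#'   `reduction`, `n_simulations`, `extinction`, `polyploid_larger`,
#'   `non_polyploid_larger`, `tie`.
#' @export
summarize_experiment <- function(final_states) {
  stopifnot(nrow(final_states) >= 1L)
  outcome <- mapply(classify_outcome,
                    final_states$n_polyploid, final_states$n_nonpolyploid)
  levels <- sort(unique(final_states$reduction))
  rows <- lapply(levels, function(lv) {
    oc <- outcome[final_states$reduction == lv]
    n <- length(oc)
    data.frame(
      reduction = lv, n_simulations = n,
      extinction = sum(oc == "extinction") / n,
      polyploid_larger = sum(oc == "polyploid_larger") / n,
      non_polyploid_larger = sum(oc == "non_polyploid_larger") / n,
      tie = sum(oc == "tie") / n
    )
  })
  do.call(rbind, rows)
}

#' Compare a metric between ploidy classes
#'
#' Welch's two-sample t-test on per-genome metric values pooled across time
#' steps and simulations, as used for the STGD/LTGD class comparisons.
#'
#' @param values_polyploid,values_nonpolyploid Numeric vectors (n >= 2
#'   each).
#' @return List with `mean_polyploid`, `mean_nonpolyploid`, `statistic` and
#'   `p_value`.
#' @export
compare_groups <- function(values_polyploid, values_nonpolyploid) {
  x <- values_polyploid; y <- values_nonpolyploid
  if (length(x) < 2L || length(y) < 2L ||
      (stats::var(x) == 0 && stats::var(y) == 0)) {
    stop(structure(
      class = c("wgdsim_undefined_test", "error", "condition"),
      list(message = "degenerate groups: need n >= 2 per class and non-zero variance",
           call = sys.call(-1))
    ))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(mean_polyploid = mean(x), mean_nonpolyploid = mean(y),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Bin per-step metric values into step windows
#'
#' Ascribes records to consecutive bins of `width` time steps and returns
#' per-bin, per-ploidy-class means -- the tidy form behind the binned
#' box-plot summaries.
#'
#' @param records Step-record data.frame with columns `step`,
#'   `ploidy_class` and the metric column.
#' @param metric Name of the metric column (e.g. `"stgd"`).
#' @param width Bin width in steps (default 100).
#' @return Data.frame with columns `bin` (first step of the bin),
#'   `ploidy_class`, `mean`, `n`.
#' @export
bin_metric <- function(records, metric, width = 100L) {
  b <- (records$step %/% width) * width
  v <- records[[metric]]
  v[!is.finite(v)] <- NA
  agg <- aggregate(v, list(bin = b, ploidy_class = records$ploidy_class),
                   function(z) c(mean(z, na.rm = TRUE), sum(!is.na(z))))
  data.frame(
    bin = as.integer(agg$bin),
    ploidy_class = agg$ploidy_class,
    mean = agg$x[, 1],
    n = as.integer(agg$x[, 2])
  )
}
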