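#' Generate a random genome
#'
#' Draws `length` i.i.d. uniform digits over \{0,1,2,3\}. Deterministic given
#' the state of R's random number generator (use `set.seed()`).
#'
#' @param length Number of digits (> 0).
#' @return Integer digit vector.
#' @export
random_genome <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length <= 0) {
    stop("genome length must be a positive number", call. = FALSE)
  }
  sample.int(4L, as.integer(length), replace = TRUE) - 1L
}

#' Default founder-genome requirements
#'
#' Minimum classified-kind gene counts a founder genome must encode to be
#' able to express (polymerase), respond to the environment (signaling),
#' replicate and move, with enough regulatory genes to fill the 12-TF
#' bootstrap set. Because gene density is roughly proportional to genome
#' length (about 12 regulatory genes per 65 kb of random sequence), the
#' regulatory requirement scales with the genome length and is capped at 12
#' -- a fixed requirement of 12 would be unsatisfiable for the short
#' genomes of scaled-down runs.
#'
#' @param genome_length Genome length the requirements are for.
#' @return Named integer vector of minimum counts, keyed by kind label
#'   (either a base kind such as `"polymerase"` or a classified label such
#'   as `"replication_plus"`; `"regulatory"` counts both signs).
#' @export
default_viability_requirements <- function(genome_length = 100000L) {
  reg <- min(12L, max(1L, as.integer(12 * genome_length / 1e5)))
  c(polymerase = 1L, signaling = 1L,
    replication_plus = 1L, movement_plus = 1L,
    regulatory = reg)
}

count_kind <- function(genes, label) {
  if (label %in% genes$kind) return(sum(genes$kind == label))
  sum(gene_class(genes) == label)
}

#' Generate a random genome satisfying viability requirements
#'
#' Repeatedly draws random genomes until the parsed gene list contains at
#' least the required number of genes of each requested kind, or the retry
#' cap is reached.
#'
#' @param length Genome length in digits.
#' @param requirements Named integer vector of minimum gene counts per kind
#'   label (see [default_viability_requirements()]). An empty vector accepts
#'   the first random genome.
#' @param max_tries Retry cap.
#' @param kind_words Reserved kind word table.
#' @return Integer digit vector whose parse satisfies the requirements.
#' @export
random_viable_genome <- function(length,
                                 requirements = default_viability_requirements(),
                                 max_tries = 100L,
                                 kind_words = wgd_kind_words()) {
  if (length(requirements) == 0L) return(random_genome(length))
  missing_last <- character(0)
  for (i in seq_len(max_tries)) {
    g <- random_genome(length)
    genes <- scan_genes(g, kind_words)
    have <- vapply(names(requirements), function(lb) count_kind(genes, lb), integer(1))
    if (all(have >= requirements)) return(g)
    missing_last <- names(requirements)[have < requirements]
  }
  stop(structure(
    class = c("wgdsim_generation_failure", "error", "condition"),
    list(message = paste0(
           "failed to generate a viable genome after ", max_tries,
           " tries; unsatisfied kinds: ", paste(missing_last, collapse = ", ")),
         call = sys.call(-1))
  ))
}

#' Apply per-digit substitution mutations
#'
#' Each digit is independently replaced, with probability `rate`, by a
#' uniformly chosen *different* digit. The input genome is not modified.
#'
#' @param genome Integer digit vector.
#' @param rate Per-digit substitution probability in \[0, 1\].
#' @return A list with `genome` (the mutated copy) and `n` (the number of
#'   substituted positions).
#' @export
apply_substitutions <- function(genome, rate) {
  assert_genome(genome)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    stop("substitution rate must be a single value in [0, 1]", call. = FALSE)
  }
  n <- length(genome)
  if (n == 0L || rate == 0) return(list(genome = genome, n = 0L))
  hit <- which(runif(n) < rate)
  k <- length(hit)
  if (k) {
    genome[hit] <- (genome[hit] + sample.int(3L, k, replace = TRUE)) %% 4L
  }
  list(genome = genome, n = k)
}

#' Whole-genome duplication
#'
#' Returns the concatenation of the genome with itself. Because the gene
#' grammar is local, the parse of the duplicate is the parse of the original
#' followed by the same genes offset by the original length (provided the
#' final gene ends at or before the copy boundary).
#'
#' @param genome Integer digit vector.
#' @return Integer digit vector of exactly twice the length.
#' @export
whole_genome_duplicate <- function(genome) {
  assert_genome(genome)
  c(genome, genome)
}

#' Read and write genome files
#'
#' Genomes are stored in a FASTA-like plain-text format: a header line
#' `">id ploidy=N"` followed by lines of digits 0--3 (70 per line). The
#' writer emits the canonical form, so write/read/write round-trips are
#' byte-identical.
#'
#' @param path File path.
#' @param genomes For `write_genomes`, a list of records, each a list with
#'   `id` (character), `ploidy` (integer) and `digits` (integer digit
#'   vector).
#' @return `read_genomes` returns such a list; `write_genomes` returns
#'   `path` invisibly.
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) return(list())
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    h <- lines[hdr[i]]
    m <- regmatches(h, regexec("^>(\\S+)\\s+ploidy=(\\d+)\\s*$", h))[[1]]
    if (length(m) != 3L) stop("malformed genome header: ", h, call. = FALSE)
    seq_lines <- if (hdr[i] + 1L <= ends[i]) lines[seq(hdr[i] + 1L, ends[i])] else character(0)
    seq_lines <- seq_lines[nzchar(seq_lines)]
    out[[i]] <- list(
      id = m[2],
      ploidy = as.integer(m[3]),
      digits = string_to_digits(paste(seq_lines, collapse = ""))
    )
  }
  out
}

#' @rdname read_genomes
#' @export
write_genomes <- function(genomes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(sprintf(">%s ploidy=%d", g$id, as.integer(g$ploidy)), con)
    s <- digits_to_string(g$digits)
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = 70L)
      writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
    }
  }
  invisible(path)
}
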