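## Gene grammar: TATA box + 5-50 cis words + reserved kind word + payload.
## Digits are base-4 integers 0..3; a "word" is 4 consecutive digits read
## base-4 (0..255). The TATA box "1010" has word value 68.

WGD_TATA_DIGITS <- c(1L, 0L, 1L, 0L)
WGD_TATA_VALUE <- 68L
WGD_N_IDENTITIES <- 1000L

#' Sensor slot names
#'
#' The fixed sensor vector layout used by signaling equations: the organism's
#' own energy, the number of food sources and of other organisms within the
#' sensing radius, and five reserved slots (attack/defense inputs) that are
#' always zero in this implementation.
#'
#' @return Character vector of sensor slot names, in address order.
#' @export
sensor_names <- function() {
  c("own_energy", "n_food_nearby", "n_dos_nearby",
    paste0("reserved_", 1:5))
}

WGD_N_SENSORS <- 8L

#' Reserved gene kind words
#'
#' The eight reserved 4-digit words that terminate the cis-element block of a
#' promoter and determine the kind of the gene that follows. Five structural
#' kinds (replication, movement, attack, defense, search) plus regulatory,
#' polymerase and signaling. Structural and regulatory genes additionally
#' carry a sign (promoting/activating vs repressing) read from the parity of
#' the last payload digit, so random sequence yields activators and
#' repressors in equal proportion. Attack, defense and search genes are
#' parsed but have no behavioural effect.
#'
#' @return Named character vector mapping kind name to its 4-digit word.
#' @export
wgd_kind_words <- function() {
  c(replication = "0001",
    movement    = "0002",
    attack      = "0003",
    defense     = "0010",
    search      = "0011",
    regulatory  = "0020",
    polymerase  = "0021",
    signaling   = "0022")
}

WGD_STRUCTURAL_KINDS <- c("replication", "movement", "attack", "defense", "search")

#' Convert between digit vectors and strings
#'
#' Genomes are integer vectors over \{0,1,2,3\}; the string form is used in
#' genome files and examples.
#'
#' @param x A string of digits (for `string_to_digits`) or an integer digit
#'   vector (for `digits_to_string`).
#' @return The converted representation.
#' @export
string_to_digits <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(integer(0))
  d <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  if (anyNA(d) || any(d < 0L | d > 3L)) {
    stop("genome strings may only contain the digits 0-3", call. = FALSE)
  }
  d
}

#' @rdname string_to_digits
#' @export
digits_to_string <- function(x) paste(x, collapse = "")

## word value of a 4-digit window
word_value <- function(d) {
  stopifnot(length(d) == 4L)
  as.integer(d[1] * 64L + d[2] * 16L + d[3] * 4L + d[4])
}

## word values at every start position of a genome (length n - 3)
word_values <- function(g) {
  n <- length(g)
  if (n < 4L) return(integer(0))
  g[1:(n - 3L)] * 64L + g[2:(n - 2L)] * 16L + g[3:(n - 1L)] * 4L + g[4:n]
}

kind_word_values <- function(kind_words = wgd_kind_words()) {
  vapply(kind_words, function(w) word_value(string_to_digits(w)), integer(1))
}

assert_genome <- function(g) {
  if (!is.numeric(g)) stop("genome must be an integer digit vector", call. = FALSE)
  if (length(g) && (anyNA(g) || any(g < 0L | g > 3L))) {
    stop("genome digits must all be in {0,1,2,3}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Derive a gene-product identity from a coding payload
#'
#' The first five payload digits are read as a base-4 number (0--1023) and
#' reduced modulo 1000, giving the product identity shared by all genes with
#' the same payload prefix.
#'
#' @param payload Integer digit vector with at least 5 elements.
#' @return Integer identity in 0--999.
#' @examples
#' identity_of(c(0, 0, 0, 0, 0)) # 0
#' identity_of(c(3, 3, 3, 3, 3)) # 1023 %% 1000 = 23
#' @export
identity_of <- function(payload) {
  if (length(payload) < 5L) {
    stop("payload window must contain at least 5 digits", call. = FALSE)
  }
  d <- as.integer(payload[1:5])
  if (anyNA(d) || any(d < 0L | d > 3L)) {
    stop("payload digits must be in {0,1,2,3}", call. = FALSE)
  }
  (d[1] * 256L + d[2] * 64L + d[3] * 16L + d[4] * 4L + d[5]) %% WGD_N_IDENTITIES
}

empty_gene_table <- function() {
  data.frame(
    start = integer(0), end = integer(0), kind = character(0),
    sign = integer(0), identity = integer(0), n_cis = integer(0),
    target = integer(0), motif = integer(0),
    cis = I(list()), equation = I(list()),
    stringsAsFactors = FALSE
  )
}

#' Scan a genome for genes
#'
#' Performs the left-to-right, non-overlapping scan of the gene grammar. At
#' every occurrence of the TATA word "1010" a parse is attempted: a block of
#' 5--50 four-digit cis words (none of which may be a reserved kind word or
#' the TATA word itself), terminated by the first word that is a reserved
#' kind word, followed by the kind-specific payload with no interspersed
#' digits. On success the gene is emitted and scanning resumes after its end;
#' on failure scanning resumes at the next TATA occurrence after the failed
#' start position.
#'
#' Payloads: structural, regulatory and polymerase genes carry a 5-digit
#' payload whose base-4 value modulo 1000 is the product identity; the
#' regulatory payload's first word is the TF's target cis word and the
#' parity of its fifth digit sets the sign (even = activator); structural
#' signs are read the same way (even = promoting). Polymerase payloads carry
#' the bound motif. Signaling payloads hold a 2-digit length field mapping to
#' 3--20 equation elements, each element an 8-digit slot: a 4-digit sensor
#' address (reduced modulo the number of sensors) and a 4-digit weight
#' decoded to a signed integer in -128..127.
#'
#' @param genome Integer digit vector over \{0,1,2,3\}.
#' @param kind_words Named character vector of reserved kind words, as from
#'   [wgd_kind_words()].
#' @param n_sensors Number of sensor slots for address reduction.
#' @return A `data.frame` with one row per gene, ordered by start position:
#'   columns `start`/`end` (0-based, half-open span), `kind`, `sign` (+1/-1,
#'   `NA` for polymerase and signaling), `identity`, `n_cis`, `target`
#'   (regulatory target cis word value, else `NA`), `motif` (polymerase,
#'   else `NA`), and list columns `cis` (integer cis word values) and
#'   `equation` (two-column integer matrix `addr`, `weight`, or `NULL`).
#' @export
scan_genes <- function(genome, kind_words = wgd_kind_words(),
                       n_sensors = WGD_N_SENSORS) {
  assert_genome(genome)
  genome <- as.integer(genome)
  n <- length(genome)
  if (n < 4L) return(empty_gene_table())

  kw <- kind_word_values(kind_words)
  is_kind <- logical(256L)
  is_kind[kw + 1L] <- TRUE
  kind_name <- character(256L)
  kind_name[kw + 1L] <- names(kw)

  wv <- word_values(genome)
  tata <- which(wv == WGD_TATA_VALUE)
  if (!length(tata)) return(empty_gene_table())

  ## collectors
  cap0 <- length(tata)
  g_start <- integer(cap0); g_end <- integer(cap0); g_kind <- character(cap0)
  g_sign <- integer(cap0); g_id <- integer(cap0); g_ncis <- integer(cap0)
  g_target <- integer(cap0); g_motif <- integer(cap0)
  g_cis <- vector("list", cap0); g_eq <- vector("list", cap0)
  ng <- 0L

  n_words <- n - 3L
  resume <- 1L
  for (p in tata) {
    if (p < resume) next
    ## cis block: words at p+4, p+8, ..., up to 51 words (50 cis + kind)
    q <- p + 4L + 4L * (0:50)
    q <- q[q <= n_words]
    if (!length(q)) next
    ws <- wv[q]
    special <- which(is_kind[ws + 1L] | ws == WGD_TATA_VALUE)
    if (!length(special)) next            # ran off end or > 50 cis words
    j <- special[1L]
    if (ws[j] == WGD_TATA_VALUE) next     # TATA inside cis block
    ncis <- j - 1L
    if (ncis < 5L || ncis > 50L) next
    kind <- kind_name[ws[j] + 1L]
    pp <- p + 4L + 4L * j                 # first payload digit (1-based)

    if (kind == "signaling") {
      if (pp + 1L > n) next
      lenval <- genome[pp] * 4L + genome[pp + 1L]
      nel <- 3L + (lenval %% 16L)
      nel <- min(max(nel, 3L), 20L)
      payload_len <- 2L + 8L * nel
      if (pp + payload_len - 1L > n) next
      s <- pp + 2L + 8L * (0:(nel - 1L))
      addr <- wv[s] %% n_sensors
      weight <- wv[s + 4L] - 128L
      eq <- cbind(addr = addr, weight = weight)
      id <- identity_of(genome[pp:(pp + 4L)])
      sign <- NA_integer_; target <- NA_integer_; motif <- NA_integer_
      cis <- ws[seq_len(ncis)]
    } else {
      payload_len <- 5L
      if (pp + 4L > n) next
      pd <- genome[pp:(pp + 4L)]
      id <- identity_of(pd)
      eq <- NULL
      cis <- ws[seq_len(ncis)]
      target <- NA_integer_; motif <- NA_integer_; sign <- NA_integer_
      if (kind == "regulatory") {
        target <- wv[pp]
        sign <- if (pd[5] %% 2L == 0L) 1L else -1L
      } else if (kind == "polymerase") {
        motif <- wv[pp]
      } else {
        sign <- if (pd[5] %% 2L == 0L) 1L else -1L
      }
    }

    end1 <- pp + payload_len - 1L         # last digit of gene, 1-based
    ng <- ng + 1L
    g_start[ng] <- p - 1L                 # 0-based
    g_end[ng] <- end1                     # 0-based half-open == 1-based inclusive
    g_kind[ng] <- kind
    g_sign[ng] <- sign
    g_id[ng] <- id
    g_ncis[ng] <- ncis
    g_target[ng] <- target
    g_motif[ng] <- motif
    g_cis[[ng]] <- cis
    g_eq[[ng]] <- eq
    resume <- end1 + 1L
  }

  if (ng == 0L) return(empty_gene_table())
  idx <- seq_len(ng)
  data.frame(
    start = g_start[idx], end = g_end[idx], kind = g_kind[idx],
    sign = g_sign[idx], identity = g_id[idx], n_cis = g_ncis[idx],
    target = g_target[idx], motif = g_motif[idx],
    cis = I(g_cis[idx]), equation = I(g_eq[idx]),
    stringsAsFactors = FALSE
  )
}

#' Classified kind label of parsed genes
#'
#' Collapses kind and sign into the classified gene kind used by the organism
#' actuators, e.g. `"movement_plus"`, `"regulatory_activator"`.
#'
#' @param genes A gene table from [scan_genes()].
#' @return Character vector of classified kind labels, one per gene.
#' @export
gene_class <- function(genes) {
  k <- genes$kind
  s <- genes$sign
  out <- k
  str <- k %in% WGD_STRUCTURAL_KINDS
  out[str] <- paste0(k[str], ifelse(s[str] > 0L, "_plus", "_minus"))
  reg <- k == "regulatory"
  out[reg] <- paste0("regulatory_", ifelse(s[reg] > 0L, "activator", "repressor"))
  out
}
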