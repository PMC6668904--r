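## Independent naive reference scanner for the gene grammar, written against
## the string representation with a character-by-character walk. Used as the
## oracle for scan_genes(); deliberately shares no code with the package
## implementation.

naive_scan <- function(genome, kind_words = wgd_kind_words()) {
  s <- digits_to_string(genome)
  n <- nchar(s)
  words <- unname(kind_words)
  res <- list()
  i <- 1L
  while (i + 3L <= n) {
    if (substr(s, i, i + 3L) != "1010") { i <- i + 1L; next }
    j <- i + 4L
    ncis <- 0L
    ok <- FALSE
    kind <- NA_character_
    repeat {
      if (j + 3L > n) break
      w <- substr(s, j, j + 3L)
      if (w %in% words) {
        if (ncis >= 5L && ncis <= 50L) {
          ok <- TRUE
          kind <- names(kind_words)[match(w, words)]
          j <- j + 4L
        }
        break
      }
      if (w == "1010" || ncis == 50L) break
      ncis <- ncis + 1L
      j <- j + 4L
    }
    plen <- NA_integer_
    if (ok) {
      if (kind == "signaling") {
        if (j + 1L > n) {
          ok <- FALSE
        } else {
          v <- as.integer(substr(s, j, j)) * 4L + as.integer(substr(s, j + 1L, j + 1L))
          nel <- 3L + (v %% 16L)
          nel <- min(max(nel, 3L), 20L)
          plen <- 2L + 8L * nel
          if (j + plen - 1L > n) ok <- FALSE
        }
      } else {
        plen <- 5L
        if (j + 4L > n) ok <- FALSE
      }
    }
    if (ok) {
      end <- j + plen - 1L
      res[[length(res) + 1L]] <- data.frame(
        start = i - 1L, end = end, kind = kind, n_cis = ncis,
        stringsAsFactors = FALSE
      )
      i <- end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), n_cis = integer(0)))
  }
  do.call(rbind, res)
}
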