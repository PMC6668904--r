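## Builders for hand-crafted toy genomes, assembled digit by digit from the
## grammar components. Filler regions use only zeros, which contain neither
## the TATA word nor any reserved kind word.

KW <- wgd_kind_words()

## base-4 value of a 4-digit word string
word_value_of <- function(s) {
  d <- string_to_digits(s)
  d[1] * 64L + d[2] * 16L + d[3] * 4L + d[4]
}

int_to_word <- function(v) {
  stopifnot(v >= 0, v <= 255)
  paste0(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L)
}

## five default cis words (none reserved, none "1010")
default_cis <- c("0120", "2231", "0121", "3300", "0130")

## payload for structural/regulatory/polymerase genes: 5 digits
build_gene <- function(kind, cis = default_cis, payload = "00000") {
  stopifnot(kind %in% names(KW), nchar(payload) == 5L)
  paste0("1010", paste(cis, collapse = ""), KW[[kind]], payload)
}

## signaling gene: length field digits chosen for n elements (3..18),
## elements as list of c(addr_raw, weight_raw) word values (0..255)
build_signaling_gene <- function(elements, cis = default_cis) {
  nel <- length(elements)
  stopifnot(nel >= 3L, nel <= 18L)
  v <- nel - 3L  # length field value, 0..15
  lenfield <- paste0(v %/% 4L, v %% 4L)
  body <- vapply(elements, function(e) {
    paste0(int_to_word(e[1]), int_to_word(e[2]))
  }, character(1))
  paste0("1010", paste(cis, collapse = ""), KW[["signaling"]],
         lenfield, paste(body, collapse = ""))
}

## weight encoding used by the grammar: raw word value = weight + 128
weight_word <- function(w) w + 128L

as_digits <- function(...) string_to_digits(paste0(...))

zeros <- function(n) strrep("0", n)

## expected identity of a 5-digit payload string
payload_identity <- function(payload) {
  d <- as.integer(strsplit(payload, "")[[1]])
  (d[1] * 256L + d[2] * 64L + d[3] * 16L + d[4] * 4L + d[5]) %% 1000L
}

## a regulatory gene targeting cis word `target` with given sign
build_tf_gene <- function(target = "2231", activator = TRUE) {
  sign_digit <- if (activator) "0" else "1"
  build_gene("regulatory", payload = paste0(target, sign_digit))
}
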