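# Text <-> bit-grid codec for the domino-array data carrier.
#
# A carrier stores one word: a 5 x 5 message array plus a 1 x 5 address row
# above it. A site carrying a biotin-labelled staple is bit 1; a plain staple
# is bit 0. The address row holds the word index; before access the message
# bits are mixed ("scrambled") by an address-keyed permutation so the OFF
# conformation reads as ciphertext.

#' Construct an encoding scheme
#'
#' Two schemes are provided. `"a5"` (default) packs one character per column
#' using a 5-bit alphabet: space/pad = 0, A = 1 .. Z = 26 (codes 27..31 are
#' reserved and render as `?` on decode). It is the only coding consistent
#' with the 5 x 5 array capacity: a full 8-bit ASCII word such as "NANO"
#' (32 bits) cannot fit 25 message bits. `"ascii8"` is the 8-bit alternative:
#' the word's byte stream is laid out column-major across the grid (up to 3
#' characters per carrier).
#'
#' @param scheme_id `"a5"` or `"ascii8"`.
#' @param grid_rows,grid_cols message array shape (default 5 x 5).
#' @param address_rows number of address rows above the message array.
#' @param spacing_rule `"inter_character_blank_column"` or `"none"`.
#'   Defaults to blank-column spacing for `"a5"` (a guard against one
#'   tetravalent streptavidin bridging biotins in adjacent columns) and
#'   `"none"` for `"ascii8"`.
#' @param scramble_rule identifier of the address-keyed permutation family;
#'   only `"colshift"` (per-column cyclic shifts) is built in.
#' @return an object of class `encoding_scheme`.
#' @export
encoding_scheme <- function(scheme_id = c("a5", "ascii8"),
                            grid_rows = 5L, grid_cols = 5L, address_rows = 1L,
                            spacing_rule = NULL,
                            scramble_rule = "colshift") {
  scheme_id <- match.arg(scheme_id)
  bits_per_char <- if (scheme_id == "a5") 5L else 8L
  if (is.null(spacing_rule)) {
    spacing_rule <- if (scheme_id == "a5") "inter_character_blank_column" else "none"
  }
  spacing_rule <- match.arg(spacing_rule, c("none", "inter_character_blank_column"))
  if (scheme_id == "a5" && grid_rows < bits_per_char) {
    ddc_error("a5 scheme needs at least 5 message rows (one character per column)",
              "ddc_scheme_error")
  }
  structure(list(scheme_id = scheme_id,
                 bits_per_char = bits_per_char,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 address_rows = as.integer(address_rows),
                 spacing_rule = spacing_rule,
                 scramble_rule = scramble_rule),
            class = "encoding_scheme")
}

# --- message grid ------------------------------------------------------------

new_message_grid <- function(bits, address, scrambled = FALSE,
                             scheme_id = "a5", word_index = NA_integer_,
                             carrier_ref = NA_character_, spaced = FALSE) {
  bits <- as.matrix(bits); storage.mode(bits) <- "integer"
  address <- matrix(as.integer(address), nrow = nrow(as.matrix(address)))
  if (!all(bits %in% c(0L, 1L)) || !all(address %in% c(0L, 1L))) {
    ddc_error("grid entries must be 0 or 1", "ddc_grid_error")
  }
  structure(list(bits = bits, address = address,
                 scrambled = isTRUE(scrambled),
                 scheme_id = scheme_id,
                 word_index = as.integer(word_index),
                 carrier_ref = carrier_ref,
                 spaced = isTRUE(spaced)),
            class = "message_grid")
}

#' @export
print.message_grid <- function(x, ...) {
  cat(sprintf("<message_grid %s%s word_index=%s>\n", x$scheme_id,
              if (x$scrambled) " (scrambled)" else "",
              ifelse(is.na(x$word_index), "?", x$word_index)))
  cat("A:", paste(t(x$address), collapse = " "), "\n")
  for (r in seq_len(nrow(x$bits))) cat("  ", paste(x$bits[r, ], collapse = " "), "\n")
  invisible(x)
}

empty_grid <- function(scheme) {
  new_message_grid(matrix(0L, scheme$grid_rows, scheme$grid_cols),
                   matrix(0L, scheme$address_rows, scheme$grid_cols),
                   scheme_id = scheme$scheme_id)
}

# 5-bit alphabet tables
a5_code <- function(ch) {
  ifelse(ch == " ", 0L,
         ifelse(ch %in% LETTERS, match(ch, LETTERS), NA_integer_))
}
a5_char <- function(code) {
  ifelse(code == 0L, "", ifelse(code >= 1L & code <= 26L, LETTERS[pmax(code, 1L)], "?"))
}

encode_word_a5 <- function(word, scheme) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  codes <- a5_code(ch)
  if (anyNA(codes)) {
    ddc_error(sprintf("character '%s' is not encodable under scheme a5",
                      ch[which(is.na(codes))[1]]),
              "ddc_encoding_error")
  }
  if (length(codes) > scheme$grid_cols) {
    ddc_error(sprintf("word '%s' (%d characters) exceeds the %d-column grid",
                      word, length(codes), scheme$grid_cols),
              "ddc_capacity_error")
  }
  bits <- matrix(0L, scheme$grid_rows, scheme$grid_cols)
  for (j in seq_along(codes)) {
    bits[seq_len(5L), j] <- int_to_bits(codes[j], 5L)
  }
  bits
}

encode_word_ascii8 <- function(word, scheme) {
  codes <- utf8ToInt(word)
  if (any(codes > 255L)) {
    ddc_error(sprintf("character '%s' is not encodable under scheme ascii8",
                      intToUtf8(codes[codes > 255L][1])),
              "ddc_encoding_error")
  }
  capacity <- scheme$grid_rows * scheme$grid_cols
  stream <- unlist(lapply(codes, int_to_bits, nbits = 8L))
  if (length(stream) > capacity) {
    ddc_error(sprintf("word '%s' needs %d bits, grid holds %d",
                      word, length(stream), capacity),
              "ddc_capacity_error")
  }
  bits <- matrix(0L, scheme$grid_rows, scheme$grid_cols)
  bits[seq_along(stream)] <- stream   # column-major fill
  bits
}

#' Encode plaintext into per-carrier bit grids
#'
#' Splits `text` on single spaces; each word becomes one unscrambled
#' [message_grid][encoding_scheme] with a zeroed address row (use
#' [assign_address()] to number the carriers). Blank-column spacing is applied
#' when the scheme requests it and the word fits; otherwise spacing is dropped
#' with a warning, mirroring selective use of blank columns.
#'
#' @param text plaintext over the scheme alphabet; `""` yields an empty list.
#' @param scheme an [encoding_scheme()].
#' @return list of `message_grid` objects, one per word.
#' @export
#' @examples
#' grids <- encode_text("DNA NANO TECH", encoding_scheme("a5"))
#' length(grids)  # 3 carriers
encode_text <- function(text, scheme = encoding_scheme("a5")) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) return(list())
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  lapply(words, function(w) {
    bits <- switch(scheme$scheme_id,
                   a5 = encode_word_a5(w, scheme),
                   ascii8 = encode_word_ascii8(w, scheme))
    g <- new_message_grid(bits,
                          matrix(0L, scheme$address_rows, scheme$grid_cols),
                          scheme_id = scheme$scheme_id)
    if (scheme$spacing_rule == "inter_character_blank_column") {
      g <- apply_spacing(g, scheme)
    }
    g
  })
}

#' Insert blank columns between character columns
#'
#' Moves the packed character columns of an unspaced grid onto every other
#' column, leaving all-zero columns between consecutive characters. If the
#' spaced layout does not fit the grid, spacing is dropped with a warning
#' instead of rejecting the word. The total number of 1-bits is unchanged.
#'
#' @param grid an unscrambled `message_grid` with packed character columns.
#' @param scheme the scheme in force (`spacing_rule` must request spacing).
#' @return the grid, possibly with `spaced = TRUE`.
#' @export
apply_spacing <- function(grid, scheme) {
  if (scheme$spacing_rule != "inter_character_blank_column") return(grid)
  if (grid$scrambled) ddc_error("cannot space a scrambled grid", "ddc_state_error")
  if (grid$spaced) return(grid)
  occupied <- which(colSums(grid$bits) > 0)
  if (length(occupied) == 0) return(grid)
  k <- max(occupied)
  need <- 2L * k - 1L
  if (need > ncol(grid$bits)) {
    warning(sprintf("spacing dropped: %d characters need %d columns, grid has %d",
                    k, need, ncol(grid$bits)), call. = FALSE)
    return(grid)
  }
  bits <- matrix(0L, nrow(grid$bits), ncol(grid$bits))
  bits[, seq(1L, need, by = 2L)] <- grid$bits[, seq_len(k)]
  grid$bits <- bits
  grid$spaced <- TRUE
  grid
}

#' Write a carrier's word index into its address row
#'
#' The address row (row above the message array) stores the binary expansion
#' of `word_index`, most-significant bit leftmost. With the default 1 x 5 row
#' the system distinguishes `2^5 = 32` carriers.
#'
#' @param grid a `message_grid`.
#' @param word_index integer in `[0, 2^(address_rows * grid_cols) - 1]`.
#' @param scheme the [encoding_scheme()].
#' @return the grid with its address row and `word_index` set.
#' @export
assign_address <- function(grid, word_index, scheme = encoding_scheme(grid$scheme_id)) {
  nbits <- scheme$address_rows * scheme$grid_cols
  if (word_index < 0 || word_index >= 2^nbits) {
    ddc_error(sprintf("word_index %d outside address capacity [0, %d)",
                      word_index, 2^nbits),
              "ddc_address_error")
  }
  bits <- int_to_bits(word_index, nbits)
  grid$address <- matrix(bits, nrow = scheme$address_rows, byrow = TRUE)
  grid$word_index <- as.integer(word_index)
  grid
}

#' Read a word index back from the address row
#' @param grid a `message_grid`.
#' @return integer word index (MSB-leftmost convention).
#' @export
address_index <- function(grid) {
  bits_to_int(as.integer(t(grid$address)))
}

# Column shifts of the "colshift" permutation family: column c (0-based) is
# shifted cyclically downward by (word_index + c) mod grid_rows.
colshift_shifts <- function(word_index, n_rows, n_cols) {
  (word_index + (seq_len(n_cols) - 1L)) %% n_rows
}

shift_column <- function(v, s) {
  n <- length(v)
  s <- s %% n
  if (s == 0) v else c(v[(n - s + 1L):n], v[seq_len(n - s)])
}

#' Mix message bits under the address-keyed permutation
#'
#' Applies the `colshift` permutation: column *c* (0-based) of the message
#' array is cyclically shifted downward by `(word_index + c) mod grid_rows`,
#' where `word_index` is read from the address row. The address row itself is
#' untouched, so the permutation is invertible by [descramble()] from the
#' observed pattern alone. The multiset of message bits is conserved.
#'
#' @param grid an unscrambled `message_grid` with its address assigned.
#' @return the scrambled grid.
#' @export
scramble <- function(grid) {
  if (grid$scrambled) ddc_error("grid is already scrambled", "ddc_state_error")
  wi <- address_index(grid)
  shifts <- colshift_shifts(wi, nrow(grid$bits), ncol(grid$bits))
  for (j in seq_len(ncol(grid$bits))) {
    grid$bits[, j] <- shift_column(grid$bits[, j], shifts[j])
  }
  grid$scrambled <- TRUE
  grid$word_index <- as.integer(wi)
  grid
}

#' Invert the address-keyed permutation
#'
#' Exact inverse of [scramble()]. The shifts are recomputed from the address
#' row, never from message content, so any observer holding the pattern can
#' reorder it once the carrier has been opened.
#'
#' @param grid a scrambled `message_grid`.
#' @return the unscrambled grid (`word_index` refreshed from the address row).
#' @export
descramble <- function(grid) {
  if (!grid$scrambled) ddc_error("grid is not scrambled", "ddc_state_error")
  wi <- address_index(grid)
  shifts <- colshift_shifts(wi, nrow(grid$bits), ncol(grid$bits))
  for (j in seq_len(ncol(grid$bits))) {
    grid$bits[, j] <- shift_column(grid$bits[, j], -shifts[j])
  }
  grid$scrambled <- FALSE
  grid$word_index <- as.integer(wi)
  grid
}

decode_word <- function(grid, scheme) {
  if (grid$scrambled) ddc_error("descramble the grid before decoding", "ddc_state_error")
  if (scheme$scheme_id == "a5") {
    vals <- apply(grid$bits[seq_len(5L), , drop = FALSE], 2, bits_to_int)
    paste(a5_char(vals), collapse = "")
  } else {
    stream <- as.integer(grid$bits)   # column-major
    nbytes <- (length(stream)) %/% 8L
    bytes <- vapply(seq_len(nbytes),
                    function(i) bits_to_int(stream[(8L * (i - 1L) + 1L):(8L * i)]),
                    integer(1))
    bytes <- bytes[bytes != 0]
    if (length(bytes) == 0) "" else intToUtf8(bytes, multiple = FALSE)
  }
}

#' Decode descrambled grids back to plaintext
#'
#' Orders carriers by their address word index, strips blank/pad columns, and
#' maps column codes to characters. Codes outside the alphabet degrade to the
#' fallback glyph `?`; decoding never fails on noisy data.
#'
#' @param grids list of descrambled `message_grid` objects.
#' @param scheme the [encoding_scheme()].
#' @return the recovered plaintext (words joined by single spaces; all-blank
#'   carriers contribute nothing).
#' @export
decode_text <- function(grids, scheme = encoding_scheme("a5")) {
  if (length(grids) == 0) return("")
  wi <- vapply(grids, function(g) g$word_index, integer(1))
  if (!anyNA(wi)) grids <- grids[order(wi)]
  words <- vapply(grids, decode_word, character(1), scheme = scheme)
  paste(words[nzchar(words)], collapse = " ")
}

#' Render a grid as ciphertext
#'
#' Displays what a reader sees on an unopened (OFF, scrambled) carrier:
#' 5-bit column values `v` render as the character with code `64 + v`
#' (so `v = 1..26` are `A..Z`, `v = 28` is `\`), `v = 0` as a space. This is
#' the character inventory of scrambled text such as "PDTDB XUUUI \\PBXDL".
#'
#' @param grids a `message_grid` or list of them.
#' @return one string per input grid, trailing spaces trimmed.
#' @export
render_ciphertext <- function(grids) {
  if (inherits(grids, "message_grid")) grids <- list(grids)
  vapply(grids, function(g) {
    vals <- apply(g$bits[seq_len(min(5L, nrow(g$bits))), , drop = FALSE], 2, bits_to_int)
    chs <- vapply(vals, function(v) if (v == 0) " " else intToUtf8(64L + v), character(1))
    sub(" +$", "", paste(chs, collapse = ""))
  }, character(1))
}

#' One-call pipeline: encode, address, scramble
#'
#' Convenience wrapper producing the physical (scrambled) carrier grids for a
#' message: [encode_text()], then [assign_address()] with consecutive word
#' indices, then [scramble()].
#'
#' @inheritParams encode_text
#' @return list of scrambled `message_grid` objects.
#' @export
encode_message <- function(text, scheme = encoding_scheme("a5")) {
  grids <- encode_text(text, scheme)
  lapply(seq_along(grids), function(i) {
    scramble(assign_address(grids[[i]], i - 1L, scheme))
  })
}

#' One-call pipeline: descramble and decode
#' @param grids list of scrambled `message_grid` objects.
#' @inheritParams encode_text
#' @return recovered plaintext.
#' @export
decode_message_grids <- function(grids, scheme = encoding_scheme("a5")) {
  decode_text(lapply(grids, descramble), scheme)
}
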