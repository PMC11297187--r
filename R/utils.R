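`%||%` <- function(a, b) if (is.null(a)) b else a

# Excel-style bijective base-26 letters: 1->A, 26->Z, 27->AA, ...
.letter_name <- function(i) {
  out <- ""
  while (i > 0) {
    r <- (i - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}
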