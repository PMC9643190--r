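# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
#' Clean an amino-acid sequence: strip '*' (with a warning), map any letter
#' outside the 20 standard residues + X to X. Input and output are plain
#' uppercase character scalars.
sanitize_aa <- function(seq, id = "<sequence>") {
  seq <- toupper(seq)
  if (grepl("*", seq, fixed = TRUE)) {
    warning(sprintf("sequence %s contains '*'; stripped", id), call. = FALSE)
    seq <- gsub("*", "", seq, fixed = TRUE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(AA20, "X"))
  if (any(bad)) chars[bad] <- "X"
  paste(chars, collapse = "")
}

#' @noRd
#' Derive a 32-bit-safe RNG seed from a base seed and an integer stream id.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 1103L + as.double(stream) * 7919) %% 2147483646
  as.integer(s) + 1L
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
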