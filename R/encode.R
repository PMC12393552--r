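#' One-hot encode a DNA sequence
#'
#' Encodes A, C, G, T as the four unit rows of a `length x 4` matrix and N
#' (any ambiguous base) as an all-zero row. Case-insensitive.
#'
#' @param sequence A DNA string over A/C/G/T/N (upper or lower case).
#' @return A numeric matrix of shape `(nchar(sequence), 4)` with columns
#'   ordered A, C, G, T.
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n == 0L) return(matrix(0, 0L, 4L, dimnames = list(NULL, c("A", "C", "G", "T"))))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  bad <- which(is.na(idx) & chars != "N")
  if (length(bad) > 0L) {
    stop(errorCondition(
      sprintf("cannot encode character '%s' at position %d", chars[bad[1]], bad[1]),
      class = c("s2t_encoding_error", "error")))
  }
  m <- matrix(0, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot encoding back to a DNA string
#'
#' Inverse of [one_hot_encode()]: unit rows map back to A/C/G/T and all-zero
#' rows to N.
#'
#' @param encoding A `(length, 4)` one-hot matrix.
#' @return A DNA string.
#' @export
one_hot_decode <- function(encoding) {
  stopifnot(is.matrix(encoding), ncol(encoding) == 4L)
  if (nrow(encoding) == 0L) return("")
  idx <- max.col(encoding, ties.method = "first")
  hit <- rowSums(encoding) > 0
  chars <- rep("N", nrow(encoding))
  chars[hit] <- c("A", "C", "G", "T")[idx[hit]]
  paste(chars, collapse = "")
}
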