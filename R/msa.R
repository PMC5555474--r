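#' Reference-anchored multiple alignment
#'
#' Builds a multiple alignment by aligning every sequence pairwise to one
#' reference and merging on the reference coordinate system: insertions
#' relative to the reference open a gap column block whose width is the
#' longest insertion observed at that reference position. This is exact
#' for datasets whose members differ from the reference mainly by
#' substitutions (the RIP situation) and is a reasonable anchor alignment
#' otherwise; it makes no attempt to align the inserted segments against
#' each other.
#'
#' @param sequences named character vector of ungapped sequences.
#' @param reference ungapped reference string; also returned as a row under
#'   `ref_name`.
#' @param ref_name row name for the reference (default `"reference"`); set
#'   `NULL` to omit the reference row.
#' @return Named character vector of equal-length gapped rows.
#' @export
anchor_msa <- function(sequences, reference, ref_name = "reference") {
  L <- nchar(reference)
  # per sequence: list(ins = insertion strings at ref slots 0..L,
  #                    at  = query char aligned to each ref base)
  parsed <- lapply(sequences, function(s) {
    aln <- pairwise_align(s, reference)
    q <- seq_to_chars(aln$query)
    r <- seq_to_chars(aln$reference)
    ins <- character(L + 1L)
    at <- character(L)
    slot <- 0L
    buf <- character(0)
    for (col in seq_along(r)) {
      if (r[col] == "-") {
        buf <- c(buf, q[col])
      } else {
        ins[slot + 1L] <- chars_to_seq(buf)
        buf <- character(0)
        slot <- slot + 1L
        at[slot] <- q[col]
      }
    }
    ins[L + 1L] <- chars_to_seq(buf)
    list(ins = ins, at = at)
  })
  ins_width <- rep(0L, L + 1L)
  for (p in parsed)
    ins_width <- pmax(ins_width, nchar(p$ins))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  build <- function(ins, at) {
    parts <- character(2L * L + 1L)
    for (t in 0:L) {
      parts[2L * t + 1L] <- if (ins_width[t + 1L] > 0)
        pad(ins[t + 1L], ins_width[t + 1L]) else ""
      if (t < L) parts[2L * t + 2L] <- at[t + 1L]
    }
    paste(parts, collapse = "")
  }
  rows <- vapply(parsed, function(p) build(p$ins, p$at), character(1))
  names(rows) <- names(sequences)
  if (!is.null(ref_name)) {
    ref_row <- build(rep("", L + 1L), seq_to_chars(reference))
    rows <- c(setNames(ref_row, ref_name), rows)
  }
  rows
}
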