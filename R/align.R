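#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch-Gotoh alignment of two ungapped DNA sequences. The score
#' of a gap of length L is `-(gap_open + L * gap_ext)`. Ties are broken
#' deterministically: diagonal moves are preferred over a gap in the query,
#' which is preferred over a gap in the reference, so repeated runs always
#' return the same alignment.
#'
#' @param query,reference ungapped DNA strings.
#' @param match,mismatch,gap_open,gap_ext scoring parameters (defaults
#'   +1/-1/5/1).
#' @return A list with elements `query` and `reference` (equal-length gapped
#'   strings using `-`) and `score`.
#' @examples
#' pairwise_align("ACGT", "AGT")
#' @export
pairwise_align <- function(query, reference, match = 1L, mismatch = -1L,
                           gap_open = 5L, gap_ext = 1L) {
  if (!nzchar(query) || !nzchar(reference))
    stop("query and reference must be non-empty", call. = FALSE)
  .cpp_align_global(query, reference, as.integer(match), as.integer(mismatch),
                    as.integer(gap_open), as.integer(gap_ext))
}

#' Local pairwise alignment with affine gap costs
#'
#' Smith-Waterman-Gotoh local alignment, same scoring and tie-breaking
#' conventions as [pairwise_align()]. Used by the repeat-mining and
#' subunit-annotation steps.
#'
#' @inheritParams pairwise_align
#' @return A list with gapped `query`/`reference` strings, `score`, and
#'   1-based inclusive coordinates `query_start`, `query_end`, `ref_start`,
#'   `ref_end` of the aligned segment (all 0 when no positive-scoring local
#'   alignment exists).
#' @export
local_align <- function(query, reference, match = 1L, mismatch = -1L,
                        gap_open = 5L, gap_ext = 1L) {
  if (!nzchar(query) || !nzchar(reference))
    stop("query and reference must be non-empty", call. = FALSE)
  .cpp_align_local(query, reference, as.integer(match), as.integer(mismatch),
                   as.integer(gap_open), as.integer(gap_ext))
}

#' Fraction of identical columns in a gapped alignment
#'
#' Identity is the number of matching columns divided by the total number of
#' alignment columns (gap columns count in the denominator). Columns where
#' either sequence carries an IUPAC ambiguity code are excluded from both
#' numerator and denominator.
#'
#' @param a,b equal-length gapped strings.
#' @return A fraction in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  ca <- seq_to_chars(a); cb <- seq_to_chars(b)
  if (length(ca) != length(cb))
    stop("gapped sequences have unequal lengths", call. = FALSE)
  plain <- c(DNA_BASES, "-")
  keep <- ca %in% plain & cb %in% plain
  if (!any(keep)) return(0)
  sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep)
}
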