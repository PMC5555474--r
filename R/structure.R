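#' Parse a dot-bracket secondary structure into a pairing table
#'
#' Accepts plain nested brackets (`(`, `)`, `.`). Crossing (pseudoknot)
#' bracket types are not supported and raise an error.
#'
#' @param dotbracket dot-bracket string.
#' @return Data frame with 1-based columns `i`, `j` (`i < j`).
#' @export
dotbracket_to_pairs <- function(dotbracket) {
  chars <- seq_to_chars(dotbracket)
  if (any(!chars %in% c("(", ")", ".")))
    stop("unsupported characters in dot-bracket string ",
         "(pseudoknot bracket types are not supported)", call. = FALSE)
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced brackets at position ", k, call. = FALSE)
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced brackets: ", length(stack), " unclosed", call. = FALSE)
  o <- order(pi)
  data.frame(i = pi[o], j = pj[o])
}

#' Read a base-pairing table
#'
#' Reads either a two-column TSV of 1-based paired positions (columns `i`,
#' `j`, header optional) or a file whose single line is a dot-bracket
#' string.
#'
#' @param path file path.
#' @return Data frame with columns `i`, `j`.
#' @export
read_pairing_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^[().]+$", first)) {
    return(dotbracket_to_pairs(first))
  }
  has_header <- grepl("[A-Za-z]", first)
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("pairing TSV needs two columns", call. = FALSE)
  pairs <- data.frame(i = as.integer(tab[[1]]), j = as.integer(tab[[2]]))
  validate_pairing(pairs)
  pairs
}

validate_pairing <- function(pairs, ref_length = NULL) {
  if (any(pairs$i >= pairs$j))
    stop("pairing table requires i < j", call. = FALSE)
  all_pos <- c(pairs$i, pairs$j)
  if (anyDuplicated(all_pos))
    stop("a position appears in more than one pair", call. = FALSE)
  if (!is.null(ref_length) && any(all_pos < 1L | all_pos > ref_length))
    stop("pairing positions outside the reference", call. = FALSE)
  invisible(pairs)
}

.valid_rna_pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
.valid_wc_pairs <- c("AT", "TA", "GC", "CG")

#' Map mutations onto a secondary-structure pairing table
#'
#' Each mutation falls either on a paired or an unpaired reference
#' position. A mutation at a paired position is *disrupting* when the
#' post-mutation base pair (DNA read as RNA, T standing for U) is no longer
#' a valid pair; by default the valid set is Watson-Crick plus the GU
#' wobble (AU, UA, GC, CG, GU, UG), the standard convention for rRNA
#' structure. Compensated double mutations that restore a valid pair are
#' therefore not counted as disruptions.
#'
#' @param mutations data frame with columns `position` (1-based on the
#'   reference), `ref`, `alt`.
#' @param pairs pairing table (data frame `i`, `j`) from
#'   [read_pairing_table()] or [dotbracket_to_pairs()].
#' @param reference ungapped reference DNA string the positions refer to.
#' @param wobble logical; count GU/UG as valid (default `TRUE`). `FALSE`
#'   gives strict Watson-Crick pairing.
#' @return Object of class `structure_impact`: list with `n_paired_mut`,
#'   `n_unpaired_mut`, `disrupted` (data frame: i, j, ref_pair, mut_pair),
#'   and `annotation` (per-mutated-position data frame: position, status in
#'   {paired, unpaired, disrupted}).
#' @export
map_mutations_to_structure <- function(mutations, pairs, reference,
                                       wobble = TRUE) {
  check_dna(reference, "reference")
  chars <- seq_to_chars(reference)
  validate_pairing(pairs, ref_length = length(chars))
  if (nrow(mutations)) {
    bad <- mutations$position < 1L | mutations$position > length(chars)
    if (any(bad))
      stop("mutation positions outside the reference: ",
           paste(mutations$position[bad], collapse = ", "), call. = FALSE)
    mism <- chars[mutations$position] != mutations$ref
    if (any(mism))
      stop("reference base mismatch at positions: ",
           paste(mutations$position[mism], collapse = ", "), call. = FALSE)
  }
  valid <- if (wobble) .valid_rna_pairs else .valid_wc_pairs

  partner <- integer(length(chars))  # 0 = unpaired
  partner[pairs$i] <- pairs$j
  partner[pairs$j] <- pairs$i

  # post-mutation sequence (apply all mutations, so compensatory double
  # mutations are judged on the final pair)
  mutated <- chars
  if (nrow(mutations)) mutated[mutations$position] <- mutations$alt

  n_paired <- 0L; n_unpaired <- 0L
  disrupted <- list()
  status <- character(nrow(mutations))
  seen_pairs <- character(0)
  for (k in seq_len(nrow(mutations))) {
    p <- mutations$position[k]
    q <- partner[p]
    if (q == 0L) {
      n_unpaired <- n_unpaired + 1L
      status[k] <- "unpaired"
      next
    }
    n_paired <- n_paired + 1L
    i <- min(p, q); j <- max(p, q)
    mut_pair <- paste0(mutated[i], mutated[j])
    if (!mut_pair %in% valid) {
      status[k] <- "disrupted"
      key <- paste(i, j)
      if (!key %in% seen_pairs) {   # a pair is reported once even if both
        seen_pairs <- c(seen_pairs, key)  # partners are mutated
        disrupted[[length(disrupted) + 1L]] <- data.frame(
          i = i, j = j,
          ref_pair = paste0(chars[i], chars[j]),
          mut_pair = mut_pair, stringsAsFactors = FALSE)
      }
    } else {
      status[k] <- "paired"
    }
  }
  disrupted <- if (length(disrupted)) do.call(rbind, disrupted) else
    data.frame(i = integer(0), j = integer(0), ref_pair = character(0),
               mut_pair = character(0), stringsAsFactors = FALSE)
  structure(list(
    n_paired_mut = n_paired,
    n_unpaired_mut = n_unpaired,
    disrupted = disrupted,
    annotation = data.frame(position = mutations$position,
                            status = status, stringsAsFactors = FALSE)
  ), class = "structure_impact")
}

#' @export
print.structure_impact <- function(x, ...) {
  cat("structure impact: ", x$n_paired_mut, " mutations at paired sites (",
      nrow(x$disrupted), " disrupted pairs), ", x$n_unpaired_mut,
      " at unpaired sites\n", sep = "")
  invisible(x)
}

#' Write a per-position structure annotation file
#'
#' BED-like TSV (1-based inclusive single positions) with status
#' paired/unpaired/disrupted for each mutated position.
#'
#' @param impact a `structure_impact` object.
#' @param path output path.
#' @export
write_structure_annotation <- function(impact, path) {
  ann <- impact$annotation
  ann <- data.frame(start = ann$position, end = ann$position,
                    status = ann$status)
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
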