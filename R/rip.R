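#' Dinucleotide context class of one RIP transition
#'
#' RIP transitions are classified by the dinucleotide the mutated base sat
#' in, read from the consensus (the highest-GC sequence), never from the
#' mutated query whose neighbor may itself be RIPped. A C-to-T change is
#' classified by the nearest non-gap consensus base 3' of the column
#' (CpA/CpC/CpG/CpT); a G-to-A change by the nearest non-gap consensus base
#' 5', which is the same context read on the reverse complement (TpG pairs
#' with CpA, GpG with CpC, CpG with CpG, ApG with CpT). A site at the
#' sequence edge with no neighbor is `"unclassified"`.
#'
#' @param consensus gapped consensus string.
#' @param column 1-based alignment column of the mutation.
#' @param ref_base consensus base at the column, `"C"` or `"G"`.
#' @param alt_base query base, `"T"` (for C) or `"A"` (for G).
#' @return One of `"CpA"`, `"CpC"`, `"CpG"`, `"CpT"`, `"unclassified"`.
#' @export
classify_rip_context <- function(consensus, column, ref_base, alt_base) {
  chars <- seq_to_chars(toupper(consensus))
  if (column < 1L || column > length(chars))
    stop("column outside the alignment", call. = FALSE)
  ok <- (ref_base == "C" && alt_base == "T") ||
        (ref_base == "G" && alt_base == "A")
  if (!ok)
    stop("only C>T and G>A changes have a RIP context", call. = FALSE)
  if (ref_base == "C") {
    j <- column + 1L
    while (j <= length(chars) && chars[j] == "-") j <- j + 1L
    if (j > length(chars) || !chars[j] %in% DNA_BASES)
      return("unclassified")
    paste0("Cp", chars[j])
  } else {
    j <- column - 1L
    while (j >= 1L && chars[j] == "-") j <- j - 1L
    if (j < 1L || !chars[j] %in% DNA_BASES)
      return("unclassified")
    paste0("Cp", .complement[[chars[j]]])
  }
}

#' RIP mutation profile of a paralog against the consensus
#'
#' Scans an aligned query/consensus pair, classifies every C-to-T and
#' G-to-A difference by dinucleotide context, and summarizes:
#' `rip_rate` = RIP transitions / aligned sites (the same denominator as
#' [mutation_spectrum()], so `rip_rate` always equals `gA_rate + cT_rate`);
#' `dominance` = CpA-class count over the summed count of the other three
#' classes (guarded at 1 with `dominance_flagged = TRUE` when those classes
#' are empty); and `preference`, the opportunity-normalized counterpart of
#' dominance: the CpA-class per-eligible-site mutation frequency divided by
#' the pooled frequency of the other three classes, where eligible sites
#' are counted on the consensus. `preference` is the statistic to test when
#' asking whether CpA/TpG sites are mutated *more frequently* than other
#' contexts, because raw counts confound rate with opportunity.
#'
#' @param gapped_query,gapped_consensus equal-length gapped strings; the
#'   consensus is the highest-GC sequence of the dataset.
#' @return Object of class `rip_profile`: list with `context_counts` (named
#'   over CpA/CpC/CpG/CpT/unclassified), `eligible_sites` (consensus C/G
#'   sites per context, aligned columns only), `rip_rate`, `aligned_sites`,
#'   `dominance`, `dominance_flagged`, `preference`.
#' @export
compute_rip_profile <- function(gapped_query, gapped_consensus) {
  q <- seq_to_chars(toupper(gapped_query))
  r <- seq_to_chars(toupper(gapped_consensus))
  if (length(q) != length(r))
    stop("gapped sequences have unequal lengths", call. = FALSE)
  plain <- q %in% DNA_BASES & r %in% DNA_BASES
  counts <- setNames(integer(5L), c(RIP_CONTEXTS, "unclassified"))
  eligible <- setNames(integer(5L), c(RIP_CONTEXTS, "unclassified"))

  rip_cols <- which(plain & ((r == "C" & q == "T") | (r == "G" & q == "A")))
  for (col in rip_cols) {
    ctx <- classify_rip_context(gapped_consensus, col, r[col], q[col])
    counts[ctx] <- counts[ctx] + 1L
  }
  # opportunity: every aligned consensus C/G site, by its own context
  elig_cols <- which(plain & (r == "C" | r == "G"))
  for (col in elig_cols) {
    alt <- if (r[col] == "C") "T" else "A"
    ctx <- classify_rip_context(gapped_consensus, col, r[col], alt)
    eligible[ctx] <- eligible[ctx] + 1L
  }

  aligned <- sum(plain)
  n_rip <- sum(counts)
  other <- sum(counts[c("CpC", "CpG", "CpT")])
  flagged <- other == 0L
  dominance <- counts[["CpA"]] / max(1L, other)
  rate_cpa <- if (eligible[["CpA"]] > 0) counts[["CpA"]] / eligible[["CpA"]]
              else NA_real_
  other_elig <- sum(eligible[c("CpC", "CpG", "CpT")])
  rate_other <- if (other_elig > 0) other / other_elig else NA_real_
  preference <- if (!is.na(rate_cpa) && !is.na(rate_other) && rate_other > 0)
    rate_cpa / rate_other else NA_real_

  structure(list(
    context_counts = counts,
    eligible_sites = eligible,
    rip_rate = if (aligned > 0) n_rip / aligned else 0,
    aligned_sites = aligned,
    dominance = dominance,
    dominance_flagged = flagged,
    preference = preference
  ), class = "rip_profile")
}

#' @export
print.rip_profile <- function(x, ...) {
  cat("RIP profile: rate ", sprintf("%.4f", x$rip_rate),
      ", dominance ", sprintf("%.2f", x$dominance),
      if (x$dominance_flagged) " (flagged: no non-CpA mutations)", "\n",
      sep = "")
  print(x$context_counts)
  invisible(x)
}

#' Windowed RIP mutation track across an alignment
#'
#' Produces the table behind a RIPCAL-style mutation heat map: for every
#' sequence and every window of alignment columns, the count of RIP
#' transitions per context class, plus invariant and gap columns tallied
#' separately. With `step == window` the windows tile the alignment and
#' their sums reproduce the global per-class counts.
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences; the consensus (highest-GC sequence) must be one of them or
#'   supplied via `consensus_id`.
#' @param consensus_id id of the consensus sequence; default: the sequence
#'   with the highest GC (ties by smallest id).
#' @param window,step window width and step in alignment columns; window
#'   must be at least step, step at least 1. A window wider than the
#'   alignment yields one window.
#' @return Data frame: sequence id, window start/end (1-based columns), one
#'   count column per context class (+ unclassified), other_mut (non-RIP
#'   differences), invariant, gaps.
#' @export
windowed_rip <- function(alignment, consensus_id = NULL,
                         window = 100L, step = window) {
  if (step < 1L || window < step)
    stop("need window >= step >= 1", call. = FALSE)
  ids <- names(alignment)
  width <- unique(nchar(alignment))
  if (length(width) != 1L)
    stop("alignment rows must have equal gapped length", call. = FALSE)
  if (is.null(consensus_id)) {
    gc <- vapply(alignment, gc_content, numeric(1))
    consensus_id <- sort(names(gc)[gc == max(gc)])[1L]
  }
  cons <- alignment[[consensus_id]]
  cons_chars <- seq_to_chars(toupper(cons))
  if (window > width) window <- width

  # windows tile through the end of the alignment; the final window is
  # truncated rather than dropped so that concatenating step == window
  # tracks reproduces the global counts
  starts <- seq.int(1L, width, by = step)
  starts <- starts[starts <= width]
  classes <- c(RIP_CONTEXTS, "unclassified")
  rows <- list()
  for (id in setdiff(ids, consensus_id)) {
    q <- seq_to_chars(toupper(alignment[[id]]))
    plain <- q %in% DNA_BASES & cons_chars %in% DNA_BASES
    is_rip <- plain & ((cons_chars == "C" & q == "T") |
                       (cons_chars == "G" & q == "A"))
    ctx_all <- rep(NA_character_, width)
    for (col in which(is_rip))
      ctx_all[col] <- classify_rip_context(cons, col, cons_chars[col], q[col])
    other_mut <- plain & q != cons_chars & !is_rip
    invariant <- plain & q == cons_chars
    gap <- q == "-" | cons_chars == "-"
    for (s in starts) {
      e <- min(s + window - 1L, width)
      cols <- s:e
      cnt <- vapply(classes, function(cl)
        sum(ctx_all[cols] == cl, na.rm = TRUE), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = id, start = s, end = e,
        CpA = cnt[["CpA"]], CpC = cnt[["CpC"]], CpG = cnt[["CpG"]],
        CpT = cnt[["CpT"]], unclassified = cnt[["unclassified"]],
        other_mut = sum(other_mut[cols]),
        invariant = sum(invariant[cols]),
        gaps = sum(gap[cols]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
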