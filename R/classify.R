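#' GC content of a DNA sequence
#'
#' Fraction of G+C among counted bases. Gap characters (`-`) and IUPAC
#' ambiguity codes are removed before counting.
#'
#' @param sequence DNA string, possibly gapped.
#' @return Numeric fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  chars <- seq_to_chars(toupper(sequence))
  chars <- chars[chars %in% DNA_BASES]
  if (length(chars) == 0L)
    stop("no unambiguous bases to count", call. = FALSE)
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Split paralogs into high-GC and low-GC groups at the largest gap
#'
#' Intragenomic rDNA paralogs hit by RIP have markedly lowered GC, so
#' within one genome the GC values of a subunit fall into two
#' non-overlapping bands (functional roughly 46-53%, pseudogenic below
#' ~45%). The split point is the largest gap in the sorted GC values; when
#' that gap is below `min_gap` the distribution is treated as unimodal and
#' everything is returned in the high group.
#'
#' @param gc numeric vector of GC values (fractions or percentages, as long
#'   as `min_gap` uses the same units); may be named with paralog ids.
#' @param min_gap minimum gap width to accept a two-group split; default
#'   0.02 (two percentage points when `gc` is a fraction).
#' @return List with `high` and `low` (named GC subvectors), `gap` (width of
#'   the largest gap), and `threshold` (midpoint of the gap; `NA` when no
#'   split is made).
#' @export
split_gc_groups <- function(gc, min_gap = 0.02) {
  if (length(gc) < 2L) stop("need at least two GC values", call. = FALSE)
  o <- order(gc)
  sorted <- gc[o]
  gaps <- diff(sorted)
  k <- which.max(gaps)
  gap <- unname(gaps[k])
  if (gap < min_gap) {
    return(list(high = gc, low = gc[0], gap = gap, threshold = NA_real_))
  }
  thr <- (sorted[k] + sorted[k + 1L]) / 2
  list(high = gc[gc > thr], low = gc[gc <= thr], gap = gap, threshold = thr)
}

#' Directed substitution spectrum of an aligned pair
#'
#' Counts each of the 12 directed substitution classes (reference base to
#' query base) column by column. Columns with a gap in either sequence are
#' counted in `indel_columns` and excluded from `aligned_sites`; columns
#' with an ambiguity code in either sequence are excluded from both.
#'
#' @param gapped_query,gapped_reference equal-length gapped strings.
#' @return Object of class `mutation_spectrum`: list with `counts` (named
#'   integer vector over the 12 classes, e.g. `"C>T"`), `indel_columns`,
#'   `aligned_sites`, and `rates` (counts / aligned_sites).
#' @export
mutation_spectrum <- function(gapped_query, gapped_reference) {
  q <- seq_to_chars(toupper(gapped_query))
  r <- seq_to_chars(toupper(gapped_reference))
  if (length(q) != length(r))
    stop("gapped sequences have unequal lengths", call. = FALSE)
  is_gap_q <- q == "-"; is_gap_r <- r == "-"
  indel <- xor(is_gap_q, is_gap_r) | (is_gap_q & is_gap_r)
  plain <- q %in% DNA_BASES & r %in% DNA_BASES
  counts <- setNames(integer(length(SUBST_CLASSES)), SUBST_CLASSES)
  diffs <- plain & q != r
  if (any(diffs)) {
    tab <- table(paste0(r[diffs], ">", q[diffs]))
    counts[names(tab)] <- as.integer(tab)
  }
  aligned <- sum(plain)
  structure(list(
    counts = counts,
    indel_columns = sum(indel),
    aligned_sites = aligned,
    rates = if (aligned > 0) counts / aligned else counts * 0
  ), class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("mutation spectrum over", x$aligned_sites, "aligned sites,",
      x$indel_columns, "indel columns\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Transition rates of a mutation spectrum
#'
#' The two RIP transition classes are reported separately; everything else
#' is pooled. All rates use aligned (gap-free, unambiguous) sites as the
#' denominator.
#'
#' @param spectrum a [mutation_spectrum()] object.
#' @return List with `gA_rate` (G-to-A), `cT_rate` (C-to-T) and
#'   `other_rate` (all remaining substitution classes).
#' @export
transition_rates <- function(spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  n <- spectrum$aligned_sites
  if (n == 0L) return(list(gA_rate = 0, cT_rate = 0, other_rate = 0))
  ga <- spectrum$counts[["G>A"]]
  ct <- spectrum$counts[["C>T"]]
  other <- sum(spectrum$counts) - ga - ct
  list(gA_rate = ga / n, cT_rate = ct / n, other_rate = other / n)
}

#' Call a paralog functional, pseudogene, or undetermined
#'
#' A paralog is called a pseudogene when it sits in the low-GC group, shows
#' at least one G-to-A or C-to-T transition against the highest-GC
#' reference, and its non-RIP substitutions are consistent with the
#' error-like noise level `max_other_rate` ("uniform C-to-T and G-to-A
#' mutations"; other substitution types at noise frequency, below 0.1%, do
#' not argue against a RIP origin). Consistency is a one-sided binomial
#' test: the call is demoted to undetermined only when the observed
#' non-RIP count is significantly above `max_other_rate` at level `alpha`
#' — a hard cutoff at exactly the noise mean would reject about half of
#' the genuine pseudogenes on sampling noise alone. Members of the high-GC
#' group are functional.
#'
#' @param group `"high_gc"`, `"low_gc"`, or `"unassigned"`.
#' @param spectrum [mutation_spectrum()] of the paralog against the
#'   highest-GC reference of its subunit.
#' @param max_other_rate tolerated non-RIP substitution rate; default
#'   0.001, the error-like noise level.
#' @param alpha significance level of the noise-consistency test (default
#'   0.01); `alpha = 1` recovers a hard cutoff at `max_other_rate`.
#' @return `"functional"`, `"pseudogene"`, or `"undetermined"`.
#' @export
call_pseudogene <- function(group, spectrum, max_other_rate = 0.001,
                            alpha = 0.01) {
  if (is.na(group) || !group %in% c("high_gc", "low_gc", "unassigned"))
    stop("paralog has no GC group assigned", call. = FALSE)
  if (group == "high_gc") return("functional")
  if (group == "unassigned") return("undetermined")
  tr <- transition_rates(spectrum)
  if ((tr$gA_rate + tr$cT_rate) <= 0) return("undetermined")
  n <- spectrum$aligned_sites
  other_count <- round(tr$other_rate * n)
  # P(X >= observed) under Binomial(n, max_other_rate)
  p_excess <- pbinom(other_count - 1L, n, max_other_rate,
                     lower.tail = FALSE)
  if (alpha >= 1) {
    if (tr$other_rate <= max_other_rate) "pseudogene" else "undetermined"
  } else if (p_excess >= alpha) "pseudogene" else "undetermined"
}

#' Classify a set of paralog subunit sequences
#'
#' End-to-end classification of one subunit's paralogs within a dataset:
#' computes GC, splits GC groups at the largest gap, picks the single
#' highest-GC sequence as the functional reference (ties broken by
#' lexicographically smallest id), aligns every paralog to it globally, and
#' calls each paralog. Sequences may be pre-aligned (pass
#' `aligned = TRUE` to skip the alignment step and use the gapped input
#' as-is against the reference).
#'
#' @param sequences named character vector of paralog sequences (one
#'   subunit).
#' @param min_gap passed to [split_gc_groups()].
#' @param max_other_rate,alpha passed to [call_pseudogene()].
#' @param aligned logical; `TRUE` when `sequences` are rows of one multiple
#'   alignment (equal gapped lengths).
#' @return Object of class `paralog_classification`: list with `table`
#'   (data frame: paralog_id, gc, group, gA_rate, cT_rate, other_rate,
#'   call), `reference` (id of the highest-GC sequence), `alignments`
#'   (list of gapped query/reference pairs per paralog), and `threshold`
#'   (GC split point).
#' @export
classify_paralogs <- function(sequences, min_gap = 0.02,
                              max_other_rate = 0.001, alpha = 0.01,
                              aligned = FALSE) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names", call. = FALSE)
  gc <- vapply(sequences, gc_content, numeric(1))
  grp <- split_gc_groups(gc, min_gap = min_gap)
  group <- ifelse(names(sequences) %in% names(grp$low), "low_gc", "high_gc")
  names(group) <- names(sequences)

  # reference: highest GC, ties by smallest id
  cand <- names(gc)[gc == max(gc)]
  ref_id <- sort(cand)[1L]
  ref_seq <- sequences[[ref_id]]

  ids <- names(sequences)
  alns <- vector("list", length(ids)); names(alns) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (aligned) {
      aln <- list(query = sequences[[id]], reference = ref_seq)
    } else {
      aln <- pairwise_align(sequences[[id]], ref_seq)
    }
    alns[[id]] <- aln
    spec <- mutation_spectrum(aln$query, aln$reference)
    tr <- transition_rates(spec)
    call <- call_pseudogene(group[[id]], spec, max_other_rate, alpha)
    rows[[i]] <- data.frame(
      paralog_id = id, gc = gc[[id]], group = group[[id]],
      gA_rate = tr$gA_rate, cT_rate = tr$cT_rate, other_rate = tr$other_rate,
      call = call, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, reference = ref_id, alignments = alns,
                 threshold = grp$threshold),
            class = "paralog_classification")
}

#' @export
print.paralog_classification <- function(x, ...) {
  cat("paralog classification (reference: ", x$reference, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Find alignment windows that discriminate pseudogenes from functional genes
#'
#' Scans a labeled multiple alignment for primer-design windows: stretches
#' where all pseudogene sequences agree with one another and differ from
#' every functional sequence in at least `min_diffs` positions, optionally
#' requiring one of those differences in the three 3'-terminal positions
#' (primer specificity is dominated by the 3' end). Windows whose GC drops
#' below 0.25 carry a low-complexity warning: heavily RIPped targets can
#' force primers so AT-rich that amplification fails.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param labels named character vector over the same ids, values
#'   `"functional"` or `"pseudogene"`.
#' @param window window width in alignment columns (default 20).
#' @param min_diffs minimum fixed differences against every functional
#'   sequence (default 2).
#' @param require_3prime_diff logical; require a discriminating position in
#'   the last three window columns (default `TRUE`).
#' @return Data frame with one row per qualifying window: start, end
#'   (1-based alignment columns), sequence (pseudogene window sequence),
#'   min_diffs_vs_functional, gc, low_complexity.
#' @export
find_discriminating_sites <- function(alignment, labels, window = 20L,
                                      min_diffs = 2L,
                                      require_3prime_diff = TRUE) {
  ids <- names(alignment)
  if (!all(ids %in% names(labels)))
    stop("every sequence needs a label", call. = FALSE)
  labels <- labels[ids]
  if (!any(labels == "pseudogene") || !any(labels == "functional"))
    stop("need at least one sequence per label", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(mat) <- ids
  ncol_aln <- ncol(mat)
  if (ncol_aln < window) window <- ncol_aln
  pse <- mat[labels == "pseudogene", , drop = FALSE]
  fun <- mat[labels == "functional", , drop = FALSE]

  out <- list()
  for (s in seq_len(ncol_aln - window + 1L)) {
    cols <- s:(s + window - 1L)
    pw <- pse[, cols, drop = FALSE]
    # pseudogenes must agree and carry no gaps in the window
    if (any(pw == "-")) next
    if (nrow(pw) > 1L && !all(pw == rep(pw[1L, ], each = nrow(pw)))) next
    probe <- pw[1L, ]
    fw <- fun[, cols, drop = FALSE]
    diffs_per_fun <- apply(fw, 1L, function(f) sum(f != probe))
    if (min(diffs_per_fun) < min_diffs) next
    if (require_3prime_diff) {
      tail_cols <- (window - 2L):window
      tail_fixed <- vapply(tail_cols, function(j)
        all(fw[, j] != probe[j]), logical(1))
      if (!any(tail_fixed)) next
    }
    gcw <- sum(probe %in% c("G", "C")) / window
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = s + window - 1L,
      sequence = chars_to_seq(probe),
      min_diffs_vs_functional = min(diffs_per_fun),
      gc = gcw, low_complexity = gcw < 0.25,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0),
                      min_diffs_vs_functional = integer(0),
                      gc = numeric(0), low_complexity = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
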