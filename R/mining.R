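#' @name repeat-mining
#' @title Iterative homology mining of rDNA repeats
#' @description
#' Finds every rDNA repeat in an assembly by iterative query expansion: the
#' seed query recovers the least-diverged copies, the recovered copies are
#' used as queries in the next round, and the process repeats until no new
#' repeat is found - so heavily RIP-decayed copies below the seed's direct
#' detection range are still reached through intermediate copies. The
#' search engine is self-contained: exact k-mer seeding followed by local
#' affine-gap alignment of the candidate region.
NULL

.as_contigs <- function(assembly) {
  if (inherits(assembly, "synthetic_assembly")) return(assembly$contigs)
  if (inherits(assembly, "DNAStringSet")) {
    out <- as.character(assembly)
    names(out) <- names(assembly)
    return(out)
  }
  if (!is.character(assembly))
    stop("assembly must be a named character vector or DNAStringSet",
         call. = FALSE)
  assembly
}

# k-mer dictionary of a query, sampled every `stride` positions
.query_pdict <- function(query, k, stride) {
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  starts <- seq.int(1L, qlen - k + 1L, by = stride)
  kmers <- unique(substring(query, starts, starts + k - 1L))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(NULL)
  Biostrings::PDict(Biostrings::DNAStringSet(kmers))
}

# Seed positions of query k-mers in a contig, clustered into candidate
# regions; returns a matrix of (start, end) rows (1-based on the contig).
# Padded regions that overlap are merged so a decayed repeat whose
# surviving seeds are sparse still yields a single alignment job.
.candidate_regions <- function(pdict, qlen, contig, k,
                               cluster_gap = 2000L) {
  hits <- Biostrings::matchPDict(pdict, Biostrings::DNAString(contig))
  pos <- sort(unique(IRanges::start(unlist(hits))))
  if (length(pos) == 0L) return(NULL)
  breaks <- which(diff(pos) > cluster_gap)
  grp_start <- c(1L, breaks + 1L)
  grp_end <- c(breaks, length(pos))
  pad <- as.integer(round(0.15 * qlen)) + 200L
  reg <- cbind(
    start = pmax(1L, pos[grp_start] - pad),
    end = pmin(nchar(contig), pos[grp_end] + k - 1L + pad)
  )
  if (nrow(reg) > 1L) {           # merge overlapping padded regions
    keep <- list(reg[1L, ])
    for (i in 2L:nrow(reg)) {
      last <- keep[[length(keep)]]
      if (reg[i, "start"] <= last["end"]) {
        last["end"] <- max(last["end"], reg[i, "end"])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- reg[i, ]
    }
    reg <- do.call(rbind, keep)
  }
  reg
}

.overlap_len <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)

#' Iterative query-expansion search for rDNA repeats
#'
#' @param assembly named character vector of contig sequences (or a
#'   `DNAStringSet`, or a `synthetic_assembly`).
#' @param seed_query ungapped DNA string, length >= `min_hit_length`.
#' @param min_identity identity floor for accepting a hit (fraction of
#'   matching alignment columns; default 0.70, low enough to capture copies
#'   decayed by ~20% RIP with headroom).
#' @param min_hit_length minimum aligned span on the contig in bp (default
#'   200).
#' @param max_rounds maximum query-expansion rounds (default 10).
#' @param k,stride seeding k-mer length (default 12) and sampling stride
#'   along the query (default 8).
#' @param merge_gap hits within this many bp on the same contig and strand
#'   are merged before reporting; RIP-decayed regions can fragment one
#'   repeat into several local hits (default 100).
#' @return Data frame of hits: contig, start, end (1-based inclusive),
#'   strand, identity (best identity among the queries that found the
#'   region), round (discovery round).
#' @export
iterative_search <- function(assembly, seed_query,
                             min_identity = 0.70, min_hit_length = 200L,
                             max_rounds = 10L, k = 12L, stride = 8L,
                             merge_gap = 100L) {
  contigs <- .as_contigs(assembly)
  if (length(contigs) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), round = integer(0),
                      stringsAsFactors = FALSE))
  seed_query <- toupper(seed_query)
  if (nchar(seed_query) < min_hit_length)
    stop("seed query shorter than min_hit_length", call. = FALSE)

  hits <- data.frame(contig = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     identity = numeric(0), round = integer(0),
                     stringsAsFactors = FALSE)
  queries <- seed_query
  seen_queries <- character(0)

  for (round in seq_len(max_rounds)) {
    new_queries <- setdiff(unique(queries), seen_queries)
    if (length(new_queries) == 0L) break
    seen_queries <- c(seen_queries, new_queries)
    round_hits <- list()
    for (q in new_queries) {
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") q else revcomp(q)
        pd <- .query_pdict(qs, k, stride)
        if (is.null(pd)) next
        for (ci in seq_along(contigs)) {
          regions <- .candidate_regions(pd, nchar(qs), contigs[[ci]], k)
          if (is.null(regions)) next
          for (ri in seq_len(nrow(regions))) {
            rs <- regions[ri, "start"]; re <- regions[ri, "end"]
            # skip regions essentially covered by an accepted hit
            if (nrow(hits)) {
              same <- hits$contig == names(contigs)[ci]
              if (any(same)) {
                ov <- vapply(which(same), function(h)
                  .overlap_len(rs, re, hits$start[h], hits$end[h]),
                  numeric(1))
                span <- vapply(which(same), function(h)
                  min(re - rs + 1L, hits$end[h] - hits$start[h] + 1L),
                  numeric(1))
                if (any(ov / span > 0.9)) next
              }
            }
            region_seq <- substr(contigs[[ci]], rs, re)
            aln <- local_align(qs, region_seq)
            if (aln$ref_start == 0L) next
            span <- aln$ref_end - aln$ref_start + 1L
            ident <- alignment_identity(aln$query, aln$reference)
            if (span < min_hit_length || ident < min_identity) next
            round_hits[[length(round_hits) + 1L]] <- data.frame(
              contig = names(contigs)[ci],
              start = rs + aln$ref_start - 1L,
              end = rs + aln$ref_end - 1L,
              strand = strand, identity = ident, round = round,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(round_hits) == 0L) break
    candidate <- do.call(rbind, round_hits)
    combined <- .merge_hits(rbind(hits, candidate), merge_gap)
    added <- nrow(combined) > nrow(hits) ||
      sum(combined$end - combined$start) > sum(hits$end - hits$start)
    hits <- combined
    if (!added) break
    queries <- extract_hit_seqs(contigs, hits)
  }
  rownames(hits) <- NULL
  hits[order(hits$contig, hits$start), , drop = FALSE]
}

# merge intervals on the same contig+strand that overlap or lie within
# merge_gap; identity keeps the maximum, round the minimum
.merge_hits <- function(hits, merge_gap) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (grp in split(hits, paste(hits$contig, hits$strand))) {
    grp <- grp[order(grp$start), , drop = FALSE]
    cur <- grp[1L, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1L]) {
      if (grp$start[i] <= cur$end + merge_gap) {
        cur$end <- max(cur$end, grp$end[i])
        cur$identity <- max(cur$identity, grp$identity[i])
        cur$round <- min(cur$round, grp$round[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- grp[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strand-normalized sequences of repeat hits
#'
#' Slices hit intervals from their contigs; minus-strand hits are
#' reverse-complemented so that every returned sequence reads in the
#' orientation of the query.
#'
#' @param contigs named character vector of contig sequences.
#' @param hits hit data frame from [iterative_search()].
#' @return Character vector of hit sequences (named `contig:start-end(strand)`).
#' @export
extract_hit_seqs <- function(contigs, hits) {
  contigs <- .as_contigs(contigs)
  out <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- substr(contigs[[hits$contig[i]]], hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  names(out) <- sprintf("%s:%d-%d(%s)", hits$contig, hits$start, hits$end,
                        hits$strand)
  out
}

#' Annotate subunit boundaries within one repeat hit
#'
#' Locates each subunit of the reference unit in a strand-normalized hit
#' sequence by local alignment. A subunit is present when the alignment
#' covers at least `min_coverage` of the reference subunit (default 0.9 for
#' the coding subunits 18S/5.8S/28S, 0.5 for spacers, whose boundaries
#' erode faster). Intron-like insertions in 18S and 28S are excised via
#' [excise_introns()].
#'
#' @param hit_sequence strand-normalized DNA string.
#' @param template an `rdna_unit` reference.
#' @param min_coverage_coding,min_coverage_spacer presence thresholds.
#' @param min_insert minimum reference-gap run treated as an intron
#'   (default 50 bp; shorter runs are ordinary alignment gaps).
#' @param paralog_id identifier carried into the result.
#' @return Object of class `annotated_unit`: list with `paralog_id`,
#'   `sequence`, `subunits` (data frame: name, start, end, present,
#'   coverage, with 1-based coordinates on the hit sequence; NA coordinates
#'   when absent), `subunit_seqs` (named vector, introns removed),
#'   `introns_removed` (data frame: subunit, position, length), `complete`.
#'   Returns `NULL` (with a warning naming the reason) when no subunit can
#'   be located.
#' @export
annotate_subunits <- function(hit_sequence, template,
                              min_coverage_coding = 0.9,
                              min_coverage_spacer = 0.5,
                              min_insert = 50L,
                              paralog_id = "hit") {
  hit_sequence <- toupper(hit_sequence)
  subs <- template$subunits
  rows <- list()
  seqs <- character(0)
  introns <- list()
  for (i in seq_len(nrow(subs))) {
    name <- subs$name[i]
    ref_seq <- substr(template$sequence, subs$start[i], subs$end[i])
    aln <- local_align(ref_seq, hit_sequence)
    thr <- if (name %in% CODING_SUBUNITS) min_coverage_coding else
      min_coverage_spacer
    if (aln$ref_start == 0L) {
      rows[[i]] <- data.frame(name = name, start = NA_integer_,
                              end = NA_integer_, present = FALSE,
                              coverage = 0, stringsAsFactors = FALSE)
      next
    }
    coverage <- (aln$query_end - aln$query_start + 1L) / nchar(ref_seq)
    present <- coverage >= thr
    sub_seq <- NA_character_
    if (present) {
      # hit side (aln$reference) carries the insertions; the template
      # subunit (aln$query) is the intron-free reference
      ex <- excise_introns(aln$reference, aln$query,
                           min_insert = min_insert, on = "reference")
      if (nrow(ex$removed)) {
        ex$removed$subunit <- name
        introns[[length(introns) + 1L]] <- ex$removed
      }
      sub_seq <- gsub("-", "", ex$query, fixed = TRUE)
    }
    rows[[i]] <- data.frame(name = name,
                            start = if (present) aln$ref_start else NA_integer_,
                            end = if (present) aln$ref_end else NA_integer_,
                            present = present, coverage = coverage,
                            stringsAsFactors = FALSE)
    if (present) seqs[name] <- sub_seq
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$present)) {
    warning("hit '", paralog_id, "' discarded: no subunit locatable")
    return(NULL)
  }
  # ordering invariant among present subunits
  pres <- tab[tab$present, , drop = FALSE]
  if (is.unsorted(pres$start))
    warning("hit '", paralog_id, "': subunit order violated; ",
            "possible rearrangement")
  coding <- tab[tab$name %in% CODING_SUBUNITS, , drop = FALSE]
  complete <- all(tab$present) &&
    all(coding$coverage >= min_coverage_coding)
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(position = integer(0), length = integer(0),
               subunit = character(0), stringsAsFactors = FALSE)
  structure(list(paralog_id = paralog_id, sequence = hit_sequence,
                 subunits = tab, subunit_seqs = seqs,
                 introns_removed = introns[, c("subunit", "position",
                                               "length")],
                 complete = complete),
            class = "annotated_unit")
}

#' @export
print.annotated_unit <- function(x, ...) {
  cat("annotated unit '", x$paralog_id, "' (",
      if (x$complete) "complete" else "partial", ")\n", sep = "")
  print(x$subunits, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Excise intron-like insertions from an aligned pair
#'
#' Removes maximal runs of at least `min_insert` consecutive gap columns in
#' the reference (i.e. insertions in the query) from both rows of the
#' alignment; every other column is preserved in order. Runs shorter than
#' `min_insert` are ordinary alignment gaps and are kept.
#'
#' @param aligned_query,aligned_ref equal-length gapped strings; the query
#'   is the sequence suspected to carry insertions.
#' @param min_insert minimum run length in columns (default 50).
#' @param on which row's gaps define an insertion; `"reference"` (default)
#'   removes columns where the reference is gapped.
#' @return List with `query` and `reference` (cleaned gapped strings),
#'   `cleaned_target` (alias of the cleaned query row), and `removed`, a
#'   data frame of (position, length) giving 1-based positions of each
#'   excised insert on the ungapped cleaned query.
#' @export
excise_introns <- function(aligned_query, aligned_ref, min_insert = 50L,
                           on = c("reference", "query")) {
  on <- match.arg(on)
  q <- seq_to_chars(aligned_query)
  r <- seq_to_chars(aligned_ref)
  if (length(q) != length(r))
    stop("gapped sequences have unequal lengths", call. = FALSE)
  gap_row <- if (on == "reference") r else q
  is_gap <- gap_row == "-"
  rl <- rle(is_gap)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  drop <- logical(length(q))
  removed <- list()
  for (seg in which(rl$values & rl$lengths >= min_insert)) {
    cols <- starts[seg]:ends[seg]
    drop[cols] <- TRUE
    # position on the ungapped cleaned query: count query bases before the
    # run that survive
    before <- q[seq_len(starts[seg] - 1L)]
    keep_before <- before != "-" & !drop[seq_len(starts[seg] - 1L)]
    removed[[length(removed) + 1L]] <- data.frame(
      position = sum(keep_before) + 1L, length = rl$lengths[seg])
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(position = integer(0), length = integer(0))
  list(query = chars_to_seq(q[!drop]),
       reference = chars_to_seq(r[!drop]),
       cleaned_target = chars_to_seq(q[!drop]),
       removed = removed)
}

#' Mine and annotate all rDNA repeats of an assembly
#'
#' Convenience wrapper: [iterative_search()] seeded with the template unit,
#' strand-normalized extraction, and [annotate_subunits()] per hit; the
#' completeness flag of each hit is filled from its annotation.
#'
#' @inheritParams iterative_search
#' @param template an `rdna_unit`; its full sequence is the seed query.
#' @param ... passed on to [iterative_search()].
#' @return List with `hits` (data frame, completeness filled in) and
#'   `units` (list of `annotated_unit`, one per hit, names `paralog_#`).
#' @export
mine_repeats <- function(assembly, template, ...) {
  contigs <- .as_contigs(assembly)
  hits <- iterative_search(contigs, template$sequence, ...)
  seqs <- extract_hit_seqs(contigs, hits)
  units <- vector("list", nrow(hits))
  complete <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    id <- sprintf("paralog_%02d", i)
    units[[i]] <- annotate_subunits(seqs[[i]], template, paralog_id = id)
    complete[i] <- !is.null(units[[i]]) && units[[i]]$complete
  }
  names(units) <- sprintf("paralog_%02d", seq_len(nrow(hits)))
  hits$complete <- complete
  list(hits = hits, units = units[!vapply(units, is.null, logical(1))])
}
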