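#' @name synthetic-rdna
#' @title Synthetic rDNA assemblies with RIP-mutated paralogs
#'
#' @description
#' The simulator builds genome assemblies that contain a known set of 45S
#' rDNA paralogs: a tandem-unit template (18S-ITS1-5.8S-ITS2-28S-IGS) is
#' copied `n_paralogs` times, a chosen fraction of the copies is run through
#' a repeat-induced point mutation (RIP) process that introduces C-to-T and
#' G-to-A transitions with a dinucleotide-context bias, and the copies are
#' embedded in contigs with random flanking sequence, random strand, and a
#' controlled share of truncated (partial) repeats. Every mutation is logged
#' in a truth table so that downstream mining, classification and
#' RIP-profiling results can be scored exactly.
NULL

# -- seeded RNG isolation -----------------------------------------------------

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# -- unit template ------------------------------------------------------------

.default_subunit_lengths <- c(
  "18S" = 1800L, "ITS1" = 200L, "5.8S" = 160L,
  "ITS2" = 200L, "28S" = 3300L, "IGS" = 2000L
)
.default_subunit_gc <- c(
  "18S" = 0.48, "ITS1" = 0.50, "5.8S" = 0.48,
  "ITS2" = 0.50, "28S" = 0.48, "IGS" = 0.50
)

#' Generate a reference 45S rDNA unit template
#'
#' Builds one annotated 45S repeat unit with per-subunit target GC content.
#' The number of G/C positions per subunit is fixed at `round(length * gc)`,
#' so the realized GC fraction is always within one percentage point of the
#' target; base identities and positions are randomized from the seed.
#'
#' Defaults give a 7660 bp unit with coding subunits (18S, 5.8S, 28S) at GC
#' 0.48, inside the GC band observed for functional fungal rRNA genes
#' (roughly 46-53%).
#'
#' @param subunit_lengths named integer vector over
#'   `c("18S","ITS1","5.8S","ITS2","28S","IGS")`, lengths in bp.
#' @param subunit_gc named numeric vector of target GC fractions in (0, 1).
#' @param seed integer RNG seed.
#' @return An object of class `rdna_unit`: a list with `sequence` (the
#'   full-unit DNA string), `subunits` (data frame of name, start, end,
#'   length, gc_target, gc with 1-based inclusive coordinates), and `seed`.
#' @examples
#' unit <- generate_reference_unit(seed = 1)
#' unit$subunits
#' @export
generate_reference_unit <- function(subunit_lengths = .default_subunit_lengths,
                                    subunit_gc = .default_subunit_gc,
                                    seed = 1L) {
  nm <- SUBUNIT_ORDER[SUBUNIT_ORDER %in% names(subunit_lengths)]
  if (length(nm) == 0L) stop("no recognized subunit names", call. = FALSE)
  lens <- as.integer(subunit_lengths[nm])
  gcs <- as.numeric(subunit_gc[nm])
  if (anyNA(lens) || any(lens <= 0L))
    stop("subunit lengths must be positive integers", call. = FALSE)
  if (anyNA(gcs) || any(gcs <= 0 | gcs >= 1))
    stop("GC targets must lie in (0, 1)", call. = FALSE)

  with_seed(seed, {
    parts <- lapply(seq_along(nm), function(i) {
      len <- lens[i]
      n_gc <- round(len * gcs[i])
      x <- character(len)
      at_positions <- rep(TRUE, len)
      gc_idx <- sample.int(len, n_gc)
      at_positions[gc_idx] <- FALSE
      x[gc_idx] <- sample(c("G", "C"), n_gc, replace = TRUE)
      x[at_positions] <- sample(c("A", "T"), len - n_gc, replace = TRUE)
      chars_to_seq(x)
    })
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- unlist(parts)
    out <- list(
      sequence = paste(seqs, collapse = ""),
      subunits = data.frame(
        name = nm, start = starts, end = ends, length = lens,
        gc_target = gcs, gc = vapply(seqs, gc_content, numeric(1),
                                     USE.NAMES = FALSE),
        stringsAsFactors = FALSE
      ),
      seed = as.integer(seed)
    )
    class(out) <- "rdna_unit"
    out
  })
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat("45S rDNA unit template, ", nchar(x$sequence), " bp, GC ",
      sprintf("%.3f", gc_content(x$sequence)), "\n", sep = "")
  print(x$subunits, row.names = FALSE)
  invisible(x)
}

#' Extract one subunit sequence from a unit template
#'
#' @param unit an `rdna_unit`.
#' @param name subunit name, e.g. `"18S"`.
#' @return DNA string of that subunit.
#' @export
unit_subunit_seq <- function(unit, name) {
  i <- match(name, unit$subunits$name)
  if (is.na(i)) stop("unknown subunit: ", name, call. = FALSE)
  substr(unit$sequence, unit$subunits$start[i], unit$subunits$end[i])
}

# -- RIP parameters -----------------------------------------------------------

#' Parameters of the synthetic RIP process
#'
#' Context rates are per-eligible-site mutation probabilities for a C read
#' with its 3' neighbor (CpA, CpC, CpG, CpT); they are applied symmetrically
#' to G sites through the 5' neighbor on the reverse complement (TpG pairs
#' with CpA, GpG with CpC, CpG with CpG, ApG with CpT). Default rates encode
#' the strong CpA/TpG preference of fungal RIP and are calibrated so that a
#' pseudogenized copy loses roughly 15-25% of its aligned sites to G:C-to-A:T
#' transitions, the band observed for heavily RIPped rDNA repeats.
#'
#' @param n_paralogs number of rDNA copies to simulate (>= 2).
#' @param pseudogene_fraction fraction of copies passed through RIP; at least
#'   one copy is always kept functional.
#' @param context_rates named numeric vector over CpA/CpC/CpG/CpT in `[0,1]`.
#' @param background_rate per-site probability of a non-RIP substitution,
#'   spread uniformly over the alternative bases that do not produce C-to-T
#'   or G-to-A; default 0.001 mimics sequencing-error-level noise (<0.1%).
#' @param intron_rate probability that an 18S or 28S copy receives one
#'   intron-like insertion before mutation (pseudogene copies only, so
#'   functional copies stay identical).
#' @param intron_length insertion length in bp.
#' @param rounds number of RIP passes; in each pass contexts are read from
#'   the sequence entering that pass. Default 1 keeps every logged context
#'   exactly recoverable from the unmutated template.
#' @param seed integer RNG seed.
#' @return A list of class `rip_params`.
#' @export
rip_params <- function(n_paralogs = 10L,
                       pseudogene_fraction = 0.8,
                       context_rates = c(CpA = 0.60, CpC = 0.25,
                                         CpG = 0.25, CpT = 0.35),
                       background_rate = 0.001,
                       intron_rate = 0,
                       intron_length = 60L,
                       rounds = 1L,
                       seed = 1L) {
  if (n_paralogs < 2L) stop("n_paralogs must be >= 2", call. = FALSE)
  if (pseudogene_fraction < 0 || pseudogene_fraction > 1)
    stop("pseudogene_fraction must lie in [0, 1]", call. = FALSE)
  cr <- context_rates[RIP_CONTEXTS]
  names(cr) <- RIP_CONTEXTS
  if (anyNA(cr) || any(cr < 0 | cr > 1))
    stop("context_rates must name CpA/CpC/CpG/CpT with values in [0, 1]",
         call. = FALSE)
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_paralogs = as.integer(n_paralogs),
    pseudogene_fraction = pseudogene_fraction,
    context_rates = cr,
    background_rate = background_rate,
    intron_rate = intron_rate,
    intron_length = as.integer(intron_length),
    rounds = as.integer(rounds),
    seed = as.integer(seed)
  ), class = "rip_params")
}

# Context of a C at position i (3' neighbor) or a G at position i (5'
# neighbor, read on the reverse complement). NA when the neighbor is absent.
.rip_context <- function(chars, i) {
  n <- length(chars)
  base <- chars[i]
  if (base == "C") {
    if (i == n) return(NA_character_)
    paste0("Cp", chars[i + 1L])
  } else if (base == "G") {
    if (i == 1L) return(NA_character_)
    paste0("Cp", .complement[[chars[i - 1L]]])
  } else NA_character_
}

#' Apply repeat-induced point mutation to a sequence
#'
#' One pass flags every eligible C (has a 3' neighbor) and G (has a 5'
#' neighbor) with its dinucleotide context, then mutates each site to T or A
#' independently with the context's rate. Contexts are read from the
#' sequence entering the pass, never from already-mutated bases. Background
#' (non-RIP) substitutions are then added at `background_rate` on positions
#' not already mutated, choosing uniformly among the alternative bases that
#' do not produce a C-to-T or G-to-A change.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param params a [rip_params()] object.
#' @param seed integer RNG seed (defaults to `params$seed`).
#' @return A list with `sequence` (mutated string, same length) and `log`,
#'   a data frame with columns position, ref, alt, context (context is one
#'   of CpA/CpC/CpG/CpT for RIP transitions and "background" otherwise).
#' @examples
#' apply_rip("ACAACA", rip_params(context_rates = c(CpA = 1, CpC = 0,
#'                                                  CpG = 0, CpT = 0),
#'                                background_rate = 0))
#' @export
apply_rip <- function(sequence, params = rip_params(), seed = params$seed) {
  check_dna(sequence)
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  with_seed(seed, {
    pos <- integer(0); ref <- character(0); alt <- character(0)
    ctx <- character(0)
    for (round in seq_len(params$rounds)) {
      idx_c <- which(chars == "C"); idx_c <- idx_c[idx_c < n]
      idx_g <- which(chars == "G"); idx_g <- idx_g[idx_g > 1L]
      sites <- sort(c(idx_c, idx_g))
      if (length(sites) == 0L) break
      contexts <- vapply(sites, function(i) .rip_context(chars, i),
                         character(1))
      rates <- params$context_rates[contexts]
      hit <- runif(length(sites)) < rates
      hit_sites <- sites[hit]
      if (length(hit_sites)) {
        is_c <- chars[hit_sites] == "C"
        pos <- c(pos, hit_sites)
        ref <- c(ref, chars[hit_sites])
        alt <- c(alt, ifelse(is_c, "T", "A"))
        ctx <- c(ctx, contexts[hit])
        chars[hit_sites] <- ifelse(is_c, "T", "A")
      }
    }
    if (params$background_rate > 0) {
      cand <- setdiff(seq_len(n), pos)
      bg <- cand[runif(length(cand)) < params$background_rate]
      if (length(bg)) {
        alts <- vapply(chars[bg], function(b) {
          allowed <- switch(b,
            C = c("A", "G"),          # C>T reserved for RIP
            G = c("C", "T"),          # G>A reserved for RIP
            A = c("C", "G", "T"),
            T = c("A", "C", "G"))
          sample(allowed, 1L)
        }, character(1), USE.NAMES = FALSE)
        pos <- c(pos, bg)
        ref <- c(ref, chars[bg])
        alt <- c(alt, alts)
        ctx <- c(ctx, rep("background", length(bg)))
        chars[bg] <- alts
      }
    }
    o <- order(pos)
    list(
      sequence = chars_to_seq(chars),
      log = data.frame(position = pos[o], ref = ref[o], alt = alt[o],
                       context = ctx[o], stringsAsFactors = FALSE)
    )
  })
}

# -- assembly construction ----------------------------------------------------

.random_dna <- function(len, gc = 0.45) {
  if (len == 0L) return("")
  chars_to_seq(sample(DNA_BASES, len, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
}

# Insert intron-like segments into the 18S/28S portions of one unit copy.
# Returns the modified sequence plus an introns data frame.
.insert_introns <- function(sequence, unit, rate, len) {
  introns <- data.frame(subunit = character(0), position = integer(0),
                        length = integer(0), stringsAsFactors = FALSE)
  if (rate <= 0) return(list(sequence = sequence, introns = introns))
  offset <- 0L
  for (su in c("18S", "28S")) {
    i <- match(su, unit$subunits$name)
    if (is.na(i)) next
    if (runif(1) < rate) {
      # internal position within the subunit, away from the boundaries
      lo <- unit$subunits$start[i] + 20L
      hi <- unit$subunits$end[i] - 20L
      at <- sample(lo:hi, 1L) + offset
      ins <- .random_dna(len, gc = 0.40)
      sequence <- paste0(substr(sequence, 1L, at), ins,
                         substr(sequence, at + 1L, nchar(sequence)))
      introns <- rbind(introns, data.frame(
        subunit = su, position = at, length = len, stringsAsFactors = FALSE))
      offset <- offset + len
    }
  }
  list(sequence = sequence, introns = introns)
}

#' Build a synthetic assembly of rDNA paralogs with a truth table
#'
#' Copies the unit template `n_paralogs` times; `round(pseudogene_fraction *
#' n_paralogs)` copies (always leaving at least one functional) are passed
#' through [apply_rip()], the rest stay byte-identical to the template. A
#' `1 - complete_fraction` share of copies is truncated to a random
#' contiguous piece (35-75% of the unit, anchored at a random end). Each
#' copy is embedded in its own contig between random non-rDNA flanks and
#' placed on a random strand.
#'
#' @param template an `rdna_unit` from [generate_reference_unit()].
#' @param params a [rip_params()] object.
#' @param fragmentation list with `complete_fraction` (share of untruncated
#'   repeats, default 0.7) and `flank_lengths` (two integers, bp of flanking
#'   sequence, default 500 each).
#' @param seed integer RNG seed (defaults to `params$seed`).
#' @return A list of class `synthetic_assembly` with
#'   \describe{
#'     \item{contigs}{named character vector of contig sequences}
#'     \item{truth}{list: `paralogs` data frame (paralog_id, contig, start,
#'       end, strand, is_pseudogene, complete, unit_start, unit_end, n_rip,
#'       n_background), `mutations` data frame (paralog_id, position, ref,
#'       alt, context; positions are 1-based on the emitted plus-strand
#'       paralog sequence), `sequences` (named vector of emitted paralog
#'       sequences), and `introns`}
#'     \item{template, params, fragmentation}{the inputs, echoed}
#'   }
#'   Coordinates are 1-based inclusive; slicing `contigs[[contig]]` at
#'   `start:end` and reverse-complementing when strand is `-` reproduces
#'   `truth$sequences` exactly.
#' @export
build_synthetic_assembly <- function(template,
                                     params = rip_params(),
                                     fragmentation = list(
                                       complete_fraction = 0.7,
                                       flank_lengths = c(500L, 500L)),
                                     seed = params$seed) {
  stopifnot(inherits(template, "rdna_unit"))
  n <- params$n_paralogs
  n_pseudo <- round(params$pseudogene_fraction * n)
  if (n_pseudo >= n) {
    warning("pseudogene_fraction leaves no functional copy; keeping one")
    n_pseudo <- n - 1L
  }
  cf <- fragmentation$complete_fraction
  fl <- as.integer(fragmentation$flank_lengths)
  n_complete <- round(cf * n)

  with_seed(seed, {
    ids <- sprintf("paralog_%02d", seq_len(n))
    is_pseudo <- rep(FALSE, n)
    is_pseudo[sample.int(n, n_pseudo)] <- TRUE
    complete <- rep(FALSE, n)
    complete[sample.int(n, n_complete)] <- TRUE
    strand <- sample(c("+", "-"), n, replace = TRUE)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

    seqs <- character(n)
    unit_start <- rep(1L, n); unit_end <- rep(nchar(template$sequence), n)
    n_rip <- integer(n); n_bg <- integer(n)
    mut_list <- vector("list", n)
    intron_list <- vector("list", n)

    for (i in seq_len(n)) {
      s <- template$sequence
      introns <- NULL
      log <- data.frame(position = integer(0), ref = character(0),
                        alt = character(0), context = character(0),
                        stringsAsFactors = FALSE)
      if (is_pseudo[i]) {
        ins <- with_seed(sub_seeds[i] %% 1000003L + 1L,
                         .insert_introns(s, template, params$intron_rate,
                                         params$intron_length))
        s <- ins$sequence
        introns <- ins$introns
        mut <- apply_rip(s, params, seed = sub_seeds[i])
        s <- mut$sequence
        log <- mut$log
      }
      if (!complete[i]) {
        keep <- runif(1, 0.35, 0.75)
        klen <- max(200L, as.integer(round(keep * nchar(s))))
        from_start <- runif(1) < 0.5
        a <- if (from_start) 1L else nchar(s) - klen + 1L
        b <- a + klen - 1L
        s <- substr(s, a, b)
        unit_start[i] <- a; unit_end[i] <- b
        if (nrow(log)) {
          log <- log[log$position >= a & log$position <= b, , drop = FALSE]
          log$position <- log$position - a + 1L
        }
      }
      seqs[i] <- s
      n_rip[i] <- sum(log$context != "background")
      n_bg[i] <- sum(log$context == "background")
      if (nrow(log)) log$paralog_id <- ids[i]
      mut_list[[i]] <- log
      if (!is.null(introns) && nrow(introns)) {
        introns$paralog_id <- ids[i]
        intron_list[[i]] <- introns
      }
    }

    contig_ids <- sprintf("contig_%02d", seq_len(n))
    contigs <- character(n)
    start <- integer(n); end <- integer(n)
    for (i in seq_len(n)) {
      left <- .random_dna(fl[1])
      right <- .random_dna(fl[2])
      insert <- if (strand[i] == "+") seqs[i] else revcomp(seqs[i])
      contigs[i] <- paste0(left, insert, right)
      start[i] <- fl[1] + 1L
      end[i] <- fl[1] + nchar(insert)
    }
    names(contigs) <- contig_ids
    names(seqs) <- ids

    mutations <- do.call(rbind, mut_list[lengths(mut_list) > 0 &
                                           vapply(mut_list, nrow, 1L) > 0])
    if (is.null(mutations))
      mutations <- data.frame(position = integer(0), ref = character(0),
                              alt = character(0), context = character(0),
                              paralog_id = character(0),
                              stringsAsFactors = FALSE)
    mutations <- mutations[, c("paralog_id", "position", "ref", "alt",
                               "context")]
    rownames(mutations) <- NULL

    introns <- do.call(rbind, intron_list[lengths(intron_list) > 0])
    if (is.null(introns))
      introns <- data.frame(paralog_id = character(0), subunit = character(0),
                            position = integer(0), length = integer(0),
                            stringsAsFactors = FALSE)

    out <- list(
      contigs = contigs,
      truth = list(
        paralogs = data.frame(
          paralog_id = ids, contig = contig_ids, start = start, end = end,
          strand = strand, is_pseudogene = is_pseudo, complete = complete,
          unit_start = unit_start, unit_end = unit_end,
          n_rip = n_rip, n_background = n_bg, stringsAsFactors = FALSE),
        mutations = mutations,
        sequences = seqs,
        introns = introns
      ),
      template = template,
      params = params,
      fragmentation = list(complete_fraction = cf, flank_lengths = fl)
    )
    class(out) <- "synthetic_assembly"
    out
  })
}

#' @export
print.synthetic_assembly <- function(x, ...) {
  p <- x$truth$paralogs
  cat("synthetic assembly: ", length(x$contigs), " contigs, ",
      nrow(p), " rDNA paralogs (", sum(p$is_pseudogene), " pseudogene, ",
      sum(p$complete), " complete)\n", sep = "")
  invisible(x)
}

#' Write a synthetic assembly to disk
#'
#' Emits `contigs.fasta` (80-column wrapped), `truth_paralogs.tsv` and
#' `truth_mutations.tsv` (1-based inclusive coordinates, strand in {+,-}),
#' and `config.yaml` echoing the generator parameters.
#'
#' @param assembly a `synthetic_assembly`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_assembly <- function(assembly, dir) {
  stopifnot(inherits(assembly, "synthetic_assembly"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "contigs.fasta")
  dna <- Biostrings::DNAStringSet(assembly$contigs)
  Biostrings::writeXStringSet(dna, fa, width = 80L)
  tp <- file.path(dir, "truth_paralogs.tsv")
  write.table(assembly$truth$paralogs, tp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tm <- file.path(dir, "truth_mutations.tsv")
  write.table(assembly$truth$mutations, tm, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    n_paralogs = assembly$params$n_paralogs,
    pseudogene_fraction = assembly$params$pseudogene_fraction,
    context_rates = as.list(assembly$params$context_rates),
    background_rate = assembly$params$background_rate,
    intron_rate = assembly$params$intron_rate,
    intron_length = assembly$params$intron_length,
    rounds = assembly$params$rounds,
    seed = assembly$params$seed,
    complete_fraction = assembly$fragmentation$complete_fraction,
    flank_lengths = as.integer(assembly$fragmentation$flank_lengths)
  ), cfg)
  invisible(c(fa, tp, tm, cfg))
}
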