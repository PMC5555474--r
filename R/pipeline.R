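#' @name pipeline
#' @title End-to-end rDNA pseudogene analysis
#' @description
#' Orchestrates simulate -> mine -> classify -> RIP-profile -> (structure)
#' -> phylogeny from one seeded configuration, writing per-stage TSVs, a
#' Newick tree per subunit, and a summary table (per-subunit average
#' p-distance, G-to-A and C-to-T rates, RIP rate, pseudogene counts, clade
#' separation). In synthetic mode the report also scores the pseudogene
#' calls against the simulator's truth table.
NULL

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Build a reference unit from a FASTA and a coordinate table
#'
#' @param fasta single-record FASTA of the full 45S unit.
#' @param coords TSV with columns name, start, end (1-based inclusive).
#' @return An `rdna_unit`.
#' @export
unit_from_files <- function(fasta, coords) {
  seqs <- read_fasta(fasta)
  if (length(seqs) != 1L)
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  tab <- read.table(coords, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(tab)))
  sequence <- seqs[[1]]
  tab$length <- tab$end - tab$start + 1L
  tab$gc <- vapply(seq_len(nrow(tab)), function(i)
    gc_content(substr(sequence, tab$start[i], tab$end[i])), numeric(1))
  tab$gc_target <- tab$gc
  out <- list(sequence = sequence,
              subunits = tab[, c("name", "start", "end", "length",
                                 "gc_target", "gc")],
              seed = NA_integer_)
  class(out) <- "rdna_unit"
  out
}

#' Pipeline configuration
#'
#' Every parameter has a default; the full configuration is echoed into
#' the output directory so a run can be reproduced from its report alone.
#'
#' @param mode `"synthetic"` (simulate the assembly) or `"assembly"`
#'   (mine a supplied FASTA against a supplied reference unit).
#' @param seed master RNG seed for the whole run.
#' @param outdir output directory (`NULL` for no file output).
#' @param assembly_fasta,unit_fasta,unit_coords input paths (assembly
#'   mode).
#' @param pre_aligned optional named list of per-subunit aligned FASTA
#'   paths; when given, mining is skipped and classification, RIP
#'   profiling and phylogeny run directly on the supplied alignments.
#' @param unit_params,rip,fragmentation synthetic-mode parameter blocks
#'   (see [generate_reference_unit()], [rip_params()],
#'   [build_synthetic_assembly()]).
#' @param mining list of [iterative_search()] parameters.
#' @param classify list: min_gap, max_other_rate.
#' @param phylo list: model, n_replicates, deletion (`"auto"` picks
#'   complete deletion when all sequences are full-length, pairwise
#'   otherwise).
#' @param pairing_table optional path to a pairing table for the 18S
#'   structure stage.
#' @param subunits which subunits to analyse (default the three coding
#'   genes).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "assembly"),
                            seed = 1L,
                            outdir = NULL,
                            assembly_fasta = NULL,
                            unit_fasta = NULL,
                            unit_coords = NULL,
                            pre_aligned = NULL,
                            unit_params = list(),
                            rip = list(),
                            fragmentation = list(complete_fraction = 0.7,
                                                 flank_lengths = c(500L,
                                                                   500L)),
                            mining = list(),
                            classify = list(min_gap = 0.02,
                                            max_other_rate = 0.001),
                            phylo = list(model = "k2p",
                                         n_replicates = 100L,
                                         deletion = "auto"),
                            pairing_table = NULL,
                            subunits = CODING_SUBUNITS) {
  structure(list(mode = match.arg(mode), seed = as.integer(seed),
                 outdir = outdir, assembly_fasta = assembly_fasta,
                 unit_fasta = unit_fasta, unit_coords = unit_coords,
                 pre_aligned = pre_aligned, unit_params = unit_params,
                 rip = rip, fragmentation = fragmentation, mining = mining,
                 classify = classify, phylo = phylo,
                 pairing_table = pairing_table, subunits = subunits),
            class = "pipeline_config")
}

.write_tsv <- function(x, dir, file) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_report`: per-subunit results
#'   (classification, rip profiles, tree with supports, clade purity),
#'   `summary` data frame, and in synthetic mode `truth_eval` (confusion
#'   matrix, sensitivity, specificity). Stage outputs are written under
#'   `config$outdir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  mined <- NULL
  subunit_sets <- list()   # per subunit: named ungapped seqs (or alignments)
  pre_aligned_mode <- !is.null(config$pre_aligned)

  if (pre_aligned_mode) {
    for (su in names(config$pre_aligned))
      subunit_sets[[su]] <- read_fasta(config$pre_aligned[[su]])
    template <- NULL
  } else if (config$mode == "synthetic") {
    unit_args <- config$unit_params
    unit_args$seed <- config$seed
    template <- do.call(generate_reference_unit, unit_args)
    rip_args <- config$rip
    rip_args$seed <- config$seed
    params <- do.call(rip_params, rip_args)
    assembly <- build_synthetic_assembly(template, params,
                                         fragmentation = config$fragmentation,
                                         seed = config$seed)
    truth <- assembly$truth
    if (!is.null(outdir)) write_assembly(assembly, file.path(outdir,
                                                             "simulated"))
    mined <- do.call(mine_repeats,
                     c(list(assembly$contigs, template), config$mining))
    .write_tsv(.hits_tsv(mined$hits), outdir, "hits.tsv")
    subunit_sets <- .collect_subunits(mined$units, config$subunits)
  } else {
    if (is.null(config$assembly_fasta) || is.null(config$unit_fasta) ||
        is.null(config$unit_coords))
      stop("assembly mode requires assembly_fasta, unit_fasta, unit_coords",
           call. = FALSE)
    template <- unit_from_files(config$unit_fasta, config$unit_coords)
    contigs <- read_fasta(config$assembly_fasta)
    mined <- do.call(mine_repeats,
                     c(list(contigs, template), config$mining))
    .write_tsv(.hits_tsv(mined$hits), outdir, "hits.tsv")
    subunit_sets <- .collect_subunits(mined$units, config$subunits)
  }

  results <- list()
  summary_rows <- list()
  for (su in names(subunit_sets)) {
    seqs <- subunit_sets[[su]]
    if (length(seqs) < 2L) next
    cls <- classify_paralogs(seqs,
                             min_gap = config$classify$min_gap,
                             max_other_rate = config$classify$max_other_rate,
                             aligned = pre_aligned_mode)
    ref_id <- cls$reference
    # reference-anchored alignment for RIP track, distances and trees
    if (pre_aligned_mode) {
      msa <- seqs
    } else {
      ungapped_ref <- gsub("-", "", seqs[[ref_id]], fixed = TRUE)
      msa <- anchor_msa(seqs[setdiff(names(seqs), ref_id)], ungapped_ref,
                        ref_name = ref_id)
    }
    profiles <- lapply(setdiff(names(msa), ref_id), function(id)
      compute_rip_profile(msa[[id]], msa[[ref_id]]))
    names(profiles) <- setdiff(names(msa), ref_id)
    prof_tab <- data.frame(
      paralog_id = names(profiles),
      rip_rate = vapply(profiles, `[[`, numeric(1), "rip_rate"),
      dominance = vapply(profiles, `[[`, numeric(1), "dominance"),
      preference = vapply(profiles, `[[`, numeric(1), "preference"),
      stringsAsFactors = FALSE)
    .write_tsv(cls$table, outdir, paste0("classification_", su, ".tsv"))
    .write_tsv(prof_tab, outdir, paste0("rip_profile_", su, ".tsv"))
    .write_tsv(windowed_rip(msa, consensus_id = ref_id),
               outdir, paste0("rip_track_", su, ".tsv"))

    # phylogeny
    deletion <- config$phylo$deletion
    if (identical(deletion, "auto")) {
      lens <- nchar(gsub("-", "", msa, fixed = TRUE))
      deletion <- if (length(unique(lens)) == 1L) "complete" else "pairwise"
    }
    tree_res <- NULL; purity <- NULL
    if (length(msa) >= 3L) {
      tree_res <- tryCatch(
        bootstrap_support(msa, model = config$phylo$model,
                          n_replicates = config$phylo$n_replicates,
                          seed = config$seed, deletion = deletion),
        error = function(e) {
          warning("phylo stage skipped for ", su, ": ", conditionMessage(e))
          NULL
        })
      if (!is.null(tree_res)) {
        calls <- setNames(cls$table$call, cls$table$paralog_id)
        labels <- ifelse(calls == "pseudogene", "pseudogene", "functional")
        names(labels) <- names(calls)
        purity <- clade_purity(tree_res$tree, labels)
        if (!is.null(outdir))
          ape::write.tree(tree_res$tree,
                          file.path(outdir, paste0("nj_", su, ".nwk")))
      }
    }

    avg_p <- average_p_distance(msa, deletion = deletion)
    tab <- cls$table
    low <- tab[tab$group == "low_gc", , drop = FALSE]
    summary_rows[[su]] <- data.frame(
      subunit = su,
      n_paralogs = length(seqs),
      n_pseudogene_calls = sum(tab$call == "pseudogene"),
      avg_p_distance = avg_p,
      avg_gA_rate = if (nrow(low)) mean(low$gA_rate) else 0,
      avg_cT_rate = if (nrow(low)) mean(low$cT_rate) else 0,
      avg_rip_rate = if (nrow(low))
        mean(prof_tab$rip_rate[prof_tab$paralog_id %in% low$paralog_id])
        else 0,
      separating = if (!is.null(purity))
        purity$is_bipartition_separating else NA,
      stringsAsFactors = FALSE)
    results[[su]] <- list(classification = cls, profiles = profiles,
                          msa = msa, tree = tree_res, purity = purity,
                          deletion = deletion)
  }

  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  .write_tsv(summary, outdir, "summary.tsv")

  truth_eval <- NULL
  if (!is.null(truth) && length(results)) {
    truth_eval <- .score_against_truth(results, truth, mined$hits)
    if (!is.null(outdir))
      .write_tsv(truth_eval$table, outdir, "truth_confusion.tsv")
  }

  if (!is.null(outdir)) {
    cfg <- config
    cfg$outdir <- NULL
    yaml::write_yaml(.config_as_list(cfg), file.path(outdir, "config.yaml"))
  }
  structure(list(results = results, summary = summary,
                 hits = if (!is.null(mined)) mined$hits else NULL,
                 truth_eval = truth_eval, config = config),
            class = "pipeline_report")
}

.config_as_list <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) lapply(x, as.vector)
         else as.vector(x))
}

.hits_tsv <- function(hits) {
  hits[, intersect(c("contig", "start", "end", "strand", "identity",
                     "complete", "round"), names(hits)), drop = FALSE]
}

# per-subunit named sequence sets from a list of annotated units
.collect_subunits <- function(units, subunits) {
  sets <- list()
  for (su in subunits) {
    seqs <- character(0)
    for (u in units) {
      if (su %in% names(u$subunit_seqs) && !is.na(u$subunit_seqs[[su]]))
        seqs[u$paralog_id] <- u$subunit_seqs[[su]]
    }
    if (length(seqs)) sets[[su]] <- seqs
  }
  sets
}

# Confusion matrix of pseudogene calls against the simulator truth table.
# A mined paralog (hit row) is matched to the truth repeat whose contig
# interval it overlaps by at least half; calls are pooled over subunits (a
# repeat is called pseudogene when any of its subunits is).
.score_against_truth <- function(results, truth, hits) {
  call_by_id <- list()
  for (res in results) {
    tab <- res$classification$table
    for (i in seq_len(nrow(tab)))
      call_by_id[[tab$paralog_id[i]]] <-
        c(call_by_id[[tab$paralog_id[i]]], tab$call[i])
  }
  tp <- fp <- tn <- fn <- 0L
  rows <- list()
  for (id in names(call_by_id)) {
    calls <- call_by_id[[id]]
    called_pseudo <- any(calls == "pseudogene")
    hit_idx <- as.integer(sub("^paralog_", "", id))
    if (is.na(hit_idx) || hit_idx > nrow(hits)) next
    h <- hits[hit_idx, ]
    tpars <- truth$paralogs
    ov <- vapply(seq_len(nrow(tpars)), function(k) {
      if (tpars$contig[k] != h$contig) return(0)
      .overlap_len(h$start, h$end, tpars$start[k], tpars$end[k]) /
        min(h$end - h$start + 1L, tpars$end[k] - tpars$start[k] + 1L)
    }, numeric(1))
    k <- which.max(ov)
    if (ov[k] < 0.5) next
    is_pseudo <- tpars$is_pseudogene[k]
    if (called_pseudo && is_pseudo) tp <- tp + 1L
    else if (called_pseudo && !is_pseudo) fp <- fp + 1L
    else if (!called_pseudo && is_pseudo) fn <- fn + 1L
    else tn <- tn + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      paralog_id = id, truth_id = tpars$paralog_id[k], truth = is_pseudo,
      called = called_pseudo, stringsAsFactors = FALSE)
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(table = do.call(rbind, rows),
       tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("rDNA pseudogene pipeline report\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$truth_eval))
    cat(sprintf("truth: sensitivity %.3f, specificity %.3f (TP %d FP %d TN %d FN %d)\n",
                x$truth_eval$sensitivity, x$truth_eval$specificity,
                x$truth_eval$tp, x$truth_eval$fp, x$truth_eval$tn,
                x$truth_eval$fn))
  invisible(x)
}
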