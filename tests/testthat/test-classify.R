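test_that("GC content counts only unambiguous bases", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AATT"), 0.0)
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("GC--NN"), 1.0)
  expect_error(gc_content("---"), "no unambiguous")
})

test_that("GC groups split at the largest gap, or not at all", {
  # the two non-overlapping bands reported for fungal rDNA paralogs:
  # functional 46.45-52.55%, pseudogenic 12.26-44.43%; paralog GC values
  # fill the bands densely, so the band gap is the largest gap
  fun_vals <- c(46.45, 47.80, 49.10, 50.40, 51.60, 52.55)
  pse_vals <- seq(12.26, 44.43, length.out = 24)
  vals <- setNames(c(fun_vals, pse_vals),
                   c(paste0("f", seq_along(fun_vals)),
                     paste0("p", seq_along(pse_vals))))
  g <- split_gc_groups(vals, min_gap = 2.0)
  expect_setequal(names(g$high), paste0("f", seq_along(fun_vals)))
  expect_setequal(names(g$low), paste0("p", seq_along(pse_vals)))
  expect_gt(g$threshold, 44.43)
  expect_lt(g$threshold, 46.45)

  # unimodal: everything stays in the high group
  g2 <- split_gc_groups(c(48.0, 47.5, 47.9), min_gap = 2.0)
  expect_equal(length(g2$high), 3)
  expect_equal(length(g2$low), 0)
  expect_true(is.na(g2$threshold))

  g3 <- split_gc_groups(c(a = 50.0, b = 30.0))
  expect_equal(names(g3$high), "a")
  expect_equal(names(g3$low), "b")
  expect_equal(g3$gap, 20.0)
})

test_that("mutation spectra count directed classes and indels", {
  s <- mutation_spectrum("ATGT", "ACGT")
  expect_equal(s$counts[["C>T"]], 1)
  expect_equal(sum(s$counts), 1)
  expect_equal(s$aligned_sites, 4)

  s2 <- mutation_spectrum("ACGT", "ACGT")
  expect_equal(sum(s2$counts), 0)

  s3 <- mutation_spectrum("AC-TG", "ACGTG")
  expect_equal(s3$indel_columns, 1)
  expect_equal(s3$aligned_sites, 4)

  expect_error(mutation_spectrum("ACG", "ACGT"), "unequal")
})

test_that("a RIP-simulated spectrum equals the simulator log by class", {
  u <- small_unit()
  out <- apply_rip(u$sequence, rip_params(background_rate = 0, seed = 3))
  s <- mutation_spectrum(out$sequence, u$sequence)
  expect_equal(s$counts[["C>T"]], sum(out$log$ref == "C"))
  expect_equal(s$counts[["G>A"]], sum(out$log$ref == "G"))
  expect_equal(sum(s$counts) - s$counts[["C>T"]] - s$counts[["G>A"]], 0)

  # with background on, every logged class matches the spectrum
  out2 <- apply_rip(u$sequence, rip_params(background_rate = 0.01,
                                           seed = 4))
  s2 <- mutation_spectrum(out2$sequence, u$sequence)
  log_classes <- table(paste0(out2$log$ref, ">", out2$log$alt))
  for (cl in names(log_classes))
    expect_equal(s2$counts[[cl]], as.integer(log_classes[[cl]]), info = cl)
})

test_that("transition rates use aligned sites as denominator", {
  ref <- paste0("GGG", "CC", strrep("A", 95))
  qry <- paste0("AAA", "TT", strrep("A", 95))
  s <- mutation_spectrum(qry, ref)
  tr <- transition_rates(s)
  expect_equal(tr$gA_rate, 0.03)
  expect_equal(tr$cT_rate, 0.02)
  expect_equal(tr$other_rate, 0.0)

  s0 <- mutation_spectrum("ACGT", "ACGT")
  tr0 <- transition_rates(s0)
  expect_equal(unlist(tr0), c(gA_rate = 0, cT_rate = 0, other_rate = 0))
})

test_that("pseudogene calls follow the GC-group and noise rules", {
  # low GC, strong RIP signal, negligible other mutations -> pseudogene
  n <- 2000
  ref <- strsplit(random_dna(n, seed = 50), "")[[1]]
  qry <- ref
  cg <- which(ref %in% c("C", "G"))
  hit <- cg[seq(1, length(cg), by = 3)]
  qry[hit] <- ifelse(ref[hit] == "C", "T", "A")
  s <- mutation_spectrum(paste(qry, collapse = ""),
                         paste(ref, collapse = ""))
  expect_equal(call_pseudogene("low_gc", s), "pseudogene")
  expect_equal(call_pseudogene("high_gc", s), "functional")

  # low GC but 5% non-RIP divergence -> undetermined
  qry2 <- ref
  at <- which(ref == "A")[1:100]
  qry2[at] <- "C"
  s2 <- mutation_spectrum(paste(qry2, collapse = ""),
                          paste(ref, collapse = ""))
  expect_equal(call_pseudogene("low_gc", s2), "undetermined")

  # no transitions at all cannot be called a pseudogene
  s3 <- mutation_spectrum("AAAA", "AAAA")
  expect_equal(call_pseudogene("low_gc", s3), "undetermined")
  expect_error(call_pseudogene(NA, s3), "group")
})

test_that("noise-level other mutations do not demote a pseudogene call", {
  # other mutations at the error-like rate (0.1%) are consistent with
  # noise; a hard cutoff (alpha = 1) at the same rate is recovered
  n <- 2000
  ref <- strsplit(random_dna(n, seed = 51), "")[[1]]
  qry <- ref
  cg <- which(ref %in% c("C", "G"))
  hit <- cg[seq(1, length(cg), by = 4)]
  qry[hit] <- ifelse(ref[hit] == "C", "T", "A")
  at <- which(ref == "A" & qry == "A")[1:4]  # 4 background-like changes
  qry[at] <- "G"
  s <- mutation_spectrum(paste(qry, collapse = ""),
                         paste(ref, collapse = ""))
  expect_equal(call_pseudogene("low_gc", s), "pseudogene")
  expect_equal(call_pseudogene("low_gc", s, alpha = 1), "undetermined")
})

test_that("classification separates simulated copies with unoverlapped GC", {
  u <- small_unit()
  seqs <- c(f1 = u$sequence, f2 = u$sequence)
  for (i in 1:6)
    seqs[paste0("p", i)] <- apply_rip(u$sequence,
                                      rip_params(seed = 100 + i))$sequence
  # classify on the 18S subunit
  sub <- vapply(seqs, function(s)
    substr(s, u$subunits$start[1], u$subunits$end[1]), character(1))
  cls <- classify_paralogs(sub, aligned = TRUE)
  tab <- cls$table
  expect_true(cls$reference %in% c("f1", "f2"))
  expect_setequal(tab$paralog_id[tab$call == "functional"], c("f1", "f2"))
  expect_setequal(tab$paralog_id[tab$call == "pseudogene"],
                  paste0("p", 1:6))
  # the unoverlapped-GC property: every pseudogene below every functional
  expect_lt(max(tab$gc[tab$call == "pseudogene"]),
            min(tab$gc[tab$call == "functional"]))
  # denominator consistency: class rates sum to total count / sites
  for (id in tab$paralog_id) {
    aln <- cls$alignments[[id]]
    s <- mutation_spectrum(aln$query, aln$reference)
    tr <- transition_rates(s)
    expect_equal(tr$gA_rate + tr$cT_rate + tr$other_rate,
                 sum(s$counts) / s$aligned_sites, tolerance = 1e-12)
    expect_lte(tr$gA_rate + tr$cT_rate + tr$other_rate, 1)
  }
})

test_that("discriminating windows separate the classes, or come back empty", {
  fun <- c(f1 = "ACGACGACGACGACGACGACACGACG",
           f2 = "ACGACGACGACGACGACGACACGACG")
  pse <- c(p1 = "ATGATGATAATGATGATAACATGATG",
           p2 = "ATGATGATAATGATGATAACATGATG")
  labels <- c(f1 = "functional", f2 = "functional",
              p1 = "pseudogene", p2 = "pseudogene")
  w <- find_discriminating_sites(c(fun, pse), labels, window = 20,
                                 min_diffs = 2)
  expect_gt(nrow(w), 0)
  expect_true(all(w$min_diffs_vs_functional >= 2))

  # identical sets -> nothing discriminates
  same <- c(f1 = fun[[1]], p1 = fun[[1]])
  w0 <- find_discriminating_sites(same,
                                  c(f1 = "functional", p1 = "pseudogene"))
  expect_equal(nrow(w0), 0)
  expect_error(find_discriminating_sites(fun, labels[1:2]), "label")
})

test_that("windows from RIP-simulated data separate truth classes cleanly", {
  u <- small_unit()
  sub18 <- unit_subunit_seq(u, "18S")
  aln <- c(f1 = sub18, f2 = sub18)
  for (i in 1:3)
    aln[paste0("p", i)] <- apply_rip(sub18,
                                     uniform_rip(0.2, seed = 60 + i))$sequence
  labels <- setNames(c("functional", "functional", rep("pseudogene", 3)),
                     names(aln))
  w <- find_discriminating_sites(aln, labels, window = 20, min_diffs = 2)
  # pseudogene copies mutate independently, so fully conserved pseudogene
  # windows are rare but any reported one must separate the classes
  if (nrow(w) > 0) {
    for (k in seq_len(nrow(w))) {
      probe <- substr(aln[["p1"]], w$start[k], w$end[k])
      for (p in c("p2", "p3"))
        expect_identical(substr(aln[[p]], w$start[k], w$end[k]), probe)
      for (f in c("f1", "f2"))
        expect_false(identical(substr(aln[[f]], w$start[k], w$end[k]),
                               probe))
    }
  }
  # an AT-rich primer window carries the low-complexity warning
  fun2 <- c(f1 = strrep("GCGCGCGCGCAT", 2), f2 = strrep("GCGCGCGCGCAT", 2))
  pse2 <- c(p1 = strrep("ATATATATATAT", 2), p2 = strrep("ATATATATATAT", 2))
  w2 <- find_discriminating_sites(
    c(fun2, pse2), c(f1 = "functional", f2 = "functional",
                     p1 = "pseudogene", p2 = "pseudogene"),
    window = 20, min_diffs = 2)
  expect_true(all(w2$low_complexity))
})
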