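test_that("a verbatim embedded seed is found once with identity 1", {
  set.seed(21)
  core <- random_dna(500)
  contig <- c(c1 = paste0(random_dna(200), core, random_dna(150)))
  hits <- iterative_search(contig, core, min_hit_length = 300)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$contig, "c1")
  expect_equal(hits$start, 201)
  expect_equal(hits$end, 700)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1.0)
})

test_that("empty assemblies and short seeds are handled", {
  expect_equal(nrow(iterative_search(character(0), random_dna(300, 1))), 0)
  expect_error(iterative_search(c(c1 = random_dna(1000, 2)),
                                random_dna(50, 3)),
               "min_hit_length")
})

test_that("minus-strand repeats are found and strand-normalized", {
  set.seed(22)
  core <- random_dna(500)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core)))
  contig <- c(c1 = paste0(random_dna(100), rc, random_dna(100)))
  hits <- iterative_search(contig, core, min_hit_length = 300)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  seqs <- extract_hit_seqs(contig, hits)
  expect_identical(unname(seqs[1]), core)
})

test_that("mining a synthetic assembly recovers the truth repeat set", {
  u <- small_unit()
  p <- rip_params(n_paralogs = 8, pseudogene_fraction = 0.75, seed = 31)
  asm <- build_synthetic_assembly(
    u, p, fragmentation = list(complete_fraction = 0.75,
                               flank_lengths = c(150L, 150L)), seed = 31)
  hits <- iterative_search(asm$contigs, u$sequence)
  tr <- asm$truth$paralogs
  expect_equal(nrow(hits), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    h <- hits[hits$contig == tr$contig[i], ]
    expect_equal(nrow(h), 1)
    ov <- min(h$end, tr$end[i]) - max(h$start, tr$start[i]) + 1
    expect_gte(ov / (tr$end[i] - tr$start[i] + 1), 0.9)
    expect_equal(h$strand, tr$strand[i])
  }
})

test_that("noise-free copies are extracted exactly and search is idempotent", {
  u <- small_unit()
  p <- rip_params(n_paralogs = 5, pseudogene_fraction = 0, seed = 8)
  asm <- build_synthetic_assembly(
    u, p, fragmentation = list(complete_fraction = 1,
                               flank_lengths = c(100L, 100L)), seed = 8)
  hits <- iterative_search(asm$contigs, u$sequence)
  seqs <- extract_hit_seqs(asm$contigs, hits)
  expect_equal(nrow(hits), 5)
  expect_true(all(unname(seqs) == u$sequence))
  # seeding the search with its own output adds nothing
  hits2 <- iterative_search(asm$contigs, seqs[[1]])
  expect_equal(hits2[, c("contig", "start", "end", "strand")],
               hits[, c("contig", "start", "end", "strand")])
})

test_that("lowering min_identity never shrinks the hit set", {
  u <- small_unit()
  p <- rip_params(n_paralogs = 6, pseudogene_fraction = 0.8, seed = 41)
  asm <- build_synthetic_assembly(u, p, seed = 41)
  strict <- iterative_search(asm$contigs, u$sequence, min_identity = 0.9,
                             max_rounds = 1)
  loose <- iterative_search(asm$contigs, u$sequence, min_identity = 0.7,
                            max_rounds = 1)
  expect_gte(nrow(loose), nrow(strict))
})

test_that("a deeply decayed copy is reached only through an intermediate", {
  # homology chain: q1 is within direct reach of the seed, q2 only within
  # reach of q1; multi-round search must recover q2, single-round must not
  set.seed(77)
  q0 <- random_dna(800)
  q1 <- apply_rip(q0, uniform_rip(0.35, seed = 101))$sequence
  q2 <- apply_rip(q1, uniform_rip(0.55, seed = 102))$sequence
  id01 <- alignment_identity(q0, q1)
  id12 <- alignment_identity(q1, q2)
  id02 <- alignment_identity(q0, q2)
  min_id <- 0.78
  expect_gt(id01, min_id)
  expect_gt(id12, min_id)
  expect_lt(id02, min_id - 0.04)

  contigs <- c(cA = paste0(random_dna(150), q1, random_dna(150)),
               cB = paste0(random_dna(150), q2, random_dna(150)))
  multi <- iterative_search(contigs, q0, min_identity = min_id,
                            min_hit_length = 600, max_rounds = 5)
  expect_setequal(multi$contig, c("cA", "cB"))
  single <- iterative_search(contigs, q0, min_identity = min_id,
                             min_hit_length = 600, max_rounds = 1)
  expect_equal(single$contig, "cA")
})

test_that("subunits of an exact copy annotate at reference coordinates", {
  u <- small_unit()
  ann <- annotate_subunits(u$sequence, u)
  expect_true(ann$complete)
  expect_true(all(ann$subunits$present))
  expect_equal(ann$subunits$start, u$subunits$start)
  expect_equal(ann$subunits$end, u$subunits$end)
  for (su in u$subunits$name)
    expect_identical(ann$subunit_seqs[[su]], unit_subunit_seq(u, su))
})

test_that("a 3-prime half unit lacks 18S and is flagged partial", {
  u <- small_unit()
  half_start <- u$subunits$start[u$subunits$name == "ITS2"]
  half <- substr(u$sequence, half_start, nchar(u$sequence))
  ann <- annotate_subunits(half, u)
  tab <- ann$subunits
  expect_false(tab$present[tab$name == "18S"])
  expect_true(tab$present[tab$name == "28S"])
  expect_false(ann$complete)
})

test_that("RIP-decayed paralogs still annotate near truth boundaries", {
  u <- small_unit()
  mut <- apply_rip(u$sequence, uniform_rip(0.25, seed = 9))$sequence
  ann <- annotate_subunits(mut, u)
  expect_true(all(ann$subunits$present))
  expect_true(all(abs(ann$subunits$start - u$subunits$start) <= 10))
  expect_true(all(abs(ann$subunits$end - u$subunits$end) <= 10))
})

test_that("intron-like insertions are excised during annotation", {
  u <- small_unit()
  p <- rip_params(n_paralogs = 2, pseudogene_fraction = 0.5,
                  intron_rate = 1, intron_length = 80L,
                  background_rate = 0,
                  context_rates = c(CpA = 0.1, CpC = 0.1, CpG = 0.1,
                                    CpT = 0.1), seed = 19)
  asm <- build_synthetic_assembly(
    u, p, fragmentation = list(complete_fraction = 1,
                               flank_lengths = c(50L, 50L)), seed = 19)
  tr <- asm$truth
  pseudo_id <- tr$paralogs$paralog_id[tr$paralogs$is_pseudogene]
  expect_equal(nrow(tr$introns), 2)  # one per coding subunit at rate 1
  ann <- annotate_subunits(tr$sequences[[pseudo_id]], u)
  expect_equal(sort(ann$introns_removed$subunit), c("18S", "28S"))
  expect_true(all(ann$introns_removed$length >= 70))
  # intron-free subunit sequences come back at reference length +/- ends
  expect_lt(abs(nchar(ann$subunit_seqs[["18S"]]) -
                  u$subunits$length[u$subunits$name == "18S"]), 12)
})

test_that("excise_introns removes only long reference-gap runs", {
  # no reference gaps: unchanged
  r <- excise_introns("ACGTACGT", "ACGTACGT", min_insert = 5)
  expect_equal(r$query, "ACGTACGT")
  expect_equal(nrow(r$removed), 0)

  # one 60-column insert against the reference
  q <- paste0(strrep("A", 20), strrep("G", 60), strrep("T", 20))
  rf <- paste0(strrep("A", 20), strrep("-", 60), strrep("T", 20))
  r <- excise_introns(q, rf, min_insert = 50)
  expect_equal(nchar(r$query), nchar(q) - 60)
  expect_equal(r$removed$length, 60)
  expect_equal(r$removed$position, 21)

  # two 40-column runs stay below the threshold
  q2 <- paste0(strrep("A", 10), strrep("G", 40), strrep("C", 10),
               strrep("G", 40), strrep("T", 10))
  rf2 <- paste0(strrep("A", 10), strrep("-", 40), strrep("C", 10),
                strrep("-", 40), strrep("T", 10))
  r2 <- excise_introns(q2, rf2, min_insert = 50)
  expect_equal(r2$query, q2)
  expect_equal(nrow(r2$removed), 0)

  expect_error(excise_introns("ACG", "ACGT"), "unequal")
})
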