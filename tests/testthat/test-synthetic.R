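test_that("simulation is byte-identical under one seed", {
  cfg <- sim_cluster_config(seed = 91, scaffold_len = 5e4, cluster_start = 5e3,
                            spacing = 1e4, n_decoys = 4)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$manifest, s2$manifest)
  # a different seed changes the background
  cfg2 <- sim_cluster_config(seed = 92, scaffold_len = 5e4, cluster_start = 5e3,
                             spacing = 1e4, n_decoys = 4)
  expect_false(identical(simulate_genome(cfg2)$genome$seq, s1$genome$seq))
})

test_that("zero-divergence implants embed the exact back-translated consensus", {
  aln <- synthetic_reference_alignment(seed = 42)
  cfg <- sim_config(
    seed = 93, scaffold_len = 2e4,
    implants = tibble::tibble(group = "HOX5", scaffold = "scaffold_1",
                              nt_start = 7000L, strand = "+",
                              aa_divergence = 0),
    reference_alignment = aln
  )
  sim <- simulate_genome(cfg)
  prof <- build_profile(aln, group = "HOX5", q = pooled_background(aln))
  expected_nt <- back_translate(consensus_window(prof))
  expect_equal(substr(sim$genome$seq, 7001, 7000 + nchar(expected_nt)),
               expected_nt)
  expect_equal(sim$manifest$nt_start[1], 7000L)
  expect_equal(sim$manifest$aa_divergence_realized[1], 0)
})

test_that("minus-strand implants carry the reverse complement", {
  aln <- synthetic_reference_alignment(seed = 42)
  cfg <- sim_config(
    seed = 94, scaffold_len = 2e4,
    implants = tibble::tibble(group = "HOX1", scaffold = "scaffold_1",
                              nt_start = 5000L, strand = "-",
                              aa_divergence = 0),
    reference_alignment = aln
  )
  sim <- simulate_genome(cfg)
  prof <- build_profile(aln, group = "HOX1", q = pooled_background(aln))
  expected <- revcomp(back_translate(consensus_window(prof)))
  expect_equal(substr(sim$genome$seq, 5001, 5180), expected)
})

test_that("mutate_protein has binomial substitution statistics", {
  aa <- random_aa(60, seed = 95)
  expect_equal(mutate_protein(aa, 0, seed = 1), aa)
  full <- mutate_protein(aa, 1, seed = 2)
  expect_equal(sum(strsplit(full, "")[[1]] != strsplit(aa, "")[[1]]), 60)
  # rate 0.2, length 60: mean distance 12, se of the mean over n reps
  dists <- vapply(1:200, function(s) {
    m <- mutate_protein(aa, 0.2, seed = 1000 + s)
    sum(strsplit(m, "")[[1]] != strsplit(aa, "")[[1]])
  }, numeric(1))
  se <- sqrt(60 * 0.2 * 0.8) / sqrt(200)
  expect_lt(abs(mean(dists) - 12), 3 * se)
})

test_that("realized implant divergence matches the binomial expectation", {
  aln <- synthetic_reference_alignment(seed = 42)
  dists <- vapply(1:200, function(s) {
    cfg <- sim_config(
      seed = 2000 + s, scaffold_len = 1000,
      implants = tibble::tibble(group = "HOX4", scaffold = "scaffold_1",
                                nt_start = 100L, strand = "+",
                                aa_divergence = 0.1),
      reference_alignment = aln
    )
    simulate_genome(cfg)$manifest$aa_divergence_realized[1] * 60
  }, numeric(1))
  se <- sqrt(60 * 0.1 * 0.9) / sqrt(200)
  expect_lt(abs(mean(dists) - 6), 3 * se)
})

test_that("truth features and manifest are mutually consistent", {
  mir <- synthetic_mirnas(seed = 96, n = 2)
  cfg <- sim_config(
    seed = 97, scaffold_len = 6e4,
    implants = tibble::tibble(group = c("HOX1", "HOX4"),
                              scaffold = "scaffold_1",
                              nt_start = c(10000L, 30000L),
                              strand = c("+", "-"), aa_divergence = 0.05),
    n_decoys = 6, mirna_implants = tibble::tibble(
      mirna_id = mir$id, scaffold = "scaffold_1",
      position = c(15000L, 45000L), strand = c("+", "-"),
      n_mismatches = c(0L, 2L)
    ),
    mirnas = mir
  )
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), nrow(sim$manifest))
  merged <- dplyr::inner_join(sim$truth, sim$manifest, by = "feature_id")
  expect_equal(merged$start, merged$nt_start)
  expect_equal(merged$end, merged$nt_end)
  expect_equal(merged$strand.x, merged$strand.y)
  expect_equal(sum(sim$truth$kind == "mirna"), 2L)

  # a written sim round-trips through the standard formats
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  genome_back <- read_fasta(file.path(dir, "genome.fasta"), "nt")
  expect_equal(genome_back$seq, sim$genome$seq)
  truth_back <- read_gff3(file.path(dir, "truth.gff3"), quiet = TRUE)
  expect_equal(truth_back$start, sim$truth$start)
  expect_equal(truth_back$kind, sim$truth$kind)
})

test_that("implanted miRNAs carry exactly the configured mismatches", {
  mir <- synthetic_mirnas(seed = 98, n = 1)
  cfg <- sim_config(
    seed = 99, scaffold_len = 5000,
    mirna_implants = tibble::tibble(mirna_id = mir$id, scaffold = "scaffold_1",
                                    position = 1000L, strand = "+",
                                    n_mismatches = 2L),
    mirnas = mir
  )
  sim <- simulate_genome(cfg)
  planted <- substr(sim$genome$seq, 1001, 1022)
  d <- sum(strsplit(planted, "")[[1]] != strsplit(mir$seq[1], "")[[1]])
  expect_equal(d, 2L)
})

test_that("overlapping implant placements are rejected with the collision", {
  aln <- synthetic_reference_alignment(seed = 42)
  cfg <- sim_config(
    seed = 100, scaffold_len = 2e4,
    implants = tibble::tibble(group = c("HOX1", "HOX2"),
                              scaffold = "scaffold_1",
                              nt_start = c(5000L, 5100L), strand = "+",
                              aa_divergence = 0),
    reference_alignment = aln
  )
  expect_error(simulate_genome(cfg), "collision.*\\[5100,5280\\)")
  expect_error(sim_config(seed = 1, implants = tibble::tibble(
    group = "HOX1", scaffold = "scaffold_9", nt_start = 0L, strand = "+",
    aa_divergence = 0
  )), "unknown scaffold")
})

test_that("intron-bearing implants have canonical splice ends", {
  aln <- synthetic_reference_alignment(seed = 42)
  cfg <- sim_config(
    seed = 101, scaffold_len = 2e4,
    implants = tibble::tibble(group = "HOX3", scaffold = "scaffold_1",
                              nt_start = 4000L, strand = "+",
                              aa_divergence = 0, intron_offset_aa = 30L,
                              intron_len = 300L),
    reference_alignment = aln
  )
  sim <- simulate_genome(cfg)
  expect_equal(sim$manifest$nt_end[1] - sim$manifest$nt_start[1], 480L)
  intron <- substr(sim$genome$seq, 4001 + 90, 4000 + 90 + 300)
  expect_equal(substr(intron, 1, 2), "GT")
  expect_equal(substr(intron, 299, 300), "AG")
  # T-free interior: no stop codon can arise on the implant strand
  expect_false(grepl("T", substr(intron, 3, 298)))
})

test_that("the synthetic reference alignment is labelled, ungapped, rectangular", {
  aln <- synthetic_reference_alignment(seed = 7, n_per_group = 4)
  expect_setequal(unique(aln$group), hox_groups())
  expect_equal(nrow(aln), 36)
  expect_true(all(nchar(aln$aa_row) == 60))
  expect_false(any(grepl("-", aln$aa_row)))
  # deterministic
  expect_identical(aln, synthetic_reference_alignment(seed = 7, n_per_group = 4))
})
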