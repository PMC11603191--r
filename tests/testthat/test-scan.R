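make_frame <- function(aa_seq, frame_id = "+1", scaffold = "s1",
                       seq_len = 3L * nchar(aa_seq) + 2L) {
  list(scaffold = scaffold, frame_id = frame_id,
       strand = substr(frame_id, 1, 1), aa_seq = aa_seq, seq_len = seq_len)
}

test_that("a planted consensus window is found at the forced coordinates", {
  prof <- std_profiles[["HOX4"]]
  cons <- consensus_window(prof)
  aa <- paste0(strrep("X", 10), cons, strrep("X", 10))
  frame <- make_frame(aa, "+1", seq_len = 3L * nchar(aa))
  hits <- scan_frame(std_profiles, frame, threshold_E = 1e-5, m = 1000)
  hox4 <- hits[hits$group == "HOX4", ]
  expect_equal(nrow(hox4), 1)
  expect_equal(hox4$aa_start, 11L)
  expect_equal(hox4$nt_start, frame_nt_window("+1", 11L, prof$L, frame$seq_len)$nt_start)
  expect_equal(hox4$window, cons)
})

test_that("all-stop frames and empty frames yield no hits", {
  frame <- make_frame(strrep("*", 100))
  expect_equal(nrow(scan_frame(std_profiles, frame, m = 100)), 0)
  expect_equal(nrow(scan_frame(std_profiles, make_frame(""), m = 100)), 0)
})

test_that("profiles with differing window lengths are rejected", {
  short <- build_profile(tiny_alignment("ACDEF"), q = uniform_q)
  mixed <- c(std_profiles["HOX1"], list(short = short))
  expect_error(scan_frame(mixed, make_frame(strrep("A", 80)), m = 10),
               "differing window lengths")
})

test_that("a vacuous E-value threshold accepts every stop-free window", {
  prof <- std_profiles["HOX1"]
  aa <- random_aa(80, seed = 5)
  hits <- scan_frame(prof, make_frame(aa), threshold_E = Inf, m = 100)
  expect_equal(nrow(hits), 80 - prof[[1]]$L + 1)
})

test_that("merge_hits merges by interval hull within max_gap", {
  h <- function(start, end, group = "HOX1", score = 30, strand = "+") {
    tibble::tibble(scaffold = "s1", frame_id = "+1", aa_start = 1L,
                   nt_start = as.integer(start), nt_end = as.integer(end),
                   strand = strand, group = group, score = score,
                   evalue = 1e-9, window = "W")
  }
  # overlapping hits: dominance of the best score
  m1 <- merge_hits(dplyr::bind_rows(h(100, 280, score = 30),
                                    h(150, 330, score = 28)))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$score, 30)
  expect_equal(c(m1$nt_start, m1$nt_end), c(100L, 330L))

  # 50 kb apart with a 5 kb gap: two loci
  m2 <- merge_hits(dplyr::bind_rows(h(100, 280), h(50100, 50280)),
                   max_gap = 5000)
  expect_equal(nrow(m2), 2)

  # within max_gap: single hull [100, 480)
  m3 <- merge_hits(dplyr::bind_rows(h(100, 280), h(300, 480)), max_gap = 5000)
  expect_equal(nrow(m3), 1)
  expect_equal(c(m3$nt_start, m3$nt_end), c(100L, 480L))

  # opposite strands never merge
  m4 <- merge_hits(dplyr::bind_rows(h(100, 280), h(300, 480, strand = "-")),
                   max_gap = 5000)
  expect_equal(nrow(m4), 2)

  # margin: two groups at one locus
  m5 <- merge_hits(dplyr::bind_rows(h(100, 280, "HOX1", 30),
                                    h(100, 280, "HOX4", 22)))
  expect_equal(m5$best_group, "HOX1")
  expect_equal(m5$margin, 8)
  expect_equal(nrow(m5), 1)
})

test_that("implants at zero divergence are recovered at exact coordinates", {
  cfg <- sim_cluster_config(seed = 21, divergence = 0, scaffold_len = 1e5,
                            cluster_start = 1e4, spacing = 2e4, n_decoys = 3)
  sim <- simulate_genome(cfg)
  loci <- assign_group(scan_genome(std_profiles, sim$genome, rounds = 1))
  truth <- dplyr::filter(sim$manifest, type == "hox")
  expect_equal(nrow(loci), nrow(truth))
  expect_equal(loci$nt_start, truth$nt_start)
  expect_equal(loci$nt_end, truth$nt_end)
  expect_equal(loci$strand, truth$strand)
  expect_equal(loci$best_group, truth$group)
  expect_true(all(loci$status == "assigned"))
})

test_that("reported loci re-translate to a window scoring exactly the report", {
  cfg <- sim_cluster_config(seed = 22, divergence = 0.1, scaffold_len = 1e5,
                            cluster_start = 1e4, spacing = 2e4, n_decoys = 0)
  sim <- simulate_genome(cfg)
  loci <- scan_genome(std_profiles, sim$genome, rounds = 1)
  expect_gt(nrow(loci), 0)
  for (i in seq_len(nrow(loci))) {
    sub <- substr(sim$genome$seq[sim$genome$id == loci$scaffold[i]],
                  loci$nt_start[i] + 1, loci$nt_end[i])
    if (loci$strand[i] == "-") sub <- revcomp(sub)
    fr <- six_frame_translate(sub)
    aa <- fr$aa_seq[fr$frame_id == "+1"]  # the oriented locus's own frame
    prof <- std_profiles[[loci$best_group[i]]]
    expect_equal(max(score_windows(prof, aa)), loci$score[i], tolerance = 1e-9)
  }
})

test_that("scanning the reverse-complemented genome mirrors loci and strands", {
  cfg <- sim_cluster_config(seed = 23, divergence = 0, scaffold_len = 5e4,
                            groups = c("HOX1", "HOX9-13"), cluster_start = 8e3,
                            spacing = 2e4, n_decoys = 0)
  sim <- simulate_genome(cfg)
  g <- sim$genome
  g_rc <- dplyr::mutate(g, seq = revcomp(seq))
  len <- nchar(g$seq)
  fwd <- scan_genome(std_profiles, g, rounds = 1)
  rev <- scan_genome(std_profiles, g_rc, rounds = 1)
  expect_equal(nrow(fwd), nrow(rev))
  fwd <- dplyr::arrange(fwd, nt_start)
  rev_mirror <- rev |>
    dplyr::mutate(new_start = len - nt_end, new_end = len - nt_start,
                  new_strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::arrange(new_start)
  expect_equal(rev_mirror$new_start, fwd$nt_start)
  expect_equal(rev_mirror$new_end, fwd$nt_end)
  expect_equal(rev_mirror$new_strand, fwd$strand)
  expect_equal(rev_mirror$best_group, fwd$best_group)
  expect_equal(rev_mirror$score, fwd$score)
})

test_that("a second round on an implant-free genome changes nothing", {
  genome <- tibble::tibble(id = "null1", desc = "",
                           seq = random_dna(3e4, seed = 31))
  r1 <- scan_genome(std_profiles, genome, rounds = 1)
  r2 <- scan_genome(std_profiles, genome, rounds = 2)
  expect_equal(r1, r2)
  expect_equal(nrow(r1), 0)
  # empty genome is empty output, not an error
  expect_equal(nrow(scan_genome(std_profiles, genome[0, ])), 0)
})

test_that("an intron-split homeodomain is bridged into one locus by merging", {
  aln <- synthetic_reference_alignment(seed = 42)
  cfg <- sim_config(
    seed = 33, scaffold_len = 3e4,
    implants = tibble::tibble(group = "HOX4", scaffold = "scaffold_1",
                              nt_start = 12000L, strand = "+",
                              aa_divergence = 0,
                              intron_offset_aa = 30L, intron_len = 900L),
    reference_alignment = aln
  )
  sim <- simulate_genome(cfg)
  # each exon-side window aligns only half the profile columns, so detection
  # of split loci needs a permissive threshold; the merge gap must bridge
  # the 900 nt intron into a single locus spanning the whole gene
  loci <- scan_genome(std_profiles, sim$genome, threshold_E = 1e-2,
                      rounds = 1, max_gap = 5000)
  hox4 <- loci[loci$best_group == "HOX4", ]
  expect_equal(nrow(hox4), 1)
  expect_equal(hox4$nt_start, 12000L)
  expect_equal(hox4$nt_end, 12000L + 180L + 900L)
})

test_that("proteome scanning reports aa-space loci", {
  prof <- std_profiles[["HOX3"]]
  cons <- consensus_window(prof)
  prot <- tibble::tibble(
    id = c("p1", "p2"),
    desc = "",
    seq = c(paste0(strrep("X", 20), cons),
            paste0(cons, strrep("G", 70), cons))
  )
  loci <- scan_proteome(std_profiles, prot)
  expect_true(all(loci$coord_space == "aa"))
  expect_true(all(loci$strand == "+"))
  p1 <- loci[loci$scaffold == "p1", ]
  expect_equal(c(p1$nt_start, p1$nt_end), c(20L, 20L + prof$L))
  expect_equal(nrow(loci[loci$scaffold == "p2", ]), 2)
  expect_equal(nrow(scan_proteome(std_profiles, prot[0, ])), 0)
  expect_error(scan_proteome(std_profiles,
                             tibble::tibble(id = "x", seq = "ACGTACGT")),
               "nucleotides")
})

test_that("null hit counts are consistent with the E-value budget", {
  # 20 seeded null genomes of 100 kb at threshold 1e-5: the expected number
  # of accepted windows is 9 profiles x 1e-5 per genome, so about 2e-3 hits
  # in total; observing more than 1 would reject the calibration
  total <- 0L
  for (s in 1:20) {
    genome <- tibble::tibble(id = "null", desc = "",
                             seq = random_dna(1e5, seed = 4000 + s))
    total <- total + nrow(scan_genome(std_profiles, genome, rounds = 1))
  }
  expect_lte(total, 1)
})
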