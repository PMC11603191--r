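test_that("cluster detection applies the size and span thresholds", {
  loci <- make_loci("s1", c(0, 10000, 20000, 30000),
                    c("HOX1", "HOX3", "HOX4", "HOX6-8_ftz"))
  cl <- detect_clusters(loci)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$span, 30180L)
  expect_equal(cl$n_genes, 4L)

  # three loci never form a cluster at min_genes = 4
  expect_equal(nrow(detect_clusters(loci[1:3, ])), 0)

  # span boundary is inclusive
  tight <- make_loci("s1", c(0, 1e5, 2e5, 300000 - 180), "HOX1")
  expect_equal(detect_clusters(tight)$span, 300000L)
  over <- make_loci("s1", c(0, 1e5, 2e5, 300001 - 180), "HOX1")
  expect_equal(nrow(detect_clusters(over)), 0)

  # ambiguous loci are excluded unless requested
  loci$status[2] <- "ambiguous"
  expect_equal(nrow(detect_clusters(loci)), 0)
  expect_equal(nrow(detect_clusters(loci, include_ambiguous = TRUE)), 1)
})

test_that("window selection maximises members then minimises span", {
  # five loci spanning 250 kb; a sixth would push the hull past 300 kb
  loci <- make_loci("s1", c(0, 6e4, 1.2e5, 1.8e5, 249820, 310000),
                    c("HOX1", "HOX2", "HOX3", "HOX4", "HOX5", "HOX9-13"))
  cl <- detect_clusters(loci)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 5L)
  expect_equal(cl$start, 0L)
})

test_that("cluster detection agrees with the exhaustive-window oracle", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      loci <- make_loci("s1", sort(sample.int(6e5, n)),
                        sample(hox_groups(), n, replace = TRUE))
      got <- detect_clusters(loci)
      want <- oracle_clusters(loci)
      expect_equal(nrow(got), length(want))
      if (length(want) > 0) {
        want_ids <- lapply(want, function(w) sort(w$locus_id))
        got_ids <- lapply(got$members, function(m) sort(m$locus_id))
        expect_setequal(got_ids, want_ids)
      }
    }
  })
})

test_that("collinearity counts concordant and discordant pairs", {
  tau_of <- function(groups) {
    collinearity(make_loci("s1", seq(0, by = 1e4, length.out = length(groups)),
                           groups))
  }
  canonical <- tau_of(c("HOX1", "HOX3", "HOX4", "HOX6-8_ftz"))
  expect_equal(canonical$tau, 1)
  expect_equal(canonical$discordant, 0L)

  reversed <- tau_of(c("HOX6-8_ftz", "HOX4", "HOX3", "HOX1"))
  expect_equal(reversed$tau, -1)
  expect_equal(reversed$tau_rev, 1)

  # (HOX4, HOX1, HOX3, HOX9-13): C = 4, D = 2 -> tau = 1/3
  mixed <- tau_of(c("HOX4", "HOX1", "HOX3", "HOX9-13"))
  expect_equal(mixed$concordant, 4L)
  expect_equal(mixed$discordant, 2L)
  expect_equal(mixed$tau, 1 / 3)

  # equal ranks only: undefined
  same <- tau_of(c("HOX6-8_ftz", "HOX6-8_Antp", "HOX6-8_UbxAbdA"))
  expect_true(is.na(same$tau))
})

test_that("collinearity matches exhaustive pair enumeration on random orders", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      groups <- sample(hox_groups(), sample(2:8, 1), replace = TRUE)
      got <- collinearity(make_loci("s1", seq(0, by = 1e4,
                                              length.out = length(groups)),
                                    groups))
      ranks <- hox_rank(groups)
      C <- 0L; D <- 0L
      for (i in seq_along(ranks)) for (j in seq_along(ranks)) {
        if (i < j && ranks[i] != ranks[j]) {
          if (ranks[j] > ranks[i]) C <- C + 1L else D <- D + 1L
        }
      }
      if (C + D == 0) {
        expect_true(is.na(got$tau))
      } else {
        expect_equal(got$tau, (C - D) / (C + D))
        expect_equal(got$discordant, D)
      }
    }
  })
})

test_that("loci span is the per-scaffold hull regardless of clustering", {
  one <- loci_span(make_loci("s1", 100, "HOX1"))
  expect_equal(one$span, 180L)
  # loosely connected pair 4 Mb apart
  pair <- loci_span(make_loci("chrIII", c(0, 4e6), "HOX1", len = 200L))
  expect_equal(pair$span, 4000200L)
  withr::with_seed(47, {
    loci <- make_loci(sample(c("s1", "s2"), 12, replace = TRUE),
                      sample.int(1e6, 12), "HOX1")
    got <- loci_span(loci)
    for (sc in unique(loci$scaffold)) {
      sub <- loci[loci$scaffold == sc, ]
      expect_equal(got$span[got$scaffold == sc],
                   max(sub$nt_end) - min(sub$nt_start))
    }
  })
})

test_that("orientation profile reports modal strand, consistency and flips", {
  all_plus <- orientation_profile(make_loci("s1", c(0, 1e4, 2e4), "HOX1"))
  expect_equal(all_plus$modal_strand, "+")
  expect_equal(all_plus$consistency, 1)
  expect_equal(length(all_plus$flipped), 0)

  tie <- orientation_profile(make_loci("s1", seq(0, by = 1e4, length.out = 6),
                                       "HOX1",
                                       strand = c("+", "+", "+", "-", "-", "-")))
  expect_equal(tie$modal_strand, "+")
  expect_equal(tie$consistency, 0.5)

  # T. suis-style mixed-orientation cluster of six members
  mixed <- make_loci("cont064", seq(0, by = 1.5e4, length.out = 6),
                     c("HOX1", "HOX3", "HOX4", "HOX6-8_ftz", "HOX6-8_Antp",
                       "HOX9-13"),
                     strand = c("+", "-", "+", "+", "-", "+"))
  ori <- orientation_profile(mixed)
  expect_equal(ori$modal_strand, "+")
  expect_equal(ori$consistency, 4 / 6)
  expect_setequal(ori$flipped, mixed$locus_id[c(2, 5)])
})

test_that("cluster calls are invariant under translation and strand flip", {
  loci <- make_loci("s1", c(5000, 20000, 47000, 90000),
                    c("HOX1", "HOX4", "HOX3", "HOX9-13"),
                    strand = c("+", "+", "-", "+"))
  base <- detect_clusters(loci)
  shifted <- dplyr::mutate(loci, nt_start = nt_start + 12345L,
                           nt_end = nt_end + 12345L)
  expect_equal(detect_clusters(shifted)$n_genes, base$n_genes)
  expect_equal(detect_clusters(shifted)$span, base$span)
  expect_equal(detect_clusters(shifted)$tau, base$tau)

  # flip the whole scaffold: order reverses, strands invert
  scaf_len <- 2e5
  flipped <- loci |>
    dplyr::mutate(s = scaf_len - nt_end, e = scaf_len - nt_start,
                  nt_start = s, nt_end = e,
                  strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::select(-s, -e)
  fl <- detect_clusters(flipped)
  expect_equal(fl$n_genes, base$n_genes)
  expect_equal(fl$span, base$span)
  expect_equal(fl$tau, -base$tau)
  expect_equal(fl$orientation_consistency, base$orientation_consistency)
})

test_that("cluster span never exceeds the scaffold loci span", {
  withr::with_seed(53, {
    for (rep in 1:10) {
      n <- sample(4:10, 1)
      loci <- make_loci("s1", sort(sample.int(5e5, n)),
                        sample(hox_groups(), n, replace = TRUE))
      cl <- detect_clusters(loci)
      if (nrow(cl) > 0) {
        expect_true(all(cl$span <= loci_span(loci)$span))
      }
    }
  })
})

test_that("the architecture table merges spans and interruption counts", {
  loci <- make_loci("s1", c(0, 1e4, 2e4, 3e4),
                    c("HOX1", "HOX3", "HOX4", "HOX9-13"))
  cl <- detect_clusters(loci)
  annot <- tibble::tibble(feature_id = c("g1", "g2"), scaffold = "s1",
                          start = c(5000L, 50000L), end = c(5600L, 50600L),
                          strand = "+", kind = "gene")
  ints <- count_non_hox_all(cl, annot, hox_ids = character())
  tbl <- cluster_table(cl, loci, species = "test_sp", interruptions = ints)
  expect_equal(tbl$n_non_hox, 1L)
  expect_equal(tbl$loci_span_nt, 30180L)
  expect_equal(tbl$cluster_span_nt, 30180L)
  expect_equal(tbl$taxon, "test_sp")
  tf <- withr::local_tempfile(fileext = ".bed")
  write_cluster_bed(cl, tf)
  bed <- readr::read_tsv(tf, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bed), 4)
  expect_equal(bed$X2, loci$nt_start)
})
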