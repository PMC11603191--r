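#' Scan one translated frame for homeodomain window hits
#'
#' Scores every window position of the frame against every profile and
#' reports those whose E-value (computed over `m` scanned windows) passes
#' `threshold_E`. Windows containing a stop are never reported. Nucleotide
#' coordinates are mapped back to the forward strand of the source scaffold.
#'
#' @param profiles Named list of calibrated `hox_profile` objects sharing a
#'   common window length.
#' @param frame One row of [six_frame_translate()] output (a one-row tibble
#'   or a list with `scaffold`, `frame_id`, `strand`, `aa_seq`, `seq_len`).
#' @param threshold_E E-value cutoff (default `1e-5`).
#' @param m Total number of windows in the search space (genome-wide across
#'   frames when scanning a genome; defaults to this frame's window count).
#' @return Tibble of window hits: `scaffold`, `frame_id`, `aa_start` (1-based
#'   index in the frame), `nt_start`, `nt_end` (0-based half-open, forward
#'   strand), `strand`, `group`, `score`, `evalue`, `window` (the residues).
#' @export
scan_frame <- function(profiles, frame, threshold_E = 1e-5, m = NULL) {
  Ls <- vapply(profiles, function(p) p$L, integer(1))
  if (length(unique(Ls)) != 1) abort("scan_frame: profiles have differing window lengths")
  L <- Ls[[1]]
  frame <- as.list(frame)
  aa <- frame$aa_seq
  n_win <- max(0L, nchar(aa) - L + 1L)
  if (is.null(m)) m <- n_win
  if (m < 1) abort("scan_frame: m must be >= 1")
  if (n_win == 0) return(empty_hits())
  code <- aa_encode_str(aa)
  hits <- purrr::imap(profiles, function(prof, g) {
    cutoff <- score_cutoff(prof, threshold_E, m)
    scores <- score_windows_cutoff_cpp(code, prof$M, cutoff)
    keep <- which(is.finite(scores) & scores >= cutoff)
    if (length(keep) == 0) return(NULL)
    ev <- profile_evalue(prof, scores[keep], m)
    coords <- frame_nt_window(frame$frame_id, keep, L, frame$seq_len)
    tibble(
      scaffold = frame$scaffold, frame_id = frame$frame_id,
      aa_start = keep,
      nt_start = coords$nt_start, nt_end = coords$nt_end,
      strand = frame$strand, group = g,
      score = scores[keep], evalue = ev,
      window = substring(aa, keep, keep + L - 1L)
    )
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) empty_hits() else arrange(out, .data$nt_start, .data$group)
}

empty_hits <- function() {
  tibble(
    scaffold = character(), frame_id = character(), aa_start = integer(),
    nt_start = integer(), nt_end = integer(), strand = character(),
    group = character(), score = numeric(), evalue = numeric(),
    window = character()
  )
}

empty_loci <- function() {
  tibble(
    locus_id = character(), scaffold = character(), nt_start = integer(),
    nt_end = integer(), strand = character(), best_group = character(),
    score = numeric(), margin = numeric(), evalue = numeric(),
    status = character(), coord_space = character(), group_scores = list()
  )
}

#' Merge window hits into loci
#'
#' Hits on the same scaffold and strand whose nucleotide intervals overlap or
#' lie within `max_gap` of each other are merged into one locus spanning
#' their coordinate hull. Per merged locus, `group_scores[[g]]` is the best
#' window score for group `g` among the members; `best_group` is the argmax,
#' and `margin` is the gap in bits to the second-best group (`Inf` when only
#' one group scored). Status is left unresolved; [assign_group()] sets it.
#'
#' The default gap tolerates a single intron splitting the homeodomain across
#' frame hits on one strand.
#'
#' @param hits Window-hit tibble from [scan_frame()] (one genome).
#' @param max_gap Maximum nt gap between merged intervals.
#' @return Locus tibble (see [scan_genome()] for columns).
#' @export
merge_hits <- function(hits, max_gap = 5000L) {
  if (nrow(hits) == 0) return(empty_loci())
  hits <- arrange(hits, .data$scaffold, .data$strand, .data$nt_start, .data$nt_end)
  out <- hits |>
    group_by(.data$scaffold, .data$strand) |>
    mutate(chunk = cumsum(.data$nt_start > cummax(dplyr::lag(.data$nt_end,
                                                             default = dplyr::first(.data$nt_end))) + max_gap)) |>
    group_by(.data$scaffold, .data$strand, .data$chunk) |>
    summarise(
      nt_start = min(.data$nt_start),
      nt_end = max(.data$nt_end),
      group_scores = list({
        gs <- tapply(.data$score, .data$group, max)
        sort(setNames(as.numeric(gs), names(gs)), decreasing = TRUE)
      }),
      evalue = min(.data$evalue),
      windows = list(setNames(.data$window, .data$group)),
      .groups = "drop"
    )
  out |>
    mutate(
      best_group = purrr::map_chr(.data$group_scores, ~ names(.x)[1]),
      score = purrr::map_dbl(.data$group_scores, ~ .x[[1]]),
      margin = purrr::map_dbl(.data$group_scores,
                              ~ if (length(.x) > 1) .x[[1]] - .x[[2]] else Inf),
      status = NA_character_,
      coord_space = "nt",
      locus_id = paste0(.data$scaffold, ":", .data$nt_start, "-", .data$nt_end,
                        "(", .data$strand, ")")
    ) |>
    select("locus_id", "scaffold", "nt_start", "nt_end", "strand",
           "best_group", "score", "margin", "evalue", "status",
           "coord_space", "group_scores", "windows") |>
    arrange(.data$scaffold, .data$nt_start)
}

#' Scan a genome for Hox homeodomain loci
#'
#' Six-frame translation of every scaffold, window scoring against every
#' profile, E-value filtering at `threshold_E` (E-values share a single
#' search-space size `m` = total windows genome-wide across frames), and
#' interval merging into loci. With `rounds = 2`, windows accepted in round 1
#' augment their matched profiles ([augment_profile()], weight 1 per hit),
#' calibration is re-run with each profile's stored seed, and the scan is
#' repeated with the enriched profiles; if round 1 accepts nothing, round 2
#' is identical to round 1.
#'
#' @param profiles Named list of calibrated `hox_profile` objects.
#' @param genome Tibble of nucleotide records (columns `id`, `seq`; see
#'   [read_fasta()]).
#' @param threshold_E E-value cutoff (default `1e-5`).
#' @param max_gap Merge gap in nt (default 5000).
#' @param rounds 1 or 2 search rounds (default 2).
#' @return Locus tibble: `locus_id`, `scaffold`, `nt_start`, `nt_end`
#'   (0-based half-open), `strand`, `best_group`, `score` (bits), `margin`
#'   (bits), `evalue`, `status` (set by [assign_group()]), `coord_space`
#'   (`"nt"`), `group_scores` (named list-column), `windows` (list-column of
#'   member window residues).
#' @export
scan_genome <- function(profiles, genome, threshold_E = 1e-5, max_gap = 5000L,
                        rounds = 2L) {
  if (!rounds %in% c(1L, 2L)) abort("scan_genome: rounds must be 1 or 2")
  if (nrow(genome) == 0) return(empty_loci())
  L <- profiles[[1]]$L
  frames <- purrr::map(seq_len(nrow(genome)), function(i) {
    six_frame_translate(genome$seq[i], id = genome$id[i])
  }) |> bind_rows()
  m <- sum(pmax(0L, nchar(frames$aa_seq) - L + 1L))
  if (m < 1) return(empty_loci())

  run_round <- function(profs) {
    purrr::map(seq_len(nrow(frames)), function(i) {
      scan_frame(profs, frames[i, ], threshold_E = threshold_E, m = m)
    }) |> bind_rows()
  }

  hits <- run_round(profiles)
  if (rounds == 2L && nrow(hits) > 0) {
    aug_groups <- unique(hits$group)
    profiles2 <- profiles[aug_groups]
    for (g in aug_groups) {
      profiles2[[g]] <- augment_profile(profiles2[[g]],
                                        hits$window[hits$group == g],
                                        weight = 1)
    }
    # profiles without round-1 hits are unchanged, so only augmented groups
    # need rescanning; their round-1 hits are superseded
    hits <- bind_rows(filter(hits, !.data$group %in% aug_groups),
                      run_round(profiles2))
  }
  merge_hits(hits, max_gap = max_gap)
}

#' Scan a proteome for Hox homeodomain loci
#'
#' Scores every window of every protein against every profile. Locus
#' coordinates are amino-acid indexed (0-based half-open within the protein)
#' with `coord_space = "aa"` distinguishing them from genomic nt loci;
#' strands are fixed to `"+"`. Overlapping window hits within one protein are
#' merged.
#'
#' @param profiles Named list of calibrated `hox_profile` objects.
#' @param proteins Tibble of amino-acid records (columns `id`, `seq`).
#' @param threshold_E E-value cutoff.
#' @return Locus tibble as in [scan_genome()], with `coord_space = "aa"`.
#' @export
scan_proteome <- function(profiles, proteins, threshold_E = 1e-5) {
  if (nrow(proteins) == 0) return(empty_loci())
  looks_nt <- all(grepl("^[ACGTN]*$", toupper(proteins$seq)))
  if (looks_nt) abort("scan_proteome: sequences look like nucleotides; use scan_genome()")
  L <- profiles[[1]]$L
  m <- sum(pmax(0L, nchar(proteins$seq) - L + 1L))
  if (m < 1) return(empty_loci())
  hits <- purrr::map(seq_len(nrow(proteins)), function(i) {
    frame <- list(scaffold = proteins$id[i], frame_id = "+1", strand = "+",
                  aa_seq = toupper(proteins$seq[i]),
                  seq_len = nchar(proteins$seq[i]))
    h <- scan_frame_aa(profiles, frame, threshold_E, m)
    h
  }) |> bind_rows()
  loci <- merge_hits(hits, max_gap = 0L)
  loci$coord_space <- rep("aa", nrow(loci))
  loci
}

# scan_frame variant for protein space: coordinates are aa indices, not
# nt-mapped.
scan_frame_aa <- function(profiles, frame, threshold_E, m) {
  L <- profiles[[1]]$L
  aa <- frame$aa_seq
  n_win <- max(0L, nchar(aa) - L + 1L)
  if (n_win == 0) return(empty_hits())
  code <- aa_encode_str(aa)
  hits <- purrr::imap(profiles, function(prof, g) {
    cutoff <- score_cutoff(prof, threshold_E, m)
    scores <- score_windows_cutoff_cpp(code, prof$M, cutoff)
    keep <- which(is.finite(scores) & scores >= cutoff)
    if (length(keep) == 0) return(NULL)
    tibble(
      scaffold = frame$scaffold, frame_id = "+1", aa_start = keep,
      nt_start = keep - 1L, nt_end = keep - 1L + L,
      strand = "+", group = g, score = scores[keep],
      evalue = profile_evalue(prof, scores[keep], m),
      window = substring(aa, keep, keep + L - 1L)
    )
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) empty_hits() else out
}

#' Export loci as GFF3 and a locus table
#'
#' @param loci Locus tibble from [scan_genome()] (nt coordinates).
#' @param gff_path,table_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the feature tibble written.
#' @export
write_loci <- function(loci, gff_path = NULL, table_path = NULL) {
  feats <- tibble(
    feature_id = loci$locus_id, scaffold = loci$scaffold,
    start = loci$nt_start, end = loci$nt_end, strand = loci$strand,
    kind = "gene",
    group = loci$best_group,
    score = sprintf("%.3f", loci$score),
    margin = ifelse(is.finite(loci$margin), sprintf("%.3f", loci$margin), "Inf"),
    status = ifelse(is.na(loci$status), "unresolved", loci$status)
  )
  if (!is.null(gff_path)) write_gff3(feats, gff_path)
  if (!is.null(table_path)) {
    readr::write_tsv(select(loci, -"group_scores", -dplyr::any_of("windows")),
                     table_path)
  }
  invisible(feats)
}
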