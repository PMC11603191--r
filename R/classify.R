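#' Resolve locus status with an ambiguity margin
#'
#' A locus is `assigned` to its best-scoring group when the margin to the
#' second-best group is at least `margin_delta` bits, otherwise `ambiguous`.
#' The best group is always recorded either way. The margin rule stands in
#' for tree-based orthology assignment: a locus whose two best groups score
#' within a few bits of each other carries too little signal to separate
#' them.
#'
#' @param loci Locus tibble from [scan_genome()] / [merge_hits()].
#' @param margin_delta Minimum score margin in bits (default 3).
#' @return The locus tibble with `status` set to `"assigned"` or
#'   `"ambiguous"`.
#' @export
assign_group <- function(loci, margin_delta = 3) {
  if (nrow(loci) == 0) return(loci)
  if (any(vapply(loci$group_scores, length, integer(1)) == 0)) {
    abort("assign_group: locus with empty group_scores")
  }
  mutate(loci, status = ifelse(.data$margin >= margin_delta, "assigned", "ambiguous"))
}

#' Count Hox gene multiplicity per orthology group
#'
#' For one species, the multiplicity of a group is the number of distinct
#' genomic copies among its assigned loci: loci of the same group within
#' `min_separation` nt of each other (chained) collapse to one copy, loci
#' further apart (or on different scaffolds, or in protein space on different
#' proteins) count separately. This is how a recent within-cluster tandem
#' duplication is distinguished from redundant calls at one locus.
#'
#' @param loci Assigned locus tibble for one species.
#' @param min_separation Distance (nt gap between locus intervals) below
#'   which same-group loci collapse (default 5000, matching the scan merge
#'   gap so duplication calls and merging are mutually consistent).
#' @return Tibble with columns `group`, `multiplicity`.
#' @export
call_duplications <- function(loci, min_separation = 5000L) {
  loci <- filter(loci, .data$status %in% "assigned")
  if (nrow(loci) == 0) {
    return(tibble(group = character(), multiplicity = integer()))
  }
  loci |>
    arrange(.data$best_group, .data$scaffold, .data$nt_start) |>
    group_by(group = .data$best_group, .data$scaffold) |>
    mutate(gap = .data$nt_start - dplyr::lag(as.numeric(.data$nt_end),
                                             default = -Inf),
           new_copy = is.infinite(.data$gap) | .data$gap > min_separation) |>
    group_by(.data$group) |>
    summarise(multiplicity = sum(.data$new_copy), .groups = "drop")
}

#' Assemble a species-by-group complement table
#'
#' Builds the multiplicity matrix of orthology groups across species:
#' 0 marks an absent orthologue and 2 a duplication, alongside a per-species
#' count of ambiguous (unassigned) loci.
#'
#' @param assignments Tibble with columns `species` plus the locus columns of
#'   [assign_group()] output (concatenate per-species locus tables with a
#'   `species` column).
#' @param min_separation Passed to [call_duplications()].
#' @param species Species to include even without loci (all-zero rows);
#'   defaults to the species present in `assignments`.
#' @return A `hox_complement`: tibble with one row per species, one integer
#'   column per orthology group, and an `ambiguous` count column.
#' @export
build_complement <- function(assignments, min_separation = 5000L,
                             species = NULL) {
  stopifnot("species" %in% names(assignments))
  species <- union(species, unique(assignments$species))
  rows <- purrr::map(species, function(sp) {
    loci <- filter(assignments, .data$species == sp)
    mult <- call_duplications(loci, min_separation = min_separation)
    counts <- setNames(rep(0L, length(hox_groups())), hox_groups())
    counts[mult$group] <- as.integer(mult$multiplicity)
    n_amb <- sum(loci$status %in% "ambiguous")
    as_tibble(c(list(species = sp), as.list(counts), list(ambiguous = n_amb)))
  })
  out <- bind_rows(rows)
  class(out) <- c("hox_complement", class(out))
  out
}

#' Long-format view of a complement table
#'
#' @param complement A `hox_complement`.
#' @return Tibble with columns `species`, `group`, `count`, `status`
#'   (`"absent"`, `"present"`, or `"duplicated"`), rendering-ready.
#' @export
complement_long <- function(complement) {
  tidyr::pivot_longer(as_tibble(complement), cols = all_of(hox_groups()),
                      names_to = "group", values_to = "count") |>
    mutate(status = dplyr::case_when(
      .data$count == 0 ~ "absent",
      .data$count == 1 ~ "present",
      TRUE ~ "duplicated"
    )) |>
    select("species", "group", "count", "status")
}

#' Write / read a complement table as TSV
#'
#' Species rows, group columns, integer cells (0 = absent, 2 = duplicated).
#' `read_complement()` is the exact inverse.
#'
#' @param complement A `hox_complement`.
#' @param path File path.
#' @return `path` invisibly / a `hox_complement`.
#' @export
write_complement <- function(complement, path) {
  readr::write_tsv(as_tibble(complement), path)
  invisible(path)
}

#' @rdname write_complement
#' @export
read_complement <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(species = "c", .default = "i"))
  missing <- setdiff(c("species", hox_groups(), "ambiguous"), names(out))
  if (length(missing) > 0) {
    abort(paste0("complement table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  class(out) <- c("hox_complement", class(out))
  out
}

#' Convert a complement table to a presence/absence matrix
#'
#' Presence = multiplicity >= 1. Species whose loci are all ambiguous
#' contribute all-absent rows (with a warning), since an unassignable locus
#' cannot prove a group's presence.
#'
#' @param complement A `hox_complement`.
#' @return Tibble with columns `species` plus one 0/1 column per group.
#' @export
complement_presence <- function(complement) {
  tb <- as_tibble(complement)
  amb_only <- tb$ambiguous > 0 & rowSums(tb[hox_groups()]) == 0
  if (any(amb_only)) {
    warn(paste0("species with only ambiguous loci treated as absent: ",
                paste(tb$species[amb_only], collapse = ", ")))
  }
  mutate(tb, across(all_of(hox_groups()), ~ as.integer(.x >= 1))) |>
    select("species", all_of(hox_groups()))
}
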