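#' Detect Hox clusters
#'
#' A Hox cluster is a group of at least `min_genes` Hox loci on one scaffold
#' whose coordinate hull spans at most `max_span` nt (boundary inclusive:
#' span exactly `max_span` qualifies). Within each scaffold, candidate
#' clusters are contiguous runs of loci in genomic order; when qualifying
#' runs overlap, selection maximises member count, then minimises span, then
#' takes the leftmost start, removes the chosen loci, and repeats — so each
#' locus belongs to at most one cluster and the result is deterministic.
#'
#' @param loci Locus tibble (after [assign_group()]). Ambiguous loci are
#'   excluded unless `include_ambiguous = TRUE`.
#' @param min_genes Minimum member count (default 4).
#' @param max_span Maximum hull span in nt (default 300000).
#' @param include_ambiguous Include ambiguous-status loci as members.
#' @return A `hox_clusters` tibble, one row per cluster: `cluster_id`,
#'   `scaffold`, `n_genes`, `start`, `end`, `span`, `order_ranks`
#'   (list-column of canonical ranks in genomic order), `strands`
#'   (list-column), `tau`, `discordant_pairs`, `modal_strand`,
#'   `orientation_consistency`, `flipped` (list-column of member locus ids on
#'   the non-modal strand), `members` (list-column of member locus tibbles),
#'   `min_genes`, `max_span`.
#' @export
detect_clusters <- function(loci, min_genes = 4L, max_span = 300000L,
                            include_ambiguous = FALSE) {
  if (!include_ambiguous) loci <- filter(loci, .data$status %in% "assigned")
  out <- list()
  for (sc in unique(loci$scaffold)) {
    pool <- arrange(filter(loci, .data$scaffold == sc), .data$nt_start, .data$nt_end)
    repeat {
      n <- nrow(pool)
      if (n < min_genes) break
      # enumerate contiguous windows over the remaining loci
      best <- NULL
      for (i in seq_len(n - min_genes + 1L)) {
        hull_end <- -Inf
        for (j in i:n) {
          hull_end <- max(hull_end, pool$nt_end[j])
          size <- j - i + 1L
          span <- hull_end - pool$nt_start[i]
          if (span > max_span) break
          if (size >= min_genes) {
            cand <- list(i = i, j = j, size = size, span = span)
            if (is.null(best) ||
                cand$size > best$size ||
                (cand$size == best$size && cand$span < best$span) ||
                (cand$size == best$size && cand$span == best$span &&
                 pool$nt_start[cand$i] < pool$nt_start[best$i])) {
              best <- cand
            }
          }
        }
      }
      if (is.null(best)) break
      members <- pool[best$i:best$j, ]
      out[[length(out) + 1L]] <- cluster_row(members, min_genes, max_span)
      pool <- pool[-(best$i:best$j), ]
    }
  }
  res <- if (length(out) == 0) empty_clusters() else bind_rows(out)
  res <- arrange(res, .data$scaffold, .data$start)
  if (nrow(res) > 0) res$cluster_id <- paste0("cluster_", seq_len(nrow(res)))
  class(res) <- c("hox_clusters", class(res))
  res
}

empty_clusters <- function() {
  tibble(
    cluster_id = character(), scaffold = character(), n_genes = integer(),
    start = integer(), end = integer(), span = integer(),
    order_ranks = list(), strands = list(), tau = numeric(),
    discordant_pairs = integer(), modal_strand = character(),
    orientation_consistency = numeric(), flipped = list(), members = list(),
    min_genes = integer(), max_span = integer()
  )
}

cluster_row <- function(members, min_genes, max_span) {
  ranks <- hox_rank(members$best_group)
  col <- collinearity_ranks(ranks)
  ori <- orientation_of(members$strand, members$locus_id)
  tibble(
    cluster_id = NA_character_,
    scaffold = members$scaffold[1],
    n_genes = nrow(members),
    start = min(members$nt_start),
    end = max(members$nt_end),
    span = max(members$nt_end) - min(members$nt_start),
    order_ranks = list(ranks),
    strands = list(members$strand),
    tau = col$tau,
    discordant_pairs = col$discordant,
    modal_strand = ori$modal_strand,
    orientation_consistency = ori$consistency,
    flipped = list(ori$flipped),
    members = list(members),
    min_genes = as.integer(min_genes),
    max_span = as.integer(max_span)
  )
}

#' Collinearity of a Hox cluster
#'
#' Kendall-style concordance between genomic gene order and canonical
#' anterior-posterior rank order. Over all member pairs with distinct
#' canonical ranks (equal-rank pairs, e.g. two HOX6-8 subtypes or duplicate
#' copies, are excluded), a pair is concordant when the gene occurring first
#' along the scaffold has the lower rank. `tau = (C - D) / (C + D)`; under
#' whole-cluster reversal `tau_rev = -tau`. Undefined (NA) when fewer than
#' two distinct ranks are present.
#'
#' @param cluster One row of a `hox_clusters` tibble, or a locus tibble of
#'   cluster members ordered by position.
#' @return List with `tau`, `concordant`, `discordant`, `tau_rev`.
#' @export
collinearity <- function(cluster) {
  ranks <- if ("order_ranks" %in% names(cluster)) {
    cluster$order_ranks[[1]]
  } else {
    hox_rank(arrange(cluster, .data$nt_start)$best_group)
  }
  collinearity_ranks(ranks)
}

collinearity_ranks <- function(ranks) {
  n <- length(ranks)
  C <- 0L; D <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (ranks[i] == ranks[j]) next
        if (ranks[j] > ranks[i]) C <- C + 1L else D <- D + 1L
      }
    }
  }
  if (C + D == 0) {
    list(tau = NA_real_, concordant = 0L, discordant = 0L, tau_rev = NA_real_)
  } else {
    tau <- (C - D) / (C + D)
    list(tau = tau, concordant = C, discordant = D, tau_rev = -tau)
  }
}

#' Hox loci span per scaffold
#'
#' Coordinate hull of all Hox loci on each scaffold, regardless of whether
#' they form a cluster — the "genomic loci size" view of a possibly loosely
#' connected arrangement.
#'
#' @param loci Locus tibble.
#' @return Tibble with columns `scaffold`, `n_hox`, `start`, `end`, `span`.
#' @export
loci_span <- function(loci) {
  if (nrow(loci) == 0) {
    return(tibble(scaffold = character(), n_hox = integer(),
                  start = integer(), end = integer(), span = integer()))
  }
  loci |>
    group_by(.data$scaffold) |>
    summarise(n_hox = n(), start = min(.data$nt_start), end = max(.data$nt_end),
              span = max(.data$nt_end) - min(.data$nt_start), .groups = "drop")
}

#' Transcriptional orientation profile of a cluster
#'
#' Majority strand (ties broken to `"+"`), the fraction of members on it,
#' and the ids of members transcribed from the other strand.
#'
#' @param cluster One row of a `hox_clusters` tibble, or a member locus
#'   tibble.
#' @return List with `modal_strand`, `consistency`, `flipped`.
#' @export
orientation_profile <- function(cluster) {
  members <- if ("members" %in% names(cluster)) cluster$members[[1]] else cluster
  orientation_of(members$strand, members$locus_id)
}

orientation_of <- function(strands, ids) {
  n_plus <- sum(strands == "+")
  n_minus <- sum(strands == "-")
  modal <- if (n_plus >= n_minus) "+" else "-"
  list(modal_strand = modal,
       consistency = sum(strands == modal) / length(strands),
       flipped = ids[strands != modal])
}

#' Cluster architecture table
#'
#' One row per cluster with the headline architecture metrics (taxon,
#' scaffold, Hox locus count, genomic loci span of the scaffold, cluster
#' span, non-Hox interruption count when an interruption report is
#' supplied).
#'
#' @param clusters A `hox_clusters` tibble.
#' @param loci The locus tibble the clusters were built from (for the
#'   scaffold-wide hull).
#' @param species Taxon label for the table.
#' @param interruptions Optional output of [count_non_hox()] rows matched by
#'   `cluster_id`.
#' @return Tibble mirroring a cluster-features table: `taxon`, `scaffold`,
#'   `n_hox_scaffold`, `loci_span_nt`, `cluster_id`, `n_genes`,
#'   `cluster_span_nt`, `tau`, `orientation_consistency`, `n_non_hox`.
#' @export
cluster_table <- function(clusters, loci, species = "species",
                          interruptions = NULL) {
  spans <- loci_span(loci)
  out <- as_tibble(clusters) |>
    left_join(select(spans, "scaffold", n_hox_scaffold = "n_hox",
                     loci_span_nt = "span"),
              by = "scaffold") |>
    mutate(taxon = species, cluster_span_nt = .data$span) |>
    select("taxon", "scaffold", "n_hox_scaffold", "loci_span_nt",
           "cluster_id", "n_genes", "cluster_span_nt", "tau",
           "orientation_consistency")
  if (!is.null(interruptions)) {
    out <- left_join(out, select(interruptions, "cluster_id", "n_non_hox"),
                     by = "cluster_id")
  } else {
    out$n_non_hox <- NA_integer_
  }
  out
}

#' Write cluster members as a BED file
#'
#' 0-based half-open member intervals for genome-browser loading; the name
#' field carries the assigned group, the score field the bit score.
#'
#' @param clusters A `hox_clusters` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, path) {
  members <- bind_rows(clusters$members)
  bed <- tibble(
    chrom = members$scaffold, start = members$nt_start, end = members$nt_end,
    name = members$best_group,
    score = round(pmin(1000, pmax(0, members$score))),
    strand = members$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
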