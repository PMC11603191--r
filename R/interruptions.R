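#' Count non-Hox gene interruptions within a cluster
#'
#' Counts annotated protein-coding genes (kind `"gene"`) that are not Hox
#' loci and whose interval overlaps the cluster hull
#' `[min Hox start, max Hox end)` by at least 1 nt. Each gene is counted
#' once. "Within the cluster" is operationalised as any-overlap with the
#' hull, so a gene straddling a cluster boundary counts.
#'
#' @param cluster One row of a `hox_clusters` tibble (or any object with
#'   `scaffold`, `start`, `end`, and optionally `cluster_id`).
#' @param annotation Gene-feature tibble from [read_gff3()] on the same
#'   coordinate system.
#' @param hox_ids Character vector of feature ids that are Hox loci (never
#'   counted as interruptions).
#' @return Tibble with one row: `cluster_id`, `scaffold`, `start`, `end`,
#'   `n_non_hox`, `non_hox_ids` (list-column).
#' @export
count_non_hox <- function(cluster, annotation, hox_ids = character()) {
  cl <- as.list(cluster)
  if (nrow(annotation) > 0 && !(cl$scaffold %in% annotation$scaffold)) {
    abort(paste0("count_non_hox: annotation has no features on scaffold ",
                 cl$scaffold))
  }
  hits <- annotation |>
    filter(.data$kind == "gene",
           .data$scaffold == cl$scaffold,
           !.data$feature_id %in% hox_ids,
           .data$start < cl$end, .data$end > cl$start) |>
    distinct(.data$feature_id)
  tibble(
    cluster_id = if (is.null(cl$cluster_id)) NA_character_ else cl$cluster_id,
    scaffold = cl$scaffold, start = cl$start, end = cl$end,
    n_non_hox = nrow(hits), non_hox_ids = list(hits$feature_id)
  )
}

#' Count interruptions for every cluster
#'
#' @param clusters A `hox_clusters` tibble.
#' @inheritParams count_non_hox
#' @return One [count_non_hox()] row per cluster.
#' @export
count_non_hox_all <- function(clusters, annotation, hox_ids = character()) {
  if (nrow(clusters) == 0) {
    return(count_non_hox(list(cluster_id = character(0)), annotation)[0, ])
  }
  purrr::map(seq_len(nrow(clusters)), function(i) {
    count_non_hox(clusters[i, ], annotation, hox_ids)
  }) |> bind_rows()
}

#' Locate mature miRNAs within a cluster interval
#'
#' Seed-and-extend search for short (~22 nt) mature miRNA queries inside a
#' genomic interval: exact `k`-mer seeds on both strands anchor an ungapped
#' alignment across the full query length, and alignments passing the
#' identity and coverage thresholds are reported. Overlapping hits of one
#' query are deduplicated to the best identity. Defaults are chosen so an
#' exact 22-mer always passes and a 22-mer with four or more substitutions
#' never does. Note the seed requirement: a heavily mutated query with no
#' surviving exact `k`-mer cannot be anchored even if its overall identity
#' clears `min_identity`.
#'
#' @param scaffold_seq Nucleotide string of the scaffold (or a one-row tibble
#'   with `id`, `seq`).
#' @param interval Length-2 numeric `[start, end)` (0-based half-open) on the
#'   scaffold, e.g. a cluster hull; `NULL` scans the whole scaffold.
#' @param mirnas Tibble of mature miRNA queries (`id`, `seq`; miRBase-style
#'   ids), each 15-30 nt.
#' @param k Exact seed length (default 9).
#' @param min_identity Minimum identity over the aligned region (default
#'   0.85).
#' @param min_coverage Minimum fraction of the query aligned (default 0.9;
#'   < 1 only at interval edges).
#' @param scaffold_id Id to report when `scaffold_seq` is a bare string.
#' @return Tibble of hits: `mirna_id`, `scaffold`, `start`, `end` (0-based
#'   half-open scaffold coordinates), `strand`, `identity`, `coverage`.
#' @export
find_mirnas <- function(scaffold_seq, interval = NULL, mirnas,
                        k = 9L, min_identity = 0.85, min_coverage = 0.9,
                        scaffold_id = "scaffold") {
  if (is.data.frame(scaffold_seq)) {
    scaffold_id <- scaffold_seq$id[1]
    scaffold_seq <- scaffold_seq$seq[1]
  }
  if (any(nchar(mirnas$seq) < k)) {
    abort(paste0("find_mirnas: query shorter than seed length k = ", k, ": ",
                 paste(mirnas$id[nchar(mirnas$seq) < k], collapse = ", ")))
  }
  out_range <- nchar(mirnas$seq) < 15 | nchar(mirnas$seq) > 30
  if (any(out_range)) {
    warn(paste0("find_mirnas: query length outside the 15-30 nt mature miRNA ",
                "range: ", paste(mirnas$id[out_range], collapse = ", ")))
  }
  if (is.null(interval)) interval <- c(0L, nchar(scaffold_seq))
  shift <- as.integer(interval[1])
  subject <- substr(scaffold_seq, interval[1] + 1L, interval[2])
  subj_dna <- Biostrings::DNAString(subject)
  slen <- nchar(subject)

  all_hits <- purrr::map(seq_len(nrow(mirnas)), function(qi) {
    qid <- mirnas$id[qi]
    hits_q <- purrr::map(c("+", "-"), function(strand) {
      q <- toupper(mirnas$seq[qi])
      if (strand == "-") q <- revcomp(q)
      ql <- nchar(q)
      qc <- str_chars(q)
      # candidate alignment starts (1-based in subject) from exact k-mer seeds
      starts <- integer(0)
      for (o in seq_len(ql - k + 1L)) {
        seed <- substr(q, o, o + k - 1L)
        mt <- Biostrings::matchPattern(seed, subj_dna)
        if (length(mt) > 0) starts <- c(starts, BiocGenerics::start(mt) - (o - 1L))
      }
      starts <- sort(unique(starts))
      if (length(starts) == 0) return(NULL)
      rows <- purrr::map(starts, function(p) {
        a_lo <- max(1L, p); a_hi <- min(slen, p + ql - 1L)
        aligned <- a_hi - a_lo + 1L
        if (aligned <= 0) return(NULL)
        sc <- str_chars(substr(subject, a_lo, a_hi))
        qseg <- qc[(a_lo - p + 1L):(a_hi - p + 1L)]
        ident <- sum(sc == qseg) / aligned
        cov <- aligned / ql
        if (ident >= min_identity && cov >= min_coverage) {
          tibble(mirna_id = qid, scaffold = scaffold_id,
                 start = shift + a_lo - 1L, end = shift + a_hi,
                 strand = strand, identity = ident, coverage = cov)
        } else NULL
      })
      bind_rows(rows)
    }) |> bind_rows()
    if (nrow(hits_q) == 0) return(NULL)
    dedup_overlaps(hits_q)
  })
  out <- bind_rows(all_hits)
  if (nrow(out) == 0) {
    tibble(mirna_id = character(), scaffold = character(), start = integer(),
           end = integer(), strand = character(), identity = numeric(),
           coverage = numeric())
  } else {
    arrange(out, .data$start, .data$mirna_id)
  }
}

# Keep the best-identity hit within each set of mutually overlapping hits of
# one query (ties: higher coverage, then leftmost).
dedup_overlaps <- function(hits) {
  hits <- arrange(hits, dplyr::desc(.data$identity), dplyr::desc(.data$coverage),
                  .data$start)
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    overlaps <- nrow(kept) > 0 &&
      any(kept$start < h$end & kept$end > h$start)
    if (!overlaps) kept <- bind_rows(kept, h)
  }
  kept
}

#' Export miRNA hits as GFF3 and/or TSV
#'
#' @param hits Output of [find_mirnas()].
#' @param gff_path,table_path Output paths; either may be `NULL`.
#' @return The feature tibble, invisibly.
#' @export
write_mirna_hits <- function(hits, gff_path = NULL, table_path = NULL) {
  feats <- tibble(
    feature_id = paste0(hits$mirna_id, "_", seq_len(nrow(hits))),
    scaffold = hits$scaffold, start = hits$start, end = hits$end,
    strand = hits$strand, kind = "mirna",
    identity = sprintf("%.3f", hits$identity),
    coverage = sprintf("%.3f", hits$coverage)
  )
  if (!is.null(gff_path)) write_gff3(feats, gff_path)
  if (!is.null(table_path)) readr::write_tsv(hits, table_path)
  invisible(feats)
}
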