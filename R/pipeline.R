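#' Run the full Hox annotation pipeline on one genome
#'
#' Chains profile building, the two-round six-frame scan, group assignment,
#' complement assembly, cluster detection, interruption counting and miRNA
#' search, and writes every artifact plus a machine-readable run log to
#' `out_dir`. Inputs may be in-memory tibbles or file paths (FASTA / GFF3).
#'
#' @param genome Genome tibble (`id`, `seq`) or nt FASTA path.
#' @param reference Labelled alignment tibble or aa FASTA path with
#'   `group=` description tags (see [read_reference_alignment()]).
#' @param out_dir Output directory, created if needed. `NULL` skips writing.
#' @param annotation Optional gene-feature tibble or GFF3 path for
#'   interruption counting.
#' @param mirnas Optional miRNA query tibble (`id`, `seq`) or nt FASTA path.
#' @param species Taxon label used in tables.
#' @param threshold_E,max_gap,rounds Scan parameters (see [scan_genome()]).
#' @param margin_delta Assignment margin in bits (see [assign_group()]).
#' @param min_genes,max_span Cluster definition (see [detect_clusters()]).
#' @param min_separation Duplication separation (see [call_duplications()]).
#' @param alpha,gap_max,n_windows Profile parameters (see [build_profiles()]).
#' @param seed Seed for E-value calibration.
#' @param quiet Suppress progress messages.
#' @return A list with elements `profiles`, `loci`, `complement`, `clusters`,
#'   `cluster_table`, `interruptions`, `mirna_hits`, `log`.
#' @export
run_hox_pipeline <- function(genome, reference, out_dir = NULL,
                             annotation = NULL, mirnas = NULL,
                             species = "species",
                             threshold_E = 1e-5, max_gap = 5000L, rounds = 2L,
                             margin_delta = 3, min_genes = 4L,
                             max_span = 300000L, min_separation = 5000L,
                             alpha = 1, gap_max = 0.5, n_windows = 10000L,
                             seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(paste0(...))
  t0 <- Sys.time()
  inputs <- list()
  if (is.character(genome)) {
    inputs$genome <- genome
    genome <- read_fasta(genome, "nt")
  }
  if (is.character(reference)) {
    inputs$reference <- reference
    reference <- read_reference_alignment(reference)
  }
  if (is.character(annotation)) {
    inputs$annotation <- annotation
    annotation <- read_gff3(annotation, quiet = quiet)
  }
  if (is.character(mirnas)) {
    inputs$mirnas <- mirnas
    mirnas <- read_fasta(mirnas, "nt")
  }

  say("building profiles for ", length(unique(reference$group)), " group(s)")
  profiles <- build_profiles(reference, alpha = alpha, gap_max = gap_max,
                             n_windows = n_windows, seed = seed,
                             threshold_E = threshold_E)

  say("scanning ", nrow(genome), " scaffold(s), ",
      sum(nchar(genome$seq)), " nt, rounds = ", rounds)
  loci <- scan_genome(profiles, genome, threshold_E = threshold_E,
                      max_gap = max_gap, rounds = rounds)
  loci <- assign_group(loci, margin_delta = margin_delta)
  say("found ", nrow(loci), " locus/loci (",
      sum(loci$status %in% "assigned"), " assigned)")

  complement <- build_complement(mutate(loci, species = species),
                                 min_separation = min_separation,
                                 species = species)
  clusters <- detect_clusters(loci, min_genes = min_genes, max_span = max_span)
  say(nrow(clusters), " cluster(s)")

  interruptions <- NULL
  if (!is.null(annotation) && nrow(clusters) > 0) {
    hox_ids <- overlapping_feature_ids(annotation, loci)
    interruptions <- count_non_hox_all(clusters, annotation, hox_ids)
  }

  mirna_hits <- NULL
  if (!is.null(mirnas) && nrow(clusters) > 0) {
    mirna_hits <- purrr::map(seq_len(nrow(clusters)), function(i) {
      sc <- clusters$scaffold[i]
      find_mirnas(filter(genome, .data$id == sc),
                  interval = c(clusters$start[i], clusters$end[i]),
                  mirnas = mirnas)
    }) |> bind_rows() |> distinct()
  }

  tbl <- cluster_table(clusters, loci, species = species,
                       interruptions = interruptions)

  log <- list(
    tool = "hoxr", version = as.character(utils::packageVersion("hoxr")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    species = species,
    params = list(threshold_E = threshold_E, max_gap = max_gap,
                  rounds = rounds, margin_delta = margin_delta,
                  min_genes = min_genes, max_span = max_span,
                  min_separation = min_separation, alpha = alpha,
                  gap_max = gap_max, n_windows = n_windows, seed = seed),
    input_checksums = if (length(inputs) > 0) {
      as.list(tools::md5sum(unlist(inputs)))
    } else list(),
    n_loci = nrow(loci), n_assigned = sum(loci$status %in% "assigned"),
    n_clusters = nrow(clusters)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_loci(loci, file.path(out_dir, "loci.gff3"),
               file.path(out_dir, "loci.tsv"))
    write_complement(complement, file.path(out_dir, "complement.tsv"))
    readr::write_tsv(tbl, file.path(out_dir, "clusters.tsv"))
    if (nrow(clusters) > 0) {
      write_cluster_bed(clusters, file.path(out_dir, "cluster_members.bed"))
    }
    if (!is.null(interruptions)) {
      readr::write_tsv(select(interruptions, -"non_hox_ids"),
                       file.path(out_dir, "interruptions.tsv"))
    }
    if (!is.null(mirna_hits)) {
      write_mirna_hits(mirna_hits,
                       gff_path = file.path(out_dir, "mirna_hits.gff3"),
                       table_path = file.path(out_dir, "mirna_hits.tsv"))
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(profiles = profiles, loci = loci, complement = complement,
                 clusters = clusters, cluster_table = tbl,
                 interruptions = interruptions, mirna_hits = mirna_hits,
                 log = log))
}

# Annotation feature ids overlapping any detected locus (same scaffold,
# >= 1 nt): these are the annotation's own records of the Hox loci and must
# not be counted as interruptions.
overlapping_feature_ids <- function(annotation, loci) {
  if (nrow(loci) == 0 || nrow(annotation) == 0) return(character(0))
  hit <- purrr::map_lgl(seq_len(nrow(annotation)), function(i) {
    any(loci$scaffold == annotation$scaffold[i] &
          loci$nt_start < annotation$end[i] &
          loci$nt_end > annotation$start[i])
  })
  annotation$feature_id[hit]
}

#' Reconstruct loss history for a multi-species complement
#'
#' Convenience wrapper: converts a complement table to presence/absence and
#' runs the per-group Dollo reconstruction against a rooted species tree.
#'
#' @param complement A `hox_complement` covering the tree's species.
#' @param tree Rooted `phylo` (or newick path) whose tip labels match the
#'   complement's species tokens.
#' @param out_path Optional TSV path for the event table.
#' @return Event tibble from [summarize_events()].
#' @export
loss_history <- function(complement, tree, out_path = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  pres <- complement_presence(complement)
  missing <- setdiff(tree$tip.label, pres$species)
  if (length(missing) > 0) {
    abort(paste0("loss_history: species missing from complement: ",
                 paste(missing, collapse = ", ")))
  }
  events <- summarize_events(tree, pres)
  if (!is.null(out_path)) readr::write_tsv(events, out_path)
  events
}
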