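# Alphabetically first codon per residue under the standard genetic code.
first_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(cs) sort(cs)[1], character(1))
}

#' Back-translate an amino-acid string to nucleotides
#'
#' The default deterministic mode uses the alphabetically first codon for
#' each residue (codon-usage realism is irrelevant to amino-acid-space
#' scanning); `"random"` draws uniformly among each residue's codons.
#'
#' @param aa Amino-acid string (20 standard residues; `*` maps to a stop
#'   codon).
#' @param codon_choice `"first"` or `"random"`.
#' @param seed Optional seed isolating the random codon draw.
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
back_translate <- function(aa, codon_choice = c("first", "random"), seed = NULL) {
  codon_choice <- match.arg(codon_choice)
  chars <- str_chars(toupper(aa))
  gc <- Biostrings::GENETIC_CODE
  if (codon_choice == "first") {
    tab <- first_codon_table()
    return(paste0(tab[chars], collapse = ""))
  }
  draw <- function() {
    paste0(vapply(chars, function(a) {
      opts <- names(gc)[gc == a]
      opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Mutate a protein by uniform substitution
#'
#' Each site is substituted independently with probability `rate`; the
#' replacement is uniform over the 19 other residues, so a mutated site never
#' keeps its original residue.
#'
#' @param aa Amino-acid string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Optional seed isolating the draw from the caller's RNG stream.
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(aa, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    chars <- str_chars(toupper(aa))
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA20, a), 1L)
      }, character(1))
    }
    paste0(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic labelled homeodomain reference alignment
#'
#' Each orthology group receives a distinct random consensus window of
#' length `L` (drawn from uniform residue frequencies) and `n_per_group`
#' members mutated from it at the given divergence — a stand-in for a curated
#' reference set that makes groups separable by construction. Ungapped, so
#' profiles built from it share `L`.
#'
#' @param seed Integer seed.
#' @param groups Groups to include (default all nine).
#' @param n_per_group Members per group.
#' @param divergence Per-site substitution rate between consensus and member.
#' @param L Window length in residues (default 60, the homeodomain core).
#' @return Labelled alignment tibble (`group`, `member_id`, `aa_row`).
#' @export
synthetic_reference_alignment <- function(seed = 42L, groups = hox_groups(),
                                          n_per_group = 6L, divergence = 0.15,
                                          L = 60L) {
  check_group(groups)
  withr::with_seed(seed, {
    rows <- purrr::map(groups, function(g) {
      consensus <- paste0(sample(AA20, L, replace = TRUE), collapse = "")
      tibble(
        group = g,
        member_id = paste0(gsub("[^A-Za-z0-9]", "", g), "_m", seq_len(n_per_group)),
        aa_row = vapply(seq_len(n_per_group),
                        function(i) mutate_protein(consensus, divergence),
                        character(1))
      )
    })
    bind_rows(rows)
  })
}

#' Generate synthetic mature miRNA queries
#'
#' @param seed Integer seed.
#' @param n Number of queries.
#' @param len Query length in nt (default 22).
#' @return Tibble (`id`, `seq`) with miRBase-style ids.
#' @export
synthetic_mirnas <- function(seed = 42L, n = 3L, len = 22L) {
  withr::with_seed(seed, {
    tibble(
      id = paste0("syn-miR-", 100 + seq_len(n), "-3p"),
      seq = vapply(seq_len(n), function(i) {
        paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

#' Build a simulation configuration
#'
#' Describes a synthetic multi-scaffold genome: i.i.d. background at a given
#' GC, implanted homeodomain-encoding genes (per orthology group, with
#' controlled amino-acid divergence, optional intron, known strand and
#' coordinates), decoy non-Hox genes, and implanted mature miRNAs. Scaffolds
#' are named `scaffold_1 ... scaffold_<n>`.
#'
#' @param seed Integer seed governing every random choice of the simulation.
#' @param n_scaffolds,scaffold_len Number and length (nt, recycled) of
#'   scaffolds.
#' @param gc Background GC fraction (default 0.42, a typical nematode-like
#'   composition).
#' @param implants Tibble with columns `group`, `scaffold`, `nt_start`,
#'   `strand`, `aa_divergence`, and optionally `intron_offset_aa`,
#'   `intron_len` (NA = no intron).
#' @param n_decoys Number of decoy non-Hox genes (half composition-preserving
#'   shuffles of group consensus windows — positional signal destroyed —
#'   half random ORFs), placed at random non-overlapping positions.
#' @param decoy_len Decoy length in nt (coding part; default 180).
#' @param mirna_implants Tibble with columns `mirna_id`, `scaffold`,
#'   `position`, `strand`, `n_mismatches` (may be empty).
#' @param mirnas Tibble (`id`, `seq`) providing the miRNA query sequences.
#' @param reference_alignment Labelled alignment from which implant consensus
#'   windows are derived.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_scaffolds = 1L, scaffold_len = 1e6, gc = 0.42,
                       implants = NULL, n_decoys = 0L, decoy_len = 180L,
                       mirna_implants = NULL, mirnas = NULL,
                       reference_alignment = NULL) {
  if (is.null(implants)) {
    implants <- tibble(group = character(), scaffold = character(),
                       nt_start = integer(), strand = character(),
                       aa_divergence = numeric())
  }
  if (!"intron_offset_aa" %in% names(implants)) implants$intron_offset_aa <- NA_integer_
  if (!"intron_len" %in% names(implants)) implants$intron_len <- NA_integer_
  if (is.null(mirna_implants)) {
    mirna_implants <- tibble(mirna_id = character(), scaffold = character(),
                             position = integer(), strand = character(),
                             n_mismatches = integer())
  }
  if (is.null(reference_alignment)) {
    reference_alignment <- synthetic_reference_alignment()
  }
  scaffold_len <- rep_len(as.integer(scaffold_len), n_scaffolds)
  stopifnot(gc > 0, gc < 1,
            all(implants$aa_divergence >= 0 & implants$aa_divergence <= 1),
            all(implants$strand %in% c("+", "-")),
            all(mirna_implants$strand %in% c("+", "-")))
  check_group(implants$group)
  scafs <- paste0("scaffold_", seq_len(n_scaffolds))
  bad <- setdiff(c(implants$scaffold, mirna_implants$scaffold), scafs)
  if (length(bad) > 0) abort(paste0("unknown scaffold in config: ", paste(bad, collapse = ", ")))
  structure(list(
    seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
    scaffold_len = scaffold_len, scaffold_names = scafs, gc = gc,
    implants = implants, n_decoys = as.integer(n_decoys),
    decoy_len = as.integer(decoy_len),
    mirna_implants = mirna_implants, mirnas = mirnas,
    reference_alignment = reference_alignment
  ), class = "sim_config")
}

# Splice-like intron: canonical GT...AG ends, interior free of T so no stop
# codon can arise in any forward reading frame (keeps the flanking exon
# windows of the scanner open).
make_intron <- function(len) {
  if (len < 6) abort("intron length must be >= 6")
  paste0("GTCC", paste0(sample(c("A", "C", "G"), len - 6, replace = TRUE),
                        collapse = ""), "AG")
}

interval_overlaps <- function(start, end, occupied) {
  if (nrow(occupied) == 0) return(FALSE)
  any(occupied$start < end & occupied$end > start)
}

#' Simulate a genome with implanted Hox loci, decoys and miRNAs
#'
#' Fully deterministic given the config seed: background scaffolds are
#' sampled i.i.d. at the configured GC; each implant is the consensus window
#' of its group's profile mutated at the configured amino-acid divergence,
#' back-translated (first-codon rule), optionally split by a single intron
#' with canonical `GT...AG` ends, and placed at the configured position and
#' strand; decoys are composition-preserving shuffles of consensus windows
#' and random ORFs at random positions; miRNA implants are placed with the
#' configured number of substitutions.
#'
#' @param config A [sim_config()].
#' @return A `hox_sim` list: `genome` (tibble `id`, `desc`, `seq`), `truth`
#'   (feature tibble as in [read_gff3()], with `group`/`role` attributes),
#'   `manifest` (tibble of realized implant coordinates and divergences),
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    at <- (1 - config$gc) / 2
    gc2 <- config$gc / 2
    scafs <- purrr::map(config$scaffold_len, function(len) {
      sample(c("A", "C", "G", "T"), len, replace = TRUE,
             prob = c(at, gc2, gc2, at))
    })
    names(scafs) <- config$scaffold_names

    aln <- config$reference_alignment
    q <- pooled_background(aln)
    consensus <- purrr::map(unique(config$implants$group), function(g) {
      consensus_window(build_profile(aln, group = g, q = q))
    })
    names(consensus) <- unique(config$implants$group)

    occupied <- tibble(scaffold = character(), start = integer(), end = integer())
    truth <- list(); manifest <- list()

    imp <- config$implants
    for (i in seq_len(nrow(imp))) {
      cons <- consensus[[imp$group[i]]]
      mut <- mutate_protein(cons, imp$aa_divergence[i])
      realized <- mean(str_chars(mut) != str_chars(cons))
      nt <- back_translate(mut, "first")
      if (!is.na(imp$intron_offset_aa[i]) && !is.na(imp$intron_len[i])) {
        at_nt <- 3L * imp$intron_offset_aa[i]
        nt <- paste0(substr(nt, 1, at_nt), make_intron(imp$intron_len[i]),
                     substr(nt, at_nt + 1, nchar(nt)))
      }
      if (imp$strand[i] == "-") nt <- revcomp(nt)
      s0 <- as.integer(imp$nt_start[i]); e0 <- s0 + nchar(nt)
      len_scaf <- config$scaffold_len[match(imp$scaffold[i], config$scaffold_names)]
      if (e0 > len_scaf) abort(paste0("implant ", i, " extends past scaffold end"))
      occ <- filter(occupied, .data$scaffold == imp$scaffold[i])
      if (interval_overlaps(s0, e0, occ)) {
        abort(paste0("implant placement collision on ", imp$scaffold[i],
                     " at [", s0, ",", e0, ")"))
      }
      scafs[[imp$scaffold[i]]][(s0 + 1):e0] <- str_chars(nt)
      occupied <- bind_rows(occupied, tibble(scaffold = imp$scaffold[i],
                                             start = s0, end = e0))
      fid <- paste0("hox_", gsub("[^A-Za-z0-9]", "", imp$group[i]), "_", i)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, scaffold = imp$scaffold[i], start = s0, end = e0,
        strand = imp$strand[i], kind = "gene",
        attributes = list(list(group = imp$group[i], role = "hox"))
      )
      manifest[[length(manifest) + 1]] <- tibble(
        type = "hox", feature_id = fid, group = imp$group[i],
        scaffold = imp$scaffold[i], nt_start = s0, nt_end = e0,
        strand = imp$strand[i],
        aa_divergence_target = imp$aa_divergence[i],
        aa_divergence_realized = realized,
        n_mismatches = NA_integer_
      )
    }

    # decoys: alternate shuffled-consensus and random-ORF construction
    all_cons <- if (length(consensus) > 0) consensus else {
      cc <- purrr::map(unique(aln$group)[1],
                       function(g) consensus_window(build_profile(aln, group = g, q = q)))
      names(cc) <- unique(aln$group)[1]
      cc
    }
    for (d in seq_len(config$n_decoys)) {
      if (d %% 2 == 1) {
        src <- all_cons[[sample.int(length(all_cons), 1)]]
        aa <- paste0(sample(str_chars(src)), collapse = "")
        nt <- back_translate(aa, "first")
      } else {
        n_aa <- max(2L, config$decoy_len %/% 3L - 2L)
        aa <- paste0(c("M", sample(AA20, n_aa - 1L, replace = TRUE)), collapse = "")
        nt <- paste0(back_translate(aa, "first"), "TAA")
      }
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") nt <- revcomp(nt)
      sc <- sample(config$scaffold_names, 1)
      len_scaf <- config$scaffold_len[match(sc, config$scaffold_names)]
      placed <- FALSE
      for (try in 1:200) {
        s0 <- sample.int(len_scaf - nchar(nt), 1) - 1L
        e0 <- s0 + nchar(nt)
        occ <- filter(occupied, .data$scaffold == sc)
        if (!interval_overlaps(s0, e0, occ)) { placed <- TRUE; break }
      }
      if (!placed) abort("could not place decoy without collision after 200 tries")
      scafs[[sc]][(s0 + 1):e0] <- str_chars(nt)
      occupied <- bind_rows(occupied, tibble(scaffold = sc, start = s0, end = e0))
      fid <- paste0("decoy_", d)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, scaffold = sc, start = s0, end = e0,
        strand = strand, kind = "gene",
        attributes = list(list(role = "decoy"))
      )
      manifest[[length(manifest) + 1]] <- tibble(
        type = "decoy", feature_id = fid, group = NA_character_,
        scaffold = sc, nt_start = s0, nt_end = e0, strand = strand,
        aa_divergence_target = NA_real_, aa_divergence_realized = NA_real_,
        n_mismatches = NA_integer_
      )
    }

    mi <- config$mirna_implants
    for (i in seq_len(nrow(mi))) {
      if (is.null(config$mirnas)) abort("mirna_implants given but config$mirnas is NULL")
      src <- config$mirnas$seq[match(mi$mirna_id[i], config$mirnas$id)]
      if (is.na(src)) abort(paste0("unknown mirna_id ", mi$mirna_id[i]))
      chars <- str_chars(src)
      nmis <- mi$n_mismatches[i]
      if (nmis > 0) {
        pos <- sample.int(length(chars), nmis)
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      nt <- paste0(chars, collapse = "")
      if (mi$strand[i] == "-") nt <- revcomp(nt)
      s0 <- as.integer(mi$position[i]); e0 <- s0 + nchar(nt)
      occ <- filter(occupied, .data$scaffold == mi$scaffold[i])
      if (interval_overlaps(s0, e0, occ)) {
        abort(paste0("miRNA implant collision on ", mi$scaffold[i],
                     " at [", s0, ",", e0, ")"))
      }
      scafs[[mi$scaffold[i]]][(s0 + 1):e0] <- str_chars(nt)
      occupied <- bind_rows(occupied, tibble(scaffold = mi$scaffold[i],
                                             start = s0, end = e0))
      fid <- paste0("mirna_", mi$mirna_id[i], "_", i)
      truth[[length(truth) + 1]] <- tibble(
        feature_id = fid, scaffold = mi$scaffold[i], start = s0, end = e0,
        strand = mi$strand[i], kind = "mirna",
        attributes = list(list(role = "mirna", mirna_id = mi$mirna_id[i]))
      )
      manifest[[length(manifest) + 1]] <- tibble(
        type = "mirna", feature_id = fid, group = NA_character_,
        scaffold = mi$scaffold[i], nt_start = s0, nt_end = e0,
        strand = mi$strand[i],
        aa_divergence_target = NA_real_, aa_divergence_realized = NA_real_,
        n_mismatches = as.integer(nmis)
      )
    }

    genome <- tibble(
      id = config$scaffold_names,
      desc = paste0("synthetic scaffold len=", config$scaffold_len),
      seq = unname(vapply(scafs, paste0, character(1), collapse = ""))
    )
    truth_tbl <- if (length(truth) > 0) bind_rows(truth) else
      read_gff3_empty()
    manifest_tbl <- if (length(manifest) > 0) bind_rows(manifest) else
      tibble(type = character(), feature_id = character(), group = character(),
             scaffold = character(), nt_start = integer(), nt_end = integer(),
             strand = character(), aa_divergence_target = numeric(),
             aa_divergence_realized = numeric(), n_mismatches = integer())
    structure(list(genome = genome, truth = truth_tbl,
                   manifest = manifest_tbl, config = config),
              class = "hox_sim")
  })
}

read_gff3_empty <- function() {
  tibble(feature_id = character(), scaffold = character(), start = integer(),
         end = integer(), strand = character(), kind = character(),
         attributes = list())
}

#' @export
print.hox_sim <- function(x, ...) {
  cat("<hox_sim> seed:", x$config$seed, "\n")
  cat("  scaffolds:", nrow(x$genome), " total nt:", sum(nchar(x$genome$seq)), "\n")
  cat("  implants:", sum(x$manifest$type == "hox"),
      " decoys:", sum(x$manifest$type == "decoy"),
      " miRNAs:", sum(x$manifest$type == "mirna"), "\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits `genome.fasta`, `truth.gff3` and `manifest.tsv` under `dir`.
#'
#' @param sim A `hox_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_gff3(sim$truth, file.path(dir, "truth.gff3"))
  readr::write_tsv(sim$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Convenience config: one scaffold with a co-located implant cluster
#'
#' Places one implant per requested group at regular spacing inside a window
#' of the scaffold, plus decoys — the standard end-to-end recovery substrate.
#'
#' @param seed Integer seed.
#' @param groups Orthology groups to implant, in placement order.
#' @param divergence Amino-acid divergence of every implant.
#' @param scaffold_len Scaffold length (default 1 Mb).
#' @param cluster_start Start of the implant window (default 30% of the
#'   scaffold; 300 kb on the default 1 Mb scaffold).
#' @param spacing Distance between implant starts (default 6% of the
#'   scaffold; 60 kb on the default scaffold, keeping four implants within a
#'   250 kb window).
#' @param n_decoys Decoy count.
#' @param strands Optional strand per implant (default alternating).
#' @return A [sim_config()].
#' @export
sim_cluster_config <- function(seed, groups = c("HOX1", "HOX3", "HOX4", "HOX6-8_ftz"),
                               divergence = 0.05, scaffold_len = 1e6,
                               cluster_start = round(0.3 * scaffold_len),
                               spacing = round(0.06 * scaffold_len),
                               n_decoys = 10L, strands = NULL) {
  n <- length(groups)
  if (is.null(strands)) strands <- rep(c("+", "-"), length.out = n)
  sim_config(
    seed = seed, n_scaffolds = 1L, scaffold_len = scaffold_len,
    implants = tibble(
      group = groups, scaffold = "scaffold_1",
      nt_start = as.integer(cluster_start + spacing * (seq_len(n) - 1L)),
      strand = strands, aa_divergence = divergence
    ),
    n_decoys = n_decoys
  )
}

#' Simulate a presence/absence matrix from gain/loss scenarios
#'
#' Replays per-group single-gain scenarios down a rooted tree
#' ([replay_events()]) to produce leaf presence states with tree-consistent
#' loss patterns.
#'
#' @param tree Rooted `phylo`.
#' @param scenarios Tibble with columns `group`, `gain_node` (node number or
#'   label; `NA` = absent everywhere), `loss_nodes` (list-column of node
#'   numbers/labels).
#' @return Tibble with `species` plus one 0/1 column per scenario group.
#' @export
simulate_presence_matrix <- function(tree, scenarios) {
  check_group(scenarios$group)
  cols <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    replay_events(tree, scenarios$gain_node[[i]], scenarios$loss_nodes[[i]])
  })
  out <- tibble(species = tree$tip.label)
  for (i in seq_len(nrow(scenarios))) out[[scenarios$group[i]]] <- unname(cols[[i]])
  out
}

#' Draw a random single-gain / multi-loss scenario on a tree
#'
#' Picks a random gain node and up to `max_losses` random loss nodes strictly
#' below it (losses may be nested, in which case fewer effective losses are
#' recoverable — the Dollo reconstruction reports the maximal all-absent
#' subtrees, never more events than simulated).
#'
#' @param tree Rooted `phylo`.
#' @param seed Integer seed.
#' @param max_losses Maximum number of loss edges drawn.
#' @return List with `gain_node`, `loss_nodes`.
#' @export
random_scenario <- function(tree, seed, max_losses = 3L) {
  withr::with_seed(seed, {
    ntip <- ape::Ntip(tree)
    n_nodes <- ntip + tree$Nnode
    gain <- sample.int(n_nodes, 1)
    kids <- tree_children(tree)
    below <- setdiff(desc_nodes(tree, kids, gain), gain)
    n_loss <- if (length(below) == 0) 0L else sample.int(min(max_losses, length(below)) + 1L, 1) - 1L
    losses <- if (n_loss > 0) sample(below, n_loss) else integer(0)
    list(gain_node = gain, loss_nodes = losses)
  })
}
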