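# Shared fixtures, built once per test run.

uniform_q <- stats::setNames(rep(0.05, 20), hoxr:::AA20)

# standard synthetic reference and calibrated profiles
ref_aln <- synthetic_reference_alignment(seed = 42)
std_profiles <- build_profiles(ref_aln, seed = 1)

# a small labelled alignment for closed-form profile tests
tiny_alignment <- function(rows, group = "HOX1") {
  tibble::tibble(group = group,
                 member_id = paste0("m", seq_along(rows)),
                 aa_row = rows)
}

# build a locus tibble by hand (bypassing the scanner) for classifier and
# cluster tests
make_loci <- function(scaffold, start, group, strand = "+", score = 50,
                      margin = Inf, status = "assigned", len = 180L,
                      group_scores = NULL) {
  n <- max(length(scaffold), length(start), length(group))
  scaffold <- rep_len(scaffold, n); start <- rep_len(as.integer(start), n)
  group <- rep_len(group, n); strand <- rep_len(strand, n)
  score <- rep_len(score, n); margin <- rep_len(margin, n)
  status <- rep_len(status, n)
  gs <- if (is.null(group_scores)) {
    purrr::map2(group, score, ~ stats::setNames(.y, .x))
  } else {
    group_scores
  }
  tibble::tibble(
    locus_id = paste0(scaffold, ":", start, "-", start + len, "(", strand, ")"),
    scaffold = scaffold, nt_start = start, nt_end = start + len,
    strand = strand, best_group = group, score = score, margin = margin,
    evalue = 1e-10, status = status, coord_space = "nt", group_scores = gs
  )
}

# independent single-codon translation oracle (direct genetic-code lookup)
codon_aa <- function(codon) {
  if (grepl("N", codon)) return("X")
  unname(Biostrings::GENETIC_CODE[codon])
}

random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

random_aa <- function(n, seed) {
  withr::with_seed(seed,
    paste0(sample(hoxr:::AA20, n, replace = TRUE), collapse = ""))
}

# exhaustive-window cluster-detection oracle: enumerate every contiguous
# window of the position-sorted loci, select by (max size, min span, leftmost
# start), remove, repeat
oracle_clusters <- function(loci, min_genes = 4L, max_span = 300000L) {
  loci <- loci[loci$status %in% "assigned", ]
  res <- list()
  for (sc in unique(loci$scaffold)) {
    pool <- loci[loci$scaffold == sc, ]
    pool <- pool[order(pool$nt_start, pool$nt_end), ]
    repeat {
      n <- nrow(pool)
      cands <- list()
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j < i) next
        size <- j - i + 1L
        if (size < min_genes) next
        span <- max(pool$nt_end[i:j]) - pool$nt_start[i]
        if (span <= max_span) cands[[length(cands) + 1]] <- c(i, j, size, span)
      }
      if (length(cands) == 0) break
      cm <- do.call(rbind, cands)
      cm <- cm[order(-cm[, 3], cm[, 4], pool$nt_start[cm[, 1]]), , drop = FALSE]
      pick <- cm[1, ]
      res[[length(res) + 1]] <- pool[pick[1]:pick[2], ]
      pool <- pool[-(pick[1]:pick[2]), ]
    }
  }
  res
}

# exhaustive single-gain Dollo oracle: try every gain node whose clade
# contains all present leaves; for each, search subsets of all-absent nodes
# below the gain for the smallest exact cover of the absent leaves; return
# the minimum loss count over feasible gains (NA when no leaf is present)
oracle_dollo_losses <- function(tree, presence) {
  ntip <- ape::Ntip(tree)
  state <- as.integer(presence[tree$tip.label] > 0)
  if (sum(state) == 0) return(0L)
  kids <- hoxr:::tree_children(tree)
  n_nodes <- ntip + tree$Nnode
  tips_under <- lapply(seq_len(n_nodes), function(v) {
    nd <- hoxr:::desc_nodes(tree, kids, v)
    nd[nd <= ntip]
  })
  present <- which(state == 1L)
  best <- Inf
  for (g in seq_len(n_nodes)) {
    if (!all(present %in% tips_under[[g]])) next
    clade_tips <- tips_under[[g]]
    absent <- setdiff(clade_tips, present)
    if (length(absent) == 0) { best <- min(best, 0L); next }
    below <- setdiff(hoxr:::desc_nodes(tree, kids, g), g)
    cands <- below[vapply(below, function(v) {
      all(state[tips_under[[v]]] == 0L)
    }, logical(1))]
    found <- NA
    for (k in seq_len(min(length(cands), length(absent)))) {
      combs <- utils::combn(cands, k, simplify = FALSE)
      for (cc in combs) {
        covered <- sort(unique(unlist(tips_under[cc])))
        if (identical(covered, sort(absent))) { found <- k; break }
      }
      if (!is.na(found)) break
    }
    if (!is.na(found)) best <- min(best, found)
  }
  as.integer(best)
}
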