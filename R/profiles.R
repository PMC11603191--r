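#' Read a labelled homeodomain reference alignment
#'
#' The reference alignment is an amino-acid FASTA in which every record
#' description carries a `group=<name>` tag naming the record's Hox orthology
#' group (see [hox_groups()]). All rows must have equal (gapped) length. This
#' emulates a curated ingroup/outgroup homeodomain set such as the C. elegans
#' plus amphioxus collection used to seed Hox searches.
#'
#' @param path Path to the aligned amino-acid FASTA.
#' @return Tibble with columns `group`, `member_id`, `aa_row`.
#' @export
read_reference_alignment <- function(path) {
  recs <- read_fasta(path, alphabet = "aa")
  m <- stringr::str_match(recs$desc, "group=([^\\s]+)")
  if (any(is.na(m[, 2]))) {
    abort(paste0("record(s) without a group= tag: ",
                 paste(recs$id[is.na(m[, 2])], collapse = ", ")))
  }
  check_group(m[, 2])
  widths <- nchar(recs$seq)
  if (length(unique(widths)) != 1) {
    abort("alignment rows have unequal lengths; the reference must be aligned")
  }
  tibble(group = m[, 2], member_id = recs$id, aa_row = recs$seq)
}

#' Pooled background residue frequencies of an alignment
#'
#' Residue composition over all rows of a labelled alignment (gaps, `X` and
#' `*` excluded), Laplace-smoothed so no residue has zero background
#' probability. This is the default null model for log-odds and E-value
#' calibration: self-contained, with no external frequency table.
#'
#' @param alignment Tibble with an `aa_row` column (see
#'   [read_reference_alignment()]).
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
pooled_background <- function(alignment) {
  chars <- unlist(strsplit(alignment$aa_row, "", fixed = TRUE))
  counts <- table(factor(chars[chars %in% AA20], levels = AA20))
  q <- (as.numeric(counts) + 1) / (sum(counts) + 20)
  setNames(q, AA20)
}

#' Build an uncalibrated log-odds profile for one orthology group
#'
#' Columns whose gap fraction is at least `gap_max` are dropped. For retained
#' column `i` and residue `a`, the probability model is
#' `p_i(a) = (n_i(a) + alpha * q(a)) / (N_i + alpha)` where `n_i(a)` is the
#' residue count and `N_i` the non-gap count in the column, and the matrix
#' entry is `M[a, i] = log2(p_i(a) / q(a))` in bits. Residues `X`/`*` are
#' excluded from counts.
#'
#' @param alignment Labelled alignment tibble; if `group` is given, rows are
#'   filtered to that group, otherwise all rows are used.
#' @param group Orthology group name the profile represents.
#' @param q Background residue frequencies (named over the 20 residues).
#'   Default: pooled composition of `alignment` (pass a pooled background
#'   explicitly when building one profile per group so all groups share q).
#' @param alpha Pseudocount weight (> 0 mixes `alpha * q` into each column;
#'   values approaching 0 give pure empirical frequencies).
#' @param gap_max Columns with gap fraction >= `gap_max` are dropped.
#' @return An object of class `hox_profile`.
#' @export
build_profile <- function(alignment, group = NULL, q = NULL, alpha = 1,
                          gap_max = 0.5) {
  if (!is.null(group)) {
    check_group(group)
    alignment <- filter(alignment, .data$group == !!group)
  } else {
    group <- unique(alignment$group)
    if (length(group) != 1) abort("build_profile: alignment spans multiple groups; pass `group`")
  }
  if (nrow(alignment) == 0) abort("build_profile: empty alignment")
  if (alpha < 0) abort("build_profile: alpha must be >= 0")
  if (gap_max < 0 || gap_max >= 1) abort("build_profile: gap_max must be in [0, 1)")
  if (is.null(q)) q <- pooled_background(alignment)
  q <- q[AA20]
  if (any(is.na(q)) || abs(sum(q) - 1) > 1e-6) {
    abort("build_profile: q must be a named distribution over the 20 residues")
  }

  mat <- do.call(rbind, strsplit(alignment$aa_row, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  # gap_max = 0 keeps only fully ungapped columns (a literal ">= 0" drop
  # would discard everything)
  kept <- if (gap_max == 0) which(gap_frac == 0) else which(gap_frac < gap_max)
  if (length(kept) == 0) abort("build_profile: all columns dropped by gap filter")
  mat <- mat[, kept, drop = FALSE]

  counts <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(match(mat[, j], AA20), nbins = 20)
  }, numeric(20))
  counts <- matrix(counts, nrow = 20, dimnames = list(AA20, NULL))
  nongap <- colSums(!(mat == "-" | mat == "."))

  prof <- structure(list(
    group = group, L = length(kept), kept_cols = kept,
    counts = counts, nongap = nongap, q = q, alpha = alpha,
    gap_max = gap_max, n_rows = nrow(alignment),
    M = NULL, calib = NULL, threshold_E = 1e-5
  ), class = "hox_profile")
  recompute_matrix(prof)
}

# Rebuild the log-odds matrix from stored counts; called after build and
# after augmentation.
recompute_matrix <- function(profile) {
  q <- profile$q
  denom <- matrix(rep(profile$nongap + profile$alpha, each = 20), nrow = 20)
  p <- (profile$counts + profile$alpha * q) / denom
  if (profile$alpha == 0) {
    # pure empirical frequencies; log2(0) columns become -Inf by design
    p <- sweep(profile$counts, 2, pmax(profile$nongap, 1), "/")
  }
  profile$M <- log2(p / q)
  profile$p <- p
  profile
}

#' Calibrate a profile's E-value statistics against a residue null model
#'
#' Draws `n_windows` i.i.d. windows of length `L` from `null_model`, scores
#' them, and fits a Gumbel distribution to the null score sample by method of
#' moments (`lambda = sd * sqrt(6) / pi`, `mu = mean - gamma * lambda`). The
#' E-value of a score `S` over `m` scanned windows is then
#' `E(S, m) = m * (1 - GumbelCDF(S))`. Deterministic given `seed`.
#'
#' @param profile A `hox_profile`.
#' @param null_model Residue distribution to sample from (default: the
#'   profile's background `q`).
#' @param n_windows Null sample size (>= 1000).
#' @param seed Integer seed for the null draw.
#' @param threshold_E Default E-value cutoff stored on the profile.
#' @return The profile with `calib = list(mu, lambda, n_windows, seed)` set.
#' @export
calibrate_profile <- function(profile, null_model = NULL, n_windows = 10000L,
                              seed = 1L, threshold_E = profile$threshold_E) {
  stopifnot(inherits(profile, "hox_profile"))
  if (n_windows < 1000) abort("calibrate_profile: n_windows must be >= 1000")
  if (is.null(null_model)) null_model <- profile$q
  null_model <- null_model[AA20]
  if (any(is.na(null_model)) || any(null_model < 0) || sum(null_model) <= 0) {
    abort("calibrate_profile: null_model must be a distribution over the 20 residues")
  }
  idx <- withr::with_seed(seed, {
    matrix(sample.int(20L, n_windows * profile$L, replace = TRUE,
                      prob = null_model),
           nrow = n_windows)
  })
  scores <- score_window_matrix_cpp(idx, profile$M)
  if (!all(is.finite(scores))) scores <- scores[is.finite(scores)]
  s <- sd(scores)
  if (!is.finite(s) || s == 0) abort("calibrate_profile: degenerate null score distribution")
  lambda <- s * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * lambda
  profile$calib <- list(mu = mu, lambda = lambda,
                        n_windows = as.integer(n_windows),
                        seed = as.integer(seed))
  profile$threshold_E <- threshold_E
  profile
}

#' E-value of a window score
#'
#' @param profile A calibrated `hox_profile`.
#' @param score Score(s) in bits.
#' @param m Number of windows scanned (the search space size).
#' @return E-value(s): expected number of null windows at or above `score`
#'   among `m` scanned.
#' @export
profile_evalue <- function(profile, score, m) {
  if (is.null(profile$calib)) abort("profile is not calibrated; run calibrate_profile()")
  z <- (score - profile$calib$mu) / profile$calib$lambda
  p_upper <- -expm1(-exp(-z))  # 1 - exp(-exp(-z)), numerically stable
  p_upper[score == -Inf] <- 1
  m * p_upper
}

# Invert the E-value at a threshold into a score cutoff: E(S, m) <= t
# iff S >= cutoff. Used so a scan evaluates exp() only on candidate hits.
score_cutoff <- function(profile, threshold_E, m) {
  if (is.null(profile$calib)) abort("profile is not calibrated; run calibrate_profile()")
  p <- threshold_E / m
  if (p >= 1) return(-Inf)
  profile$calib$mu - profile$calib$lambda * log(-log1p(-p))
}

#' Score one amino-acid window against a profile
#'
#' Sum over columns of the log-odds entries. `X` contributes 0 bits; a stop
#' (`*`) anywhere gives `-Inf` (the window is never reportable).
#'
#' @param profile A `hox_profile`.
#' @param window Amino-acid string of length `profile$L`.
#' @return Score in bits.
#' @export
score_window <- function(profile, window) {
  stopifnot(inherits(profile, "hox_profile"))
  if (nchar(window) != profile$L) {
    abort(paste0("window length ", nchar(window), " != profile length ", profile$L))
  }
  code <- aa_encode(str_chars(toupper(window)))
  if (any(code == 22L)) return(-Inf)
  keep <- code <= 20L
  sum(profile$M[cbind(code[keep], which(keep))])
}

#' Score every sliding window of a sequence against a profile
#'
#' @param profile A `hox_profile`.
#' @param aa_seq Amino-acid string (may contain `X` and `*`).
#' @return Numeric vector of length `nchar(aa_seq) - L + 1` (empty if the
#'   sequence is shorter than `L`); windows containing `*` score `-Inf`.
#' @export
score_windows <- function(profile, aa_seq) {
  stopifnot(inherits(profile, "hox_profile"))
  code <- aa_encode_str(toupper(aa_seq))
  score_windows_cpp(code, profile$M)
}

#' Consensus window of a profile
#'
#' Per-column argmax of the log-odds matrix. Because window scores are
#' column-separable, the consensus achieves the maximum score over all
#' possible windows.
#'
#' @param profile A `hox_profile`.
#' @return Amino-acid string of length `L`.
#' @export
consensus_window <- function(profile) {
  paste0(AA20[apply(profile$M, 2, which.max)], collapse = "")
}

#' Augment a profile with newly accepted members
#'
#' Adds fixed-length, ungapped windows (round-1 search hits) to the profile's
#' counts at the given weight, recomputes the log-odds matrix, and (by
#' default) re-runs calibration with the profile's stored calibration seed so
#' augmented searches stay deterministic. This implements the second-round
#' strategy in which first-round hits enrich the search profile.
#'
#' @param profile A `hox_profile`.
#' @param new_members Character vector of amino-acid windows of length `L`
#'   (no gaps).
#' @param weight Count increment per member.
#' @param recalibrate Re-run [calibrate_profile()] with the stored seed.
#' @return The augmented `hox_profile`.
#' @export
augment_profile <- function(profile, new_members, weight = 1,
                            recalibrate = TRUE) {
  stopifnot(inherits(profile, "hox_profile"))
  if (length(new_members) > 0) {
    bad <- nchar(new_members) != profile$L
    if (any(bad)) {
      abort(paste0("augment_profile: member length ", nchar(new_members[bad][1]),
                   " != profile length ", profile$L))
    }
    if (any(grepl("[-.]", new_members))) abort("augment_profile: members must be ungapped")
    for (w in new_members) {
      code <- aa_encode(str_chars(toupper(w)))
      keep <- which(code <= 20L)
      profile$counts[cbind(code[keep], keep)] <-
        profile$counts[cbind(code[keep], keep)] + weight
      profile$nongap[keep] <- profile$nongap[keep] + weight
    }
    profile$n_rows <- profile$n_rows + length(new_members) * (weight > 0)
    profile <- recompute_matrix(profile)
  }
  if (recalibrate && !is.null(profile$calib)) {
    profile <- calibrate_profile(profile, n_windows = profile$calib$n_windows,
                                 seed = profile$calib$seed,
                                 threshold_E = profile$threshold_E)
  }
  profile
}

#' Build calibrated profiles for every group in a labelled alignment
#'
#' Builds one profile per orthology group present in the alignment, sharing a
#' pooled background distribution, and calibrates each. All profiles must end
#' up with the same window length `L` (use an alignment trimmed to the
#' homeodomain core).
#'
#' @inheritParams build_profile
#' @inheritParams calibrate_profile
#' @param alignment Labelled alignment tibble covering one or more groups.
#' @return Named list of `hox_profile` objects.
#' @export
build_profiles <- function(alignment, q = NULL, alpha = 1, gap_max = 0.5,
                           n_windows = 10000L, seed = 1L, threshold_E = 1e-5) {
  if (is.null(q)) q <- pooled_background(alignment)
  groups <- intersect(hox_groups(), unique(alignment$group))
  profs <- purrr::map(groups, function(g) {
    calibrate_profile(
      build_profile(alignment, group = g, q = q, alpha = alpha, gap_max = gap_max),
      n_windows = n_windows, seed = seed, threshold_E = threshold_E
    )
  })
  names(profs) <- groups
  Ls <- vapply(profs, function(p) p$L, integer(1))
  if (length(unique(Ls)) > 1) {
    warn(paste0("profiles have differing window lengths after gap filtering: ",
                paste(unique(Ls), collapse = ", ")))
  }
  profs
}

#' @export
print.hox_profile <- function(x, ...) {
  cat("<hox_profile> group:", x$group, " L:", x$L,
      " members:", x$n_rows, " alpha:", x$alpha, "\n")
  if (!is.null(x$calib)) {
    cat("  calibration: Gumbel mu =", signif(x$calib$mu, 5),
        "lambda =", signif(x$calib$lambda, 5),
        "(n =", x$calib$n_windows, ") threshold_E =", x$threshold_E, "\n")
  } else {
    cat("  uncalibrated\n")
  }
  invisible(x)
}

#' Serialise a profile to a structured text file
#'
#' Versioned plain-text schema: header key-value lines followed by the
#' log-odds matrix row-major at 6-decimal fixed precision. Read back with
#' [read_profile()]; counts are stored too so augmentation survives a round
#' trip.
#'
#' @param profile A `hox_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "wt"); on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("#hoxr_profile\tv1")
  wl("group\t", profile$group)
  wl("L\t", profile$L)
  wl("alpha\t", format(profile$alpha, digits = 12))
  wl("gap_max\t", format(profile$gap_max, digits = 12))
  wl("n_rows\t", profile$n_rows)
  wl("threshold_E\t", format(profile$threshold_E, digits = 12))
  wl("q\t", paste(sprintf("%.8f", profile$q), collapse = ","))
  wl("nongap\t", paste(format(profile$nongap, digits = 12), collapse = ","))
  if (!is.null(profile$calib)) {
    wl("calib\t", sprintf("%.8f,%.8f,%d,%d", profile$calib$mu,
                          profile$calib$lambda, profile$calib$n_windows,
                          profile$calib$seed))
  }
  wl("counts")
  for (i in 1:20) wl(AA20[i], "\t", paste(format(profile$counts[i, ], digits = 12), collapse = ","))
  wl("M")
  for (i in 1:20) wl(AA20[i], "\t", paste(sprintf("%.6f", profile$M[i, ]), collapse = ","))
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Path to a profile text file.
#' @return A `hox_profile`. The log-odds matrix is recomputed from the stored
#'   counts (exact), so the 6-decimal serialised matrix is informative only.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#hoxr_profile")) abort("not a hoxr profile file")
  kv <- function(key) {
    ln <- grep(paste0("^", key, "\t"), lines, value = TRUE)[1]
    if (is.na(ln)) return(NULL)
    sub(paste0("^", key, "\t"), "", ln)
  }
  counts_at <- which(lines == "counts")
  counts <- t(vapply(lines[(counts_at + 1):(counts_at + 20)], function(ln) {
    as.numeric(strsplit(sub("^[A-Z]\t", "", ln), ",")[[1]])
  }, numeric(as.integer(kv("L")))))
  rownames(counts) <- AA20
  prof <- structure(list(
    group = kv("group"), L = as.integer(kv("L")), kept_cols = NA,
    counts = counts,
    nongap = as.numeric(strsplit(kv("nongap"), ",")[[1]]),
    q = setNames(as.numeric(strsplit(kv("q"), ",")[[1]]), AA20),
    alpha = as.numeric(kv("alpha")),
    gap_max = as.numeric(kv("gap_max")),
    n_rows = as.numeric(kv("n_rows")),
    M = NULL, calib = NULL,
    threshold_E = as.numeric(kv("threshold_E"))
  ), class = "hox_profile")
  cal <- kv("calib")
  if (!is.null(cal)) {
    v <- as.numeric(strsplit(cal, ",")[[1]])
    prof$calib <- list(mu = v[1], lambda = v[2], n_windows = as.integer(v[3]),
                       seed = as.integer(v[4]))
  }
  recompute_matrix(prof)
}
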