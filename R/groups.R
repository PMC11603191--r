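#' Hox orthology groups
#'
#' The nine orthology groups recognised by the pipeline. The three HOX6-8
#' subtypes (ftz-like, Antp-like, Ubx/AbdA-like) are distinct groups for
#' profile building and classification but share a single canonical rank for
#' collinearity, reflecting their common origin from the central part of the
#' ancestral cluster.
#'
#' @return Character vector of the nine group names, in canonical order.
#' @examples
#' hox_groups()
#' @export
hox_groups <- function() {
  c("HOX1", "HOX2", "HOX3", "HOX4", "HOX5",
    "HOX6-8_ftz", "HOX6-8_Antp", "HOX6-8_UbxAbdA", "HOX9-13")
}

#' Canonical anterior-posterior rank of an orthology group
#'
#' HOX1 through HOX5 take ranks 1-5, the three HOX6-8 subtypes share rank 6,
#' and HOX9-13 takes rank 7. Used by [collinearity()] to compare genomic gene
#' order against the canonical cluster order.
#'
#' @param group Character vector of group names (see [hox_groups()]).
#' @return Integer vector of ranks.
#' @examples
#' hox_rank(c("HOX1", "HOX6-8_Antp", "HOX9-13"))
#' @export
hox_rank <- function(group) {
  check_group(group)
  ranks <- c(
    "HOX1" = 1L, "HOX2" = 2L, "HOX3" = 3L, "HOX4" = 4L, "HOX5" = 5L,
    "HOX6-8_ftz" = 6L, "HOX6-8_Antp" = 6L, "HOX6-8_UbxAbdA" = 6L,
    "HOX9-13" = 7L
  )
  unname(ranks[group])
}

check_group <- function(group) {
  bad <- setdiff(unique(group), hox_groups())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown orthology group(s): ", paste(bad, collapse = ", "),
      ". Valid groups: ", paste(hox_groups(), collapse = ", ")
    ))
  }
  invisible(group)
}

# Standard 20-residue alphabet in fixed order; row order of every profile
# matrix in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Integer encoding shared with the C++ scanner: 1..20 residues, 21 = X
# (neutral), 22 = * (stop; poisons a window). Gaps and anything else map
# to 21 so they score 0 but never match.
AA_LUT <- local({
  lut <- rep(21L, 127)
  lut[vapply(AA20, utf8ToInt, integer(1))] <- seq_len(20L)
  lut[utf8ToInt("*")] <- 22L
  lut
})

aa_encode <- function(aa_chars) {
  AA_LUT[vapply(aa_chars, utf8ToInt, integer(1))]
}

# whole-string variant (hot path of the scanner)
aa_encode_str <- function(aa_seq) {
  AA_LUT[utf8ToInt(aa_seq)]
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
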