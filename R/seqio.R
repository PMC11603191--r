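#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that validates the
#' declared alphabet, normalises sequences to upper case, and returns one row
#' per record. Multi-line sequences are concatenated and record order is
#' preserved.
#'
#' Nucleotide files may contain `A C G T N` only: IUPAC ambiguity codes other
#' than `N` are rejected so the downstream scanner's alphabet stays closed.
#' Amino-acid files may contain the 20 standard residues plus `X`, `*` and the
#' gap characters `-`/`.` (gaps occur in reference alignments only).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a some gene", "ACGT", ">b", "TT"), tf)
#' read_fasta(tf, "nt")
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("No FASTA records in ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id ", dup[1], " in ", path))
  }
  seqs <- toupper(as.character(set))
  ok <- if (alphabet == "nt") "^[ACGTN]*$" else "^[ACDEFGHIKLMNPQRSTVWYX*.-]*$"
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) abort(paste0("empty sequence for id ", ids[i]))
    if (!grepl(ok, seqs[i])) {
      pos <- regexpr(if (alphabet == "nt") "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWYX*.-]",
                     seqs[i])
      abort(paste0(
        "illegal ", if (alphabet == "nt") "nucleotide" else "amino-acid",
        " residue '", substr(seqs[i], pos, pos), "' at position ", pos,
        " in record ", ids[i]
      ))
    }
  }
  tibble(id = unname(ids), desc = unname(descs), seq = unname(seqs))
}

#' Write a tibble of sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene-level features from a GFF3 file
#'
#' Parses with [rtracklayer::import()] and converts the 1-based inclusive GFF
#' coordinates to the package's internal 0-based half-open convention. Only
#' `gene` and miRNA features are retained; other feature kinds are skipped
#' with a message reporting the count.
#'
#' @param path Path to a GFF3 file.
#' @param quiet Suppress the skipped-feature message.
#' @return Tibble with columns `feature_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `kind` (`"gene"` or `"mirna"`), and an
#'   `attributes` list-column of the remaining GFF attributes.
#' @export
read_gff3 <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  # Pre-validate coordinates so a malformed line is reported by line number
  # (GRanges would reject negative widths with an opaque message).
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  for (ln in body) {
    f <- strsplit(raw[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && s > e) {
        abort(paste0("GFF3 start > end at line ", ln, " of ", path))
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gr$type))
  kind <- ifelse(type == "gene", "gene",
                 ifelse(type %in% c("mirna", "mirna_gene", "pre_mirna"), "mirna", NA))
  skipped <- sum(is.na(kind))
  if (skipped > 0 && !quiet) {
    inform(paste0("read_gff3: skipped ", skipped,
                  " feature(s) of kinds other than gene/miRNA"))
  }
  keep <- which(!is.na(kind))
  gr <- gr[keep]
  kind <- kind[keep]
  if (length(gr) == 0) {
    return(tibble(
      feature_id = character(), scaffold = character(),
      start = integer(), end = integer(), strand = character(),
      kind = character(), attributes = list()
    ))
  }
  ids <- as.character(gr$ID)
  if (all(is.na(ids))) ids <- paste0("feature_", seq_along(gr))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("read_gff3: retained features must have strand '+' or '-'")
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  drop_cols <- intersect(c("type", "ID", "source", "phase", "score"), names(mc))
  mc <- mc[, setdiff(names(mc), drop_cols), drop = FALSE]
  attrs <- lapply(seq_len(nrow(mc)), function(i) {
    row <- as.list(mc[i, , drop = FALSE])
    row[!vapply(row, function(v) all(is.na(unlist(v))), logical(1))]
  })
  tibble(
    feature_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    kind = kind,
    attributes = attrs
  )
}

#' Write gene-level features to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates become
#' 1-based inclusive, `kind = "mirna"` becomes type `miRNA`, and any extra
#' scalar columns (e.g. `group`, `score`, `margin`, `status`) are written as
#' GFF attributes.
#'
#' @param features Tibble as returned by [read_gff3()] (the `attributes`
#'   list-column is optional).
#' @param path Output path.
#' @param source Value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "hoxr") {
  req <- c("feature_id", "scaffold", "start", "end", "strand", "kind")
  stopifnot(all(req %in% names(features)))
  gr <- GenomicRanges::GRanges(
    seqnames = features$scaffold,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  gr$source <- source
  gr$type <- ifelse(features$kind == "mirna", "miRNA", "gene")
  gr$ID <- features$feature_id
  extra <- setdiff(names(features), c(req, "attributes"))
  for (col in extra) {
    v <- features[[col]]
    if (is.atomic(v)) S4Vectors::mcols(gr)[[col]] <- as.character(v)
  }
  if ("attributes" %in% names(features)) {
    keys <- unique(unlist(lapply(features$attributes, names)))
    for (key in setdiff(keys, c(req, extra))) {
      S4Vectors::mcols(gr)[[key]] <- vapply(
        features$attributes,
        function(a) if (is.null(a[[key]])) NA_character_ else as.character(a[[key]]),
        character(1)
      )
    }
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Single nucleotide string (`A C G T N`).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Six-frame conceptual translation
#'
#' Translates a nucleotide sequence in all three reading frames on both
#' strands under the standard genetic code. Codons containing `N` translate
#' to `X`; stop codons are kept as `*` in the translation (downstream window
#' scoring rejects windows containing a stop); trailing partial codons are
#' dropped.
#'
#' @param seq Single nucleotide string.
#' @param id Optional scaffold id carried through to the output.
#' @return Tibble with one row per frame: `scaffold`, `frame_id` (`"+1"` ...
#'   `"-3"`), `strand`, `offset` (0-based nt offset of the frame's first codon
#'   on its own strand), `aa_seq`, `seq_len` (source length). Use
#'   [frame_nt_window()] to map amino-acid indices back to forward-strand
#'   scaffold coordinates.
#' @examples
#' six_frame_translate("ATGAAA")
#' @export
six_frame_translate <- function(seq, id = "seq") {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) abort("six_frame_translate: alphabet must be A/C/G/T/N")
  L <- nchar(seq)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(strand_seq, f) {
    n_codon <- (length(strand_seq) - (f - 1L)) %/% 3L
    if (n_codon < 1) return("")
    sub <- Biostrings::subseq(strand_seq, start = f, width = 3L * n_codon)
    as.character(suppressWarnings(
      Biostrings::translate(sub, if.fuzzy.codon = "X")
    ))
  }
  rows <- purrr::map(1:3, function(f) {
    tibble(
      scaffold = id,
      frame_id = c(paste0("+", f), paste0("-", f)),
      strand = c("+", "-"),
      offset = f - 1L,
      aa_seq = c(one(fwd, f), one(rev, f)),
      seq_len = L
    )
  })
  bind_rows(rows) |> arrange(dplyr::desc(.data$strand), .data$offset)
}

#' Map a frame-local amino-acid window to forward-strand nt coordinates
#'
#' For a window of `n_aa` residues starting at 1-based amino-acid index
#' `aa_start` within the translation of frame `frame_id` of a scaffold of
#' length `seq_len`, returns the 0-based half-open nucleotide interval on the
#' forward strand of the scaffold. Minus-frame windows are mapped through the
#' reverse complement so intervals always refer to the forward coordinate
#' system.
#'
#' @param frame_id One of `"+1" "+2" "+3" "-1" "-2" "-3"` (vectorised).
#' @param aa_start 1-based amino-acid start index (vectorised).
#' @param n_aa Window length in residues.
#' @param seq_len Scaffold length in nt.
#' @return Tibble with columns `nt_start`, `nt_end`, `strand`.
#' @export
frame_nt_window <- function(frame_id, aa_start, n_aa, seq_len) {
  n <- max(length(frame_id), length(aa_start))
  frame_id <- rep_len(frame_id, n)
  aa_start <- rep_len(aa_start, n)
  f <- as.integer(substr(frame_id, 2, 2))
  strand <- substr(frame_id, 1, 1)
  local_start <- (f - 1L) + 3L * (aa_start - 1L)  # 0-based on own strand
  local_end <- local_start + 3L * n_aa
  plus <- strand == "+"
  nt_start <- ifelse(plus, local_start, seq_len - local_end)
  nt_end <- ifelse(plus, local_end, seq_len - local_start)
  tibble(nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
         strand = strand)
}

#' Read a rooted species tree in newick format
#'
#' @param path Path to a newick file containing a single tree. Branch lengths
#'   are permitted and ignored; polytomies are allowed; leaf labels must be
#'   unique.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) abort("read_newick: expected a single tree")
  if (is.null(tree)) abort(paste0("Could not parse newick in ", path))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    abort(paste0("duplicate leaf label(s): ", paste(unique(dup), collapse = ", ")))
  }
  tree
}
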