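#' Construct a repeat alignment object
#'
#' The core container: a fixed-width alignment of single repeats or of
#' concatenated consecutive-repeat pairs, with per-row metadata linking each
#' row to its parent protein.
#'
#' @param seqs character vector of equal-length sequences over
#'   [rf_alphabet()].
#' @param meta optional data.frame with columns `id`, `protein_id`,
#'   `repeat_index`, `start`, `end`; missing columns are filled with `NA`.
#' @param pair_flag logical; `TRUE` when each row is the concatenation of two
#'   consecutive repeats (width must then be even).
#' @param alphabet symbol set.
#' @return An object of class `rf_alignment` with elements `seqs`, `meta`,
#'   `L`, `pair_flag`, `alphabet`.
#' @export
rf_alignment <- function(seqs, meta = NULL, pair_flag = FALSE,
                         alphabet = rf_alphabet()) {
  rf_check(length(seqs) >= 1, "alignment has no rows")
  w <- unname(nchar(seqs))
  if (length(unique(w)) != 1) {
    off <- which(w != w[1])[1]
    id <- if (!is.null(meta) && "id" %in% names(meta)) meta$id[off] else off
    rf_abort("ragged alignment: record '%s' has width %d, expected %d",
             id, w[off], w[1])
  }
  L <- w[1]
  if (pair_flag) rf_check(L %% 2 == 0, "pair alignment width %d is odd", L)
  n <- length(seqs)
  full <- data.frame(id = paste0("seq", seq_len(n)),
                     protein_id = NA_character_,
                     repeat_index = NA_integer_,
                     start = NA_integer_, end = NA_integer_,
                     stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    rf_check(nrow(meta) == n, "metadata rows (%d) != sequence rows (%d)",
             nrow(meta), n)
    for (cl in intersect(names(full), names(meta))) full[[cl]] <- meta[[cl]]
  }
  structure(list(seqs = unname(seqs), meta = full, L = L,
                 pair_flag = pair_flag, alphabet = alphabet),
            class = "rf_alignment")
}

#' @export
print.rf_alignment <- function(x, ...) {
  cat(sprintf("rf_alignment: %d rows x %d columns (%s)\n",
              length(x$seqs), x$L,
              if (x$pair_flag) "repeat pairs" else "single repeats"))
  show <- head(seq_along(x$seqs), 5)
  for (i in show) cat(sprintf("  %-20s %s\n", x$meta$id[i], x$seqs[i]))
  if (length(x$seqs) > 5) cat(sprintf("  ... %d more\n", length(x$seqs) - 5))
  invisible(x)
}

#' @export
length.rf_alignment <- function(x) length(x$seqs)

# integer state matrix of an alignment
encode_alignment <- function(aln) encode_sequences(aln$seqs, aln$alphabet)

# subset rows, keeping metadata aligned
aln_subset <- function(aln, idx) {
  rf_alignment(aln$seqs[idx], aln$meta[idx, , drop = FALSE],
               pair_flag = aln$pair_flag, alphabet = aln$alphabet)
}

# Parse PFAM-convention headers "proteinID/start-end"; rows that do not
# match keep the whole header as protein_id with NA coordinates.
parse_headers <- function(ids) {
  first <- sub("\\s.*$", "", ids)
  m <- regmatches(first, regexec("^(.+)/([0-9]+)-([0-9]+)$", first))
  out <- data.frame(id = first, protein_id = first,
                    repeat_index = NA_integer_,
                    start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  ok <- lengths(m) == 4
  out$protein_id[ok] <- vapply(m[ok], `[`, "", 2)
  out$start[ok] <- as.integer(vapply(m[ok], `[`, "", 3))
  out$end[ok] <- as.integer(vapply(m[ok], `[`, "", 4))
  # ordinal repeat index per protein, by start coordinate
  has <- ok & !is.na(out$start)
  for (p in unique(out$protein_id[has])) {
    rows <- which(has & out$protein_id == p)
    out$repeat_index[rows][order(out$start[rows])] <- seq_along(rows) - 1L
  }
  out
}

read_stockholm_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                   nzchar(trimws(lines))]
  if (length(lines) == 0) return(list(ids = character(0), seqs = character(0)))
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*$", lines))
  bad <- which(lengths(parts) != 3)
  rf_check(length(bad) == 0, "malformed Stockholm line: '%s'", lines[bad[1]])
  ids <- vapply(parts, `[`, "", 2)
  seqs <- vapply(parts, `[`, "", 3)
  # multi-block files repeat the same ids; concatenate in order of appearance
  uid <- unique(ids)
  list(ids = uid,
       seqs = vapply(uid, function(u) paste(seqs[ids == u], collapse = ""), ""))
}

#' Read a repeat alignment from FASTA or Stockholm
#'
#' Sequences are uppercased; characters outside the 21-letter alphabet
#' (including non-standard residues B, Z, X, U, O and the `.` gap of
#' Stockholm insert columns) are mapped to the gap state, and the number of
#' substituted characters is reported in a warning.  Headers following the
#' PFAM `proteinID/start-end` convention are parsed into metadata and repeats
#' of the same protein are numbered by start coordinate.
#'
#' @param path input file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param pair_flag whether rows are already concatenated repeat pairs.
#' @return An [rf_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           pair_flag = FALSE) {
  format <- match.arg(format)
  rf_check(file.exists(path), "input file not found: %s", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) rf_abort("cannot parse FASTA %s: %s",
                                                 path, conditionMessage(e)))
    ids <- names(set)
    seqs <- as.character(set)
  } else {
    parsed <- read_stockholm_lines(path)
    ids <- parsed$ids
    seqs <- parsed$seqs
  }
  rf_check(length(seqs) > 0, "empty alignment file: %s", path)
  seqs <- toupper(seqs)
  alpha <- rf_alphabet()
  n_bad <- sum(!strsplit(paste(seqs, collapse = ""), "")[[1]] %in% alpha)
  if (n_bad > 0) {
    warning(sprintf("%d non-alphabet characters mapped to gap", n_bad))
    keep <- paste(alpha, collapse = "")
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!ch %in% alpha] <- "-"
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  rf_alignment(seqs, meta = parse_headers(ids), pair_flag = pair_flag)
}

#' Write an alignment to FASTA or Stockholm
#'
#' @param aln an [rf_alignment()].
#' @param path output file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::BStringSet(setNames(aln$seqs, aln$meta$id))
    Biostrings::writeXStringSet(set, path)
  } else {
    wid <- max(nchar(aln$meta$id))
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf(paste0("%-", wid, "s %s"), aln$meta$id, aln$seqs),
                 "//"), path)
  }
  invisible(path)
}
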