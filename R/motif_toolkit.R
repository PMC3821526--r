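# Sequence-level support: carbamylation-motif detection and construction of
# engineered connexin variants from edit specifications.  FASTA I/O is
# delegated to Biostrings.

.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X")

#' Amino-acid sequence record
#'
#' @param identifier record identifier (e.g. an accession).
#' @param residues amino-acid string (20-letter alphabet plus X), 1-based
#'   positions.
#' @return An object of class `SequenceRecord`.
#' @export
sequence_record <- function(identifier, residues) {
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) abort("empty sequence", "carbanm_parameter_error")
  chars <- strsplit(residues, "")[[1L]]
  bad <- setdiff(unique(chars), .AA_ALPHABET)
  if (length(bad)) {
    abort(paste("invalid residue letter(s):", paste(bad, collapse = ", ")),
          "carbanm_format_error")
  }
  structure(list(identifier = as.character(identifier), residues = residues),
            class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("SequenceRecord %s: %d aa\n", x$identifier, nchar(x$residues)))
  invisible(x)
}

#' Read amino-acid FASTA into SequenceRecords
#'
#' @param path FASTA file path.
#' @return Named list of `SequenceRecord`s (names are the first word of each
#'   header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("no such FASTA file:", path), "carbanm_io_error")
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) abort("FASTA file holds no records", "carbanm_empty_error")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  recs <- lapply(seq_along(set), function(i) {
    sequence_record(ids[i], as.character(set[[i]]))
  })
  stats::setNames(recs, ids)
}

#' Write SequenceRecords as FASTA
#'
#' @param records a `SequenceRecord` or list of them.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "SequenceRecord")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, `[[`, "", "identifier")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Locate the carbamylation motif in a sequence
#'
#' Exact matching; returns the 1-based position of the motif's lysine (for
#' KVREI the K is the first residue of the match) for every occurrence, or
#' an empty integer vector when absent.
#'
#' @param seq a `SequenceRecord`.
#' @param motif motif string (default `"KVREI"`).
#' @return Integer vector of lysine positions.
#' @export
find_motif <- function(seq, motif = "KVREI") {
  if (!inherits(seq, "SequenceRecord")) {
    abort("`seq` must be a SequenceRecord", "carbanm_parameter_error")
  }
  if (!nzchar(motif)) abort("`motif` must be nonempty", "carbanm_parameter_error")
  hits <- gregexpr(motif, seq$residues, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  k_off <- regexpr("K", motif, fixed = TRUE)
  offset <- if (k_off == -1L) 0L else as.integer(k_off) - 1L
  as.integer(hits) + offset
}

#' Specify a sequence edit
#'
#' Either a range replacement (`kind = "replace_range"`, possibly changing
#' the length, e.g. inserting TQKVREI in place of K123 H124) or a point
#' substitution carrying a wild-type guard (e.g. K125R: position 125 must be
#' K at application time).
#'
#' @param kind `"replace_range"` or `"point_substitution"`.
#' @param start,end 1-based inclusive positions (`end == start` for point
#'   edits).
#' @param replacement amino-acid string to insert.
#' @param label free-text label for the edit.
#' @param wt expected wild-type residue at `start` (point substitutions).
#' @return An object of class `EditSpec`.
#' @export
edit_spec <- function(kind = c("replace_range", "point_substitution"),
                      start, end = start, replacement, label = "", wt = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    abort("need 1 <= start <= end", "carbanm_bounds_error")
  }
  if (kind == "point_substitution" && end != start) {
    abort("point substitutions have end == start", "carbanm_parameter_error")
  }
  if (!nzchar(replacement)) {
    abort("`replacement` must be nonempty", "carbanm_parameter_error")
  }
  structure(list(kind = kind, start = start, end = end,
                 replacement = toupper(replacement), label = label,
                 wt = if (!is.null(wt)) toupper(wt)),
            class = "EditSpec")
}

#' Parse a point-mutation label such as "K125R"
#'
#' @param label `<wild-type residue><position><new residue>`, e.g. `"K125E"`
#'   or `"R104A"`.
#' @return An `EditSpec` of kind `point_substitution` with the wild-type
#'   guard recorded.
#' @export
parse_mutation_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1L]]
  if (length(m) != 4L ||
      !(toupper(m[2L]) %in% .AA_ALPHABET) || !(toupper(m[4L]) %in% .AA_ALPHABET)) {
    abort(sprintf("malformed mutation label '%s' (expected e.g. K125R)", label),
          "carbanm_parse_error")
  }
  pos <- as.integer(m[3L])
  edit_spec("point_substitution", start = pos, replacement = toupper(m[4L]),
            label = toupper(label), wt = toupper(m[2L]))
}

#' Apply an edit to a sequence
#'
#' `replace_range` removes residues `start..end` and inserts the
#' replacement; `point_substitution` swaps one residue after checking the
#' wild-type guard (protecting against off-by-one numbering).  The returned
#' record carries a derived identifier (`parent_label`).
#'
#' @param seq a `SequenceRecord`.
#' @param edit an `EditSpec` (or a mutation label string, parsed with
#'   [parse_mutation_label()]).
#' @return The edited `SequenceRecord`.
#' @export
apply_edit <- function(seq, edit) {
  if (!inherits(seq, "SequenceRecord")) {
    abort("`seq` must be a SequenceRecord", "carbanm_parameter_error")
  }
  if (is.character(edit)) edit <- parse_mutation_label(edit)
  if (!inherits(edit, "EditSpec")) {
    abort("`edit` must be an EditSpec", "carbanm_parameter_error")
  }
  len <- nchar(seq$residues)
  if (edit$start > len || edit$end > len) {
    abort(sprintf("edit positions %d..%d exceed sequence length %d",
                  edit$start, edit$end, len), "carbanm_bounds_error")
  }
  if (edit$kind == "point_substitution" && !is.null(edit$wt)) {
    found <- substr(seq$residues, edit$start, edit$start)
    if (found != edit$wt) {
      abort(sprintf("wild-type mismatch for %s: position %d is %s, expected %s",
                    if (nzchar(edit$label)) edit$label else "edit",
                    edit$start, found, edit$wt),
            "carbanm_consistency_error")
    }
  }
  new_res <- paste0(substr(seq$residues, 1L, edit$start - 1L),
                    edit$replacement,
                    substr(seq$residues, edit$end + 1L, len))
  label <- if (nzchar(edit$label)) edit$label else {
    sprintf("%s%d-%d%s", edit$kind, edit$start, edit$end, edit$replacement)
  }
  sequence_record(paste(seq$identifier, label, sep = "_"), new_res)
}

#' Invert a point substitution
#'
#' Applying the result of `invert_edit` after the original edit restores the
#' parent sequence exactly (range replacements are not invertible without
#' the removed residues and are rejected).
#'
#' @param edit a point-substitution `EditSpec` with a wild-type guard.
#' @return The inverse `EditSpec`.
#' @export
invert_edit <- function(edit) {
  if (!inherits(edit, "EditSpec") || edit$kind != "point_substitution" ||
      is.null(edit$wt)) {
    abort("only point substitutions with a wild-type guard are invertible",
          "carbanm_parameter_error")
  }
  edit_spec("point_substitution", start = edit$start, replacement = edit$wt,
            label = paste0(edit$replacement, edit$start, edit$wt),
            wt = edit$replacement)
}
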