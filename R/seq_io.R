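#' Construct a coding sequence record
#'
#' A `coding_sequence` is the package's basic unit: one ORF on the element's
#' (or gene's) positive strand, with the metadata the downstream statistics
#' group by.  Sequences are stored as plain uppercase character strings over
#' the alphabet `A, C, G, T, N`.
#'
#' @param id record identifier.
#' @param sequence nucleotide string (uppercased on construction).
#' @param clade clade label, e.g. `"L1"`, `"L2"`, `"Tx1"`; defaults to
#'   `"unknown"`.
#' @param host host label, e.g. `"lizard"`; defaults to `"unknown"`.
#' @param orf_label `"ORF1"` or `"ORF2"` (or `"unknown"`).
#' @param frame_validated logical; set by [validate_orf()], `FALSE` on
#'   construction.
#' @return An object of class `coding_sequence`.
#' @seealso [read_cds_fasta()], [validate_orf()]
#' @export
coding_sequence <- function(id, sequence, clade = "unknown", host = "unknown",
                            orf_label = "unknown", frame_validated = FALSE) {
  sequence <- toupper(as.character(sequence))
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("record '", id, "' contains non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         clade = as.character(clade), host = as.character(host),
         orf_label = as.character(orf_label),
         frame_validated = isTRUE(frame_validated)),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s  [%s / %s / %s]  %d nt%s\n",
              x$id, x$clade, x$host, x$orf_label, nchar(x$sequence),
              if (x$frame_validated) "  (frame validated)" else ""))
  invisible(x)
}

.seq_chars <- function(seq) strsplit(seq$sequence, "", fixed = TRUE)[[1]]

#' Read coding sequences from a multi-FASTA file
#'
#' Headers follow the convention `>id key=value key=value ...`; recognised
#' keys are `clade`, `host` and `orf`, anything else is ignored and missing
#' keys default to `"unknown"`.  Sequences are uppercased (soft-masking
#' discarded); `N` is allowed, any other non-ACGT character is an error that
#' names the offending record.
#'
#' @param path path to a multi-FASTA file.
#' @return List of [coding_sequence()] records in file order.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  headers <- names(set)
  seqs <- toupper(as.character(set))
  lapply(seq_along(set), function(i) {
    toks <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    id <- toks[1]
    meta <- c(clade = "unknown", host = "unknown", orf = "unknown")
    for (tok in toks[-1]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2 && kv[1] %in% names(meta)) meta[kv[1]] <- kv[2]
    }
    coding_sequence(id, seqs[i], clade = meta[["clade"]],
                    host = meta[["host"]], orf_label = meta[["orf"]])
  })
}

#' Write coding sequences to a multi-FASTA file
#'
#' Inverse of [read_cds_fasta()]: metadata is serialized as `key=value`
#' tokens on the header line, so a write/read round trip reproduces ids,
#' sequences and metadata exactly.
#'
#' @param seqs list of [coding_sequence()] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0)
  headers <- vapply(seqs, function(s)
    sprintf("%s clade=%s host=%s orf=%s", s$id, s$clade, s$host, s$orf_label),
    character(1))
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "sequence"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate the reading frame of a coding sequence
#'
#' A record passes when its length is a multiple of 3 and it contains no
#' internal stop codon.  A trailing stop codon, if present, is trimmed so
#' that downstream codon statistics run on the sense-codon payload only.
#' Validation never errors; it returns the record with `frame_validated`
#' set, so batch runs can report and drop broken ORFs.
#'
#' @param seq a [coding_sequence()].
#' @return The record with `frame_validated` set (and a trailing stop
#'   removed when validation succeeded).
#' @export
validate_orf <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"), nchar(seq$sequence) > 0)
  n <- nchar(seq$sequence)
  if (n %% 3L != 0L) {
    seq$frame_validated <- FALSE
    return(seq)
  }
  codons <- substring(seq$sequence, seq(1, n, 3), seq(3, n, 3))
  is_stop <- codons %in% stop_codons()
  if (any(is_stop[-length(codons)])) {
    seq$frame_validated <- FALSE
    return(seq)
  }
  if (is_stop[length(codons)]) {
    seq$sequence <- substr(seq$sequence, 1L, n - 3L)
  }
  seq$frame_validated <- TRUE
  seq
}

#' Split a validated coding sequence into codons
#'
#' @param seq a frame-validated [coding_sequence()].
#' @return Character vector of codons in order, with a logical attribute
#'   `"flagged"` marking codons that contain `N` (these are excluded from
#'   all codon statistics downstream).
#' @export
iter_codons <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"))
  if (!seq$frame_validated)
    stop("sequence '", seq$id, "' is not frame-validated; run validate_orf()")
  n <- nchar(seq$sequence)
  if (n == 0L) return(structure(character(0), flagged = logical(0)))
  codons <- substring(seq$sequence, seq(1, n, 3), seq(3, n, 3))
  structure(codons, flagged = grepl("N", codons, fixed = TRUE))
}
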