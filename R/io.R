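# Readers and writers for the standard exchange formats the pipeline uses.

#' Read protein entries from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return `data.frame` with columns `accession` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  data.frame(accession = acc, sequence = as.character(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param accession,sequence Character vectors of equal length.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(accession, sequence, path) {
  set <- Biostrings::AAStringSet(stats::setNames(sequence, accession))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: id, description, then member identifiers, tab
#' separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; set descriptions are kept in
#'   the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop(sum(bad), " GMT line(s) with fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[`, "", 2L), names(sets))
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional per-set description column (defaults to
#'   the set names).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a digest table as TSV
#'
#' @param peptides Digest `data.frame` ([digest()]), optionally with an
#'   `accession` and `mods` column.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_digest_tsv <- function(peptides, path) {
  if (is.null(peptides$mods)) peptides$mods <- ""
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' Thin convenience wrapper with the conventions used by the package's
#' writers (header line, no quoting, no factor conversion).
#'
#' @param path TSV file path.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
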