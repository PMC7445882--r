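#' Read a FASTQ file, tolerating malformed records
#'
#' Plain 4-line FASTQ reader. Malformed records (bad header, missing `+`
#' separator, sequence/quality length mismatch, non-nucleotide characters)
#' are skipped with a warning naming the first offending line, rather than
#' aborting the run: on real nanopore output a truncated trailing record
#' must not discard the batch.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`; attribute
#'   `n_skipped` counts skipped records.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  ids <- character(0); seqs <- character(0); quals <- character(0)
  skipped <- 0L
  i <- 1L
  while (i <= n) {
    if (i + 3L > n) {
      warning("truncated FASTQ record at line ", i, " of ", path)
      skipped <- skipped + 1L
      break
    }
    h <- lines[i]; s <- lines[i + 1L]; p <- lines[i + 2L]; q <- lines[i + 3L]
    ok <- startsWith(h, "@") && startsWith(p, "+") &&
      nchar(s) == nchar(q) && grepl("^[ACGTNacgtn]*$", s)
    if (ok) {
      ids <- c(ids, sub("^@", "", sub("\\s.*$", "", h)))
      seqs <- c(seqs, toupper(s))
      quals <- c(quals, q)
    } else {
      warning("malformed FASTQ record starting at line ", i, " of ", path,
              "; skipped")
      skipped <- skipped + 1L
    }
    i <- i + 4L
  }
  out <- data.frame(id = ids, seq = seqs, qual = quals,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (as produced by
#'   [simulate_reads()] or [read_fastq()]).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                             "+", reads$qual)), path)
  invisible(path)
}

#' Read target sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
read_targets <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write target sequences to FASTA
#'
#' @param targets named character vector.
#' @param path output path.
#' @export
write_targets <- function(targets, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(targets), path)
  invisible(path)
}
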