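#' Read sequences from FASTA or FASTQ (optionally gzipped)
#'
#' @param path file path; format is inferred from the extension (`.fq`,
#'   `.fastq` with or without `.gz` are FASTQ, everything else FASTA).
#' @return named character vector; names are truncated at the first
#'   whitespace.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param x named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Write sequences as FASTQ (placeholder qualities)
#'
#' Base qualities are not used by the graph; reads are written with constant
#' quality.
#'
#' @param x named character vector.
#' @param path output path.
#' @export
write_fastq <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              format = "fastq")
  invisible(path)
}

#' Read a paired FASTQ/FASTA file pair into a pairs table
#'
#' @param path1,path2 mate-1 and mate-2 files, in matching order.
#' @return `data.table` with columns `read_id`, `mate1`, `mate2`.
#' @export
read_paired_reads <- function(path1, path2) {
  m1 <- read_sequences(path1)
  m2 <- read_sequences(path2)
  if (length(m1) != length(m2)) {
    stop("mate files differ in record count")
  }
  data.table(read_id = names(m1), mate1 = unname(m1), mate2 = unname(m2))
}
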