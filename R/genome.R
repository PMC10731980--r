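#' Reference genome container
#'
#' A light wrapper around a named character vector of uppercase contig
#' sequences (alphabet A, C, G, T, N). Contig order is preserved as given.
#'
#' @param contigs Named character vector, one uppercase sequence per contig.
#' @return An object of class `reference_genome` with elements `contigs`,
#'   `total_length` and `non_n_length`.
#' @export
reference_genome <- function(contigs) {
  if (length(contigs) == 0) stop("reference genome has no contigs")
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop("every contig must be named")
  if (anyDuplicated(names(contigs))) stop("duplicate contig names")
  if (any(nchar(contigs) == 0)) stop("empty contig sequence")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) contain characters outside A/C/G/T/N: ",
         paste(names(contigs)[bad], collapse = ", "))
  n_count <- vapply(contigs, function(s) {
    sum(charToRaw(s) == charToRaw("N"))
  }, integer(1))
  structure(
    list(contigs = contigs,
         total_length = sum(nchar(contigs)),
         non_n_length = sum(nchar(contigs)) - sum(n_count)),
    class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$contigs), "contig(s),",
      x$total_length, "bp (", x$non_n_length, "non-N )\n")
  for (nm in utils::head(names(x$contigs), 10))
    cat("  ", nm, ": ", nchar(x$contigs[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' Contig names and lengths
#' @param genome A `reference_genome`.
#' @return Named integer vector of contig lengths, in contig order.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "reference_genome"))
  setNames(nchar(genome$contigs), names(genome$contigs))
}

#' Extract reference sequence
#'
#' 1-based inclusive coordinates on the forward strand.
#'
#' @param genome A `reference_genome`.
#' @param contig Contig name.
#' @param start,end 1-based positions, `start <= end`.
#' @return Uppercase character string.
#' @export
get_seq <- function(genome, contig, start, end = start) {
  stopifnot(inherits(genome, "reference_genome"))
  seq <- genome$contigs[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  if (any(start < 1) || any(end > nchar(seq)) || any(end < start))
    stop("coordinates off contig ", contig, " (length ", nchar(seq), ")")
  substring(seq, start, end)
}

#' Read a reference genome from FASTA
#'
#' Sequences are case-normalized to uppercase. IUPAC ambiguity codes other
#' than N are rejected by default (the substitution spectrum is defined only
#' on A/C/G/T) or mapped to N.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Either `"error"` (default) or `"to_N"`.
#' @return A [reference_genome()].
#' @export
read_reference <- function(path, ambiguity = c("error", "to_N")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  seqs <- toupper(as.character(ss))
  # FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in ", path)
  if (ambiguity == "to_N") seqs <- gsub("[^ACGTN]", "N", seqs)
  reference_genome(seqs)
}

#' Write a reference genome to FASTA
#' @param genome A `reference_genome`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "reference_genome"))
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
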