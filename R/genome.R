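#' Read a genome from FASTA
#'
#' Loads all records of a FASTA file into a [Biostrings::DNAStringSet],
#' upper-casing the sequence. Record names are truncated at the first
#' whitespace, matching the usual contig-naming convention.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("malformed FASTA '", path, "': file is empty", call. = FALSE)
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA '", path, "': line ", nonblank[1],
         " should be a '>' header but is: ",
         substr(lines[nonblank[1]], 1, 40), call. = FALSE)
  }
  genome <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(genome) == 0L)) {
    bad <- names(genome)[Biostrings::width(genome) == 0L][1]
    stop("malformed FASTA '", path, "': record '", bad,
         "' has an empty sequence", call. = FALSE)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  Biostrings::DNAStringSet(toupper(as.character(genome)))
}

#' Fetch a genomic interval, strand-aware
#'
#' Returns the transcribed sequence of a 0-based half-open interval:
#' the forward sequence on `+`, the reverse complement on `-`.
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param contig Contig name.
#' @param start,end 0-based half-open interval, vectorised.
#' @param strand `"+"` or `"-"`, vectorised.
#' @return Character vector of sequences.
#' @export
genome_fetch <- function(genome, contig, start, end, strand = "+") {
  n <- max(length(contig), length(start), length(end), length(strand))
  contig <- rep_len(contig, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  strand <- rep_len(strand, n)
  missing <- setdiff(unique(contig), names(genome))
  if (length(missing) > 0L) {
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  clen <- setNames(Biostrings::width(genome), names(genome))[contig]
  if (any(start < 0L) || any(end > clen)) {
    i <- which(start < 0L | end > clen)[1]
    stop("interval [", start[i], ",", end[i], ") outside contig ",
         contig[i], " of length ", clen[i], call. = FALSE)
  }
  if (any(end < start)) stop("interval end before start", call. = FALSE)
  seqs <- as.character(Biostrings::subseq(genome[contig], start + 1L, end))
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus]))
    )
  }
  unname(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
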