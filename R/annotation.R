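#' Read transcript models from GTF
#'
#' Imports exon features from a GTF file (1-based inclusive coordinates)
#' and returns one row per exon with internal 0-based half-open
#' coordinates, grouped by transcript and sorted in genomic order.
#'
#' @param path Path to a GTF file with `exon` features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @return A tibble with columns `transcript_id`, `gene_id`, `contig`,
#'   `strand`, `exon_start`, `exon_end` (0-based half-open), sorted by
#'   transcript and genomic position.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop("annotation GTF not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  exons <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(exons) == 0L) {
    warning("no exon features in '", path, "'; returning empty annotation")
    return(tibble(
      transcript_id = character(), gene_id = character(),
      contig = character(), strand = character(),
      exon_start = integer(), exon_end = integer()
    ))
  }
  tid <- as.character(exons$transcript_id %||% rep(NA_character_, length(exons)))
  gid <- as.character(exons$gene_id %||% rep(NA_character_, length(exons)))
  if (anyNA(tid) || any(tid == "")) {
    stop("exon feature without transcript_id in '", path, "'", call. = FALSE)
  }
  if (anyNA(gid) || any(gid == "")) {
    stop("exon feature without gene_id in '", path, "'", call. = FALSE)
  }
  out <- tibble(
    transcript_id = tid,
    gene_id = gid,
    contig = as.character(GenomeInfoDb::seqnames(exons)),
    strand = as.character(BiocGenerics::strand(exons)),
    exon_start = BiocGenerics::start(exons) - 1L,  # GTF 1-based -> 0-based
    exon_end = BiocGenerics::end(exons)
  ) |>
    arrange(.data$transcript_id, .data$exon_start)
  if (any(!out$strand %in% c("+", "-"))) {
    stop("exon with strand other than +/- in '", path, "'", call. = FALSE)
  }
  overlapping <- out |>
    group_by(.data$transcript_id) |>
    filter(n() > 1, .data$exon_start < dplyr::lag(.data$exon_end, default = -1L)) |>
    ungroup()
  if (nrow(overlapping) > 0L) {
    stop("overlapping exons within transcript ",
         overlapping$transcript_id[1], call. = FALSE)
  }
  out
}

#' Stable intron identifier
#'
#' @param contig,start,end,strand Interval fields (0-based half-open).
#' @return Character key `contig:start-end:strand`.
#' @export
intron_key <- function(contig, start, end, strand) {
  paste0(contig, ":", start, "-", end, ":", strand)
}

#' Extract a deduplicated intron catalog
#'
#' Every gap between consecutive exons of each transcript becomes an
#' intron; introns identical in (contig, start, end, strand) are collapsed
#' to a single catalog entry. The host gene is taken from the first
#' contributing transcript (ambiguity across genes is messaged), and
#' `intron_index` is the 1-based ordinal of the intron within its host
#' gene in transcription order. Terminal dinucleotides, the donor window
#' and the 3' branch-point search region are extracted strand-aware.
#'
#' @param transcripts Exon tibble from [read_annotation()].
#' @param genome Genome from [read_genome()].
#' @param donor_window Length (nt) of the 5' splice-site window, counted
#'   from the first intronic base. Default 9 covers the extended U12
#'   consensus.
#' @param bps_search_len Length (nt) of the 3'-terminal region retained
#'   for branch-point scanning. Default 40 covers the -40..-3 window.
#' @param min_intron_length Introns shorter than this are skipped with a
#'   warning. Default 30.
#' @return A tibble, one row per unique intron: `intron_id`, `contig`,
#'   `start`, `end`, `strand`, `host_gene`, `intron_index`,
#'   `donor_dinucleotide`, `acceptor_dinucleotide`, `terminal_label`,
#'   `donor_region_seq`, `three_prime_region_seq`.
#' @export
extract_introns <- function(transcripts, genome, donor_window = 9L,
                            bps_search_len = 40L, min_intron_length = 30L) {
  stopifnot(donor_window >= 2L, bps_search_len >= 1L)
  missing <- setdiff(unique(transcripts$contig), names(genome))
  if (length(missing) > 0L) {
    stop("transcript contig(s) absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gaps <- transcripts |>
    arrange(.data$transcript_id, .data$exon_start) |>
    group_by(.data$transcript_id, .data$gene_id, .data$contig, .data$strand) |>
    dplyr::reframe(
      start = head(.data$exon_end, -1L),
      end = tail(.data$exon_start, -1L)
    )
  if (nrow(gaps) == 0L) {
    return(empty_intron_catalog())
  }
  short <- gaps$end - gaps$start < min_intron_length
  if (any(short)) {
    warning(sum(short), " intron(s) shorter than ", min_intron_length,
            " nt skipped")
    gaps <- gaps[!short, , drop = FALSE]
  }
  if (nrow(gaps) == 0L) {
    return(empty_intron_catalog())
  }
  multi_gene <- gaps |>
    distinct(.data$contig, .data$start, .data$end, .data$strand,
             .data$gene_id) |>
    count(.data$contig, .data$start, .data$end, .data$strand) |>
    filter(.data$n > 1L)
  if (nrow(multi_gene) > 0L) {
    message(nrow(multi_gene),
            " intron(s) shared across genes; host gene taken from the ",
            "first contributing transcript")
  }
  introns <- gaps |>
    distinct(.data$contig, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) |>
    rename(host_gene = "gene_id") |>
    select(-"transcript_id") |>
    group_by(.data$host_gene) |>
    arrange(if_else(.data$strand == "+", .data$start, -.data$start),
            .by_group = TRUE) |>
    mutate(intron_index = row_number()) |>
    ungroup() |>
    arrange(.data$contig, .data$start, .data$end, .data$strand)

  seq_all <- genome_fetch(genome, introns$contig, introns$start,
                          introns$end, introns$strand)
  len <- introns$end - introns$start
  introns |>
    mutate(
      intron_id = intron_key(.data$contig, .data$start, .data$end,
                             .data$strand),
      donor_dinucleotide = substr(seq_all, 1L, 2L),
      acceptor_dinucleotide = substr(seq_all, len - 1L, len),
      terminal_label = paste0(.data$donor_dinucleotide, "-",
                              .data$acceptor_dinucleotide),
      donor_region_seq = substr(seq_all, 1L, pmin(donor_window, len)),
      three_prime_region_seq = substr(seq_all,
                                      pmax(1L, len - bps_search_len + 1L),
                                      len)
    ) |>
    select("intron_id", "contig", "start", "end", "strand", "host_gene",
           "intron_index", "donor_dinucleotide", "acceptor_dinucleotide",
           "terminal_label", "donor_region_seq", "three_prime_region_seq")
}

empty_intron_catalog <- function() {
  tibble(
    intron_id = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), host_gene = character(),
    intron_index = integer(), donor_dinucleotide = character(),
    acceptor_dinucleotide = character(), terminal_label = character(),
    donor_region_seq = character(), three_prime_region_seq = character()
  )
}

#' Write an intron catalog to BED6
#'
#' BED uses 0-based half-open coordinates, matching the internal
#' representation. The name field is `gene:index:label`.
#'
#' @param introns Intron catalog from [extract_introns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  bed <- introns |>
    mutate(name = paste(.data$host_gene, .data$intron_index,
                        .data$terminal_label, sep = ":"),
           score = 0L) |>
    select("contig", "start", "end", "name", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read intron intervals back from BED6
#'
#' @param path BED6 file written by [write_intron_bed()].
#' @return Tibble with `contig`, `start`, `end`, `strand`, `name`.
#' @export
read_intron_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("contig", "start", "end", "name", "score",
                                "strand"),
                  col_types = "ciicic", progress = FALSE) |>
    select("contig", "start", "end", "strand", "name")
}
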