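#' Read gapped alignments from a SAM file
#'
#' Parses SAM text records into aligned reference blocks. CIGAR `M`, `=`,
#' `X` and `D` operations extend the current block on the reference; `N`
#' (skipped region, i.e. a splice junction) closes it and opens the next;
#' `I` and `S` consume no reference. Unmapped (flag 0x4), secondary
#' (0x100) and supplementary (0x800) records are skipped.
#'
#' @param path Path to a SAM file.
#' @param sample_id Sample label attached to every record; defaults to the
#'   file name without extension.
#' @return Tibble with one row per aligned block: `read_id`, `sample_id`,
#'   `contig`, `block_start`, `block_end` (0-based half-open),
#'   `block_index`, `n_blocks`.
#' @export
read_alignments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_block_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 11L
  if (any(short)) {
    stop("malformed SAM record (fewer than 11 fields) at data line ",
         which(short)[1], call. = FALSE)
  }
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L)) - 1L  # SAM 1-based
  cigar <- vapply(fields, `[[`, "", 6L)
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L & rname != "*" & cigar != "*"
  if (!any(keep)) {
    return(empty_block_table())
  }
  blocks <- purrr::map2(cigar[keep], pos[keep], function(cg, p) {
    cigar_blocks(cg, p)
  })
  bad <- vapply(blocks, is.character, logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("malformed CIGAR for record '", qname[keep][i], "': ",
         blocks[[i]], call. = FALSE)
  }
  nb <- vapply(blocks, nrow, integer(1))
  mat <- do.call(rbind, blocks)
  tibble(
    read_id = rep(qname[keep], nb),
    sample_id = sample_id,
    contig = rep(rname[keep], nb),
    block_start = mat[, 1L],
    block_end = mat[, 2L],
    block_index = unlist(lapply(nb, seq_len)),
    n_blocks = rep(nb, nb)
  )
}

# Reference-space blocks implied by a CIGAR string at 0-based position pos.
# Returns a 2-column matrix (start, end) or a character error message.
cigar_blocks <- function(cigar, pos) {
  ops <- gregexpr("\\d+[A-Z=]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]?", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    return("unparseable operation string")
  }
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  if (any(op == "")) return("operation without type letter")
  if (any(!op %in% c("M", "I", "D", "N", "S", "=", "X"))) {
    return(paste0("unsupported operation '",
                  op[!op %in% c("M", "I", "D", "N", "S", "=", "X")][1], "'"))
  }
  starts <- integer(0); ends <- integer(0)
  cur_start <- pos; cur <- pos; open <- FALSE
  for (i in seq_along(op)) {
    o <- op[i]
    if (o %in% c("M", "=", "X", "D")) {
      if (!open) { cur_start <- cur; open <- TRUE }
      cur <- cur + lens[i]
    } else if (o == "N") {
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
      cur <- cur + lens[i]
      open <- FALSE
    }
    # I and S consume no reference
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
  if (length(starts) == 0L) return("no reference-consuming operation")
  cbind(starts, ends)
}

empty_block_table <- function() {
  tibble(
    read_id = character(), sample_id = character(), contig = character(),
    block_start = integer(), block_end = integer(),
    block_index = integer(), n_blocks = integer()
  )
}

#' Splice junctions implied by gapped alignments
#'
#' Each `N` gap between consecutive aligned blocks is one junction
#' observation; counts are aggregated per sample. Flanking block widths
#' are tracked so callers can enforce anchor requirements.
#'
#' @param blocks Block tibble from [read_alignments()] (several samples
#'   may be row-bound).
#' @param min_anchor Minimum aligned width (nt) required on both sides of
#'   the gap. Default 1.
#' @return Tibble `contig`, `start`, `end` (0-based half-open gap),
#'   `sample_id`, `count`.
#' @export
junction_counts <- function(blocks, min_anchor = 1L) {
  if (nrow(blocks) == 0L) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), sample_id = character(),
                  count = integer()))
  }
  blocks |>
    arrange(.data$sample_id, .data$read_id, .data$block_index) |>
    group_by(.data$sample_id, .data$read_id, .data$contig) |>
    filter(n() > 1L) |>
    mutate(
      gap_start = .data$block_end,
      gap_end = dplyr::lead(.data$block_start),
      left_w = .data$block_end - .data$block_start,
      right_w = dplyr::lead(.data$block_end - .data$block_start)
    ) |>
    ungroup() |>
    filter(!is.na(.data$gap_end),
           .data$left_w >= min_anchor, .data$right_w >= min_anchor) |>
    count(.data$contig, start = .data$gap_start, end = .data$gap_end,
          .data$sample_id, name = "count") |>
    select("contig", "start", "end", "sample_id", "count")
}
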