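#' Count retention and splicing evidence per intron and sample
#'
#' For every intron and sample, three read classes are tallied:
#' * `J` (junction reads): records with consecutive aligned blocks whose
#'   gap equals the intron interval exactly, with at least `k` aligned nt
#'   on each side — direct evidence for the spliced isoform.
#' * `B` (boundary reads): per exon–intron boundary crossed by an aligned
#'   block with at least `k` nt on both sides — evidence for retention.
#'   A single read can increment `B` at most twice (once per boundary).
#' * `R` (intron-body reads): records with at least `k` nt of some block
#'   inside the intron that are not junction reads for that intron.
#'
#' Records on contigs absent from the catalog are ignored (a tally is
#' messaged).
#'
#' @param blocks Aligned-block tibble from [read_alignments()]; rows from
#'   several samples may be bound together.
#' @param introns Intron catalog (needs `intron_id`, `contig`, `start`,
#'   `end`).
#' @param k Minimum anchor (aligned nt) on each side of a junction or
#'   boundary, and minimum in-intron overlap for body reads. Default 8.
#' @return Tibble `intron_id`, `sample_id`, `J`, `B`, `R`, complete over
#'   all intron x sample combinations present in `blocks`.
#' @export
count_intron_evidence <- function(blocks, introns, k = 8L) {
  stopifnot(k >= 1L)
  samples <- unique(blocks$sample_id)
  grid <- tidyr::expand_grid(intron_id = introns$intron_id,
                             sample_id = samples)
  if (nrow(blocks) == 0L || nrow(introns) == 0L) {
    return(grid |> mutate(J = 0L, B = 0L, R = 0L))
  }
  unknown <- setdiff(unique(blocks$contig), unique(introns$contig))
  if (length(unknown) > 0L) {
    n_ign <- sum(blocks$contig %in% unknown)
    message(n_ign, " block(s) on ", length(unknown),
            " contig(s) without catalog introns ignored")
  }

  # J: gaps between consecutive blocks matching an intron exactly
  gaps <- junction_counts(blocks, min_anchor = k) # already per sample
  j_tab <- gaps |>
    inner_join(introns |> select("intron_id", "contig", "start", "end"),
               by = c("contig", "start", "end")) |>
    group_by(.data$intron_id, .data$sample_id) |>
    summarise(J = sum(.data$count), .groups = "drop")

  # which (read, intron) pairs are junction-spanning (excluded from R)
  jc_pairs <- blocks |>
    arrange(.data$sample_id, .data$read_id, .data$block_index) |>
    group_by(.data$sample_id, .data$read_id, .data$contig) |>
    filter(n() > 1L) |>
    mutate(gap_start = .data$block_end,
           gap_end = dplyr::lead(.data$block_start),
           left_w = .data$block_end - .data$block_start,
           right_w = dplyr::lead(.data$block_end - .data$block_start)) |>
    ungroup() |>
    filter(!is.na(.data$gap_end), .data$left_w >= k, .data$right_w >= k) |>
    inner_join(introns |> select("intron_id", "contig",
                                 gap_start = "start", gap_end = "end"),
               by = c("contig", "gap_start", "gap_end")) |>
    distinct(.data$sample_id, .data$read_id, .data$intron_id)

  # B and R via interval overlap, per contig
  b_tab <- NULL
  r_tab <- NULL
  for (ctg in intersect(unique(introns$contig), unique(blocks$contig))) {
    bl <- blocks |> filter(.data$contig == ctg)
    it <- introns |> filter(.data$contig == ctg)
    bl_ir <- IRanges::IRanges(bl$block_start + 1L, bl$block_end)
    # boundary windows: [b - k, b + k) in 0-based, i.e. width 2k
    bounds <- tibble(
      intron_id = rep(it$intron_id, 2L),
      b = c(it$start, it$end)
    )
    win <- IRanges::IRanges(bounds$b - k + 1L, bounds$b + k)
    hit_b <- IRanges::findOverlaps(win, bl_ir, type = "within")
    if (length(hit_b) > 0L) {
      b_tab <- bind_rows(b_tab, tibble(
        intron_id = bounds$intron_id[S4Vectors::queryHits(hit_b)],
        sample_id = bl$sample_id[S4Vectors::subjectHits(hit_b)],
        read_id = bl$read_id[S4Vectors::subjectHits(hit_b)]
      ))
    }
    body <- IRanges::IRanges(it$start + 1L, it$end)
    hit_r <- IRanges::findOverlaps(body, bl_ir, minoverlap = k)
    if (length(hit_r) > 0L) {
      r_tab <- bind_rows(r_tab, tibble(
        intron_id = it$intron_id[S4Vectors::queryHits(hit_r)],
        sample_id = bl$sample_id[S4Vectors::subjectHits(hit_r)],
        read_id = bl$read_id[S4Vectors::subjectHits(hit_r)]
      ))
    }
  }
  b_counts <- if (is.null(b_tab) || nrow(b_tab) == 0L) {
    tibble(intron_id = character(), sample_id = character(), B = integer())
  } else {
    # one increment per (read, boundary); a read crossing both boundaries
    # counts twice
    b_tab |>
      count(.data$intron_id, .data$sample_id, name = "B")
  }
  r_counts <- if (is.null(r_tab) || nrow(r_tab) == 0L) {
    tibble(intron_id = character(), sample_id = character(), R = integer())
  } else {
    r_tab |>
      distinct(.data$intron_id, .data$sample_id, .data$read_id) |>
      anti_join(jc_pairs, by = c("intron_id", "sample_id", "read_id")) |>
      count(.data$intron_id, .data$sample_id, name = "R")
  }
  grid |>
    left_join(j_tab, by = c("intron_id", "sample_id")) |>
    left_join(b_counts, by = c("intron_id", "sample_id")) |>
    left_join(r_counts, by = c("intron_id", "sample_id")) |>
    mutate(across(c("J", "B", "R"), ~ tidyr::replace_na(.x, 0L)))
}

#' Estimate intron retention (psi) per condition
#'
#' Counts are pooled across a condition's replicates, then
#' `psi = retained / (retained + spliced)`. In `boundary` mode the
#' retained evidence is `B / 2` (each retained molecule presents two
#' exon–intron boundaries, each spliced molecule one junction) and the
#' spliced evidence is `J`. In `body` mode the retained evidence is `R`
#' rescaled by `read_length / intron_length` (an intron presents roughly
#' `intron_length / read_length` body-read positions per molecule) and
#' the spliced evidence is `J`. A zero denominator yields `NA`.
#'
#' @param counts Count tibble from [count_intron_evidence()] (or the
#'   simulator), columns `intron_id`, `sample_id`, `J`, `B`, `R`.
#' @param design Tibble `sample_id`, `condition` (exactly two conditions).
#' @param mode `"boundary"` (default) or `"body"`.
#' @param introns Intron catalog; required in `body` mode for lengths.
#' @param read_length Read length used in `body` mode. Default 50.
#' @return Tibble `intron_id`, `condition`, `retained_units`,
#'   `spliced_units`, `psi`.
#' @export
compute_psi <- function(counts, design, mode = c("boundary", "body"),
                        introns = NULL, read_length = 50) {
  mode <- match.arg(mode)
  pooled <- counts |>
    inner_join(design, by = "sample_id") |>
    group_by(.data$intron_id, .data$condition) |>
    summarise(J = sum(.data$J), B = sum(.data$B), R = sum(.data$R),
              .groups = "drop")
  if (mode == "boundary") {
    pooled <- pooled |>
      mutate(retained_units = .data$B / 2, spliced_units = .data$J)
  } else {
    if (is.null(introns)) {
      stop("body mode needs the intron catalog for intron lengths",
           call. = FALSE)
    }
    pooled <- pooled |>
      inner_join(introns |> mutate(.len = .data$end - .data$start) |>
                   select("intron_id", ".len"),
                 by = "intron_id") |>
      mutate(retained_units = .data$R * read_length / .data$.len,
             spliced_units = .data$J) |>
      select(-".len")
  }
  pooled |>
    mutate(psi = if_else(.data$retained_units + .data$spliced_units > 0,
                         .data$retained_units /
                           (.data$retained_units + .data$spliced_units),
                         NA_real_)) |>
    select("intron_id", "condition", "retained_units", "spliced_units",
           "psi")
}

#' Filter introns by read support
#'
#' Mirrors the two read-support filters used for the retention analyses:
#' a junction filter keeping introns with at least `min_junction` spliced
#' junction reads in total across the samples of the comparison, and a
#' body filter keeping introns with on average at least `min_avg_body`
#' intron-mapping reads per sample. Both are "at least" thresholds, so
#' equality survives.
#'
#' @param counts Count tibble (`intron_id`, `sample_id`, `J`, `B`, `R`).
#' @param filter Which filter to apply: `"junction"` or `"body"`.
#' @param min_junction Total-J threshold. Default 5.
#' @param min_avg_body Mean-R threshold. Default 5.
#' @return The rows of `counts` for surviving introns.
#' @export
filter_introns <- function(counts, filter = c("junction", "body"),
                           min_junction = 5, min_avg_body = 5) {
  filter <- match.arg(filter)
  if (nrow(counts) == 0L) return(counts)
  keep <- counts |>
    group_by(.data$intron_id) |>
    summarise(total_J = sum(.data$J), mean_R = mean(.data$R),
              .groups = "drop")
  keep <- if (filter == "junction") {
    keep |> dplyr::filter(.data$total_J >= min_junction)
  } else {
    keep |> dplyr::filter(.data$mean_R >= min_avg_body)
  }
  counts |> semi_join(keep, by = "intron_id")
}
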