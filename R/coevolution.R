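#' Read a phylogenetic presence/absence matrix
#'
#' @param path TSV with a `gene` column followed by one 0/1 column per
#'   species.
#' @return Tibble, genes in rows.
#' @export
read_profile_matrix <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  if (anyDuplicated(m$gene) > 0L) {
    stop("duplicate gene ids in profile matrix", call. = FALSE)
  }
  if (ncol(m) < 3L) stop("profile matrix needs >= 2 species", call. = FALSE)
  vals <- unlist(m[, -1])
  if (any(!vals %in% c(0L, 1L))) {
    stop("profile matrix entries must be 0/1", call. = FALSE)
  }
  m
}

#' Rank genes by phylogenetic-profile co-occurrence
#'
#' Computes, for every gene, the Pearson correlation between its binary
#' presence/absence profile and the query profile — on binary vectors
#' this is exactly the 2x2 phi coefficient. Genes with constant profiles
#' (all present or all absent) have undefined correlation and are ranked
#' last. Results are sorted by decreasing `r`, ties broken by gene id.
#'
#' @param profiles Profile tibble (see [read_profile_matrix()]): `gene`
#'   column plus one 0/1 column per species.
#' @param query A gene id present in `profiles`, or a numeric 0/1 vector
#'   of length equal to the number of species.
#' @return Tibble `gene`, `r`, sorted; `r` is `NA` for constant profiles
#'   (or when the query itself is constant).
#' @export
profile_correlation <- function(profiles, query) {
  mat <- as.matrix(profiles[, -1, drop = FALSE])
  rownames(mat) <- profiles$gene
  if (is.character(query)) {
    if (!query %in% profiles$gene) {
      stop("query gene '", query, "' absent from the matrix",
           call. = FALSE)
    }
    q <- mat[query, ]
  } else {
    if (length(query) != ncol(mat)) {
      stop("query profile length ", length(query),
           " != number of species ", ncol(mat), call. = FALSE)
    }
    q <- as.numeric(query)
  }
  r <- if (stats::sd(q) == 0) {
    rep(NA_real_, nrow(mat))
  } else {
    suppressWarnings(as.numeric(cor(t(mat), q)))
  }
  tibble(gene = rownames(mat), r = r) |>
    arrange(is.na(.data$r), dplyr::desc(.data$r), .data$gene)
}

#' Select co-occurring genes
#'
#' Genes whose profile correlation with the query strictly exceeds
#' `r_min` (default 0.5), with the query itself excluded.
#'
#' @param results Tibble from [profile_correlation()].
#' @param r_min Correlation cutoff (strict inequality). Default 0.5.
#' @param query Optional query gene id to exclude.
#' @return Character vector of gene ids.
#' @export
select_cooccurring <- function(results, r_min = 0.5, query = NULL) {
  out <- results |>
    dplyr::filter(!is.na(.data$r), .data$r > r_min)
  if (!is.null(query)) out <- out |> dplyr::filter(.data$gene != query)
  out$gene
}

#' Term over-representation among selected genes
#'
#' Upper-tail hypergeometric (one-sided Fisher) test per term: with `N`
#' background genes of which `K` carry the term, and `n` selected genes
#' of which `k` carry it, `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. P-values are Benjamini-Hochberg
#' adjusted across terms; fold enrichment is `(k/n) / (K/N)`. Terms
#' absent from the background are skipped.
#'
#' @param selected Character vector of selected gene ids (must be a
#'   subset of `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Tibble `gene`, `term` (one row per annotation).
#' @return Tibble `term`, `k`, `K`, `n`, `N`, `fold_enrichment`, `p`,
#'   `p_adj`, sorted by `p`.
#' @export
enrich_terms <- function(selected, background, term_map) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background",
         call. = FALSE)
  }
  tm <- term_map |>
    dplyr::filter(.data$gene %in% background) |>
    distinct(.data$gene, .data$term)
  N <- length(background)
  n <- length(selected)
  res <- tm |>
    group_by(.data$term) |>
    summarise(K = dplyr::n(),
              k = sum(.data$gene %in% selected),
              .groups = "drop") |>
    dplyr::filter(.data$K > 0L) |>
    mutate(
      n = n, N = N,
      fold_enrichment = (.data$k / n) / (.data$K / N),
      p = phyper(.data$k - 1, .data$K, N - .data$K, n,
                 lower.tail = FALSE)
    )
  res |>
    mutate(p_adj = adjust_bh(.data$p)) |>
    select("term", "k", "K", "n", "N", "fold_enrichment", "p", "p_adj") |>
    arrange(.data$p, .data$term)
}
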