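#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity, mapped back to the input order (a thin, validating
#' wrapper around [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. With combined sample size at most 20
#' and no ties the exact null distribution is used; otherwise the normal
#' approximation with tie and continuity corrections. If the pooled
#' sample has zero variance (every value identical) the test is
#' uninformative and `p = 1` with `U = m n / 2`.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counted
#'   half), `p.value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L) {
    return(list(U = length(x) * length(y) / 2, p.value = 1,
                method = "normal_approx"))
  }
  exact <- (length(x) + length(y)) <= 20L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, paired = FALSE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(U = unname(wt$statistic), p.value = min(p, 1),
       method = if (exact) "exact" else "normal_approx")
}

#' Differential intron retention across two conditions
#'
#' Runs the replicate-aware beta-binomial likelihood-ratio test
#' ([betabin_test()]) per intron on retained/total evidence derived from
#' boundary and junction counts (`retained = B / 2`,
#' `total = B / 2 + J`), adjusts p-values by Benjamini-Hochberg, and
#' flags affected introns: `affected_ir` when `p_adj < alpha` and
#' `affected_strict` when additionally `delta_psi > dpsi_cutoff`.
#'
#' @param counts Count tibble (`intron_id`, `sample_id`, `J`, `B`, ...).
#' @param design Tibble `sample_id`, `condition`; `control` names the
#'   reference level.
#' @param control,treatment Condition labels; by default the first and
#'   second level of `design$condition` in sorted order.
#' @param alpha Adjusted-p cutoff. Default 0.05.
#' @param dpsi_cutoff Retention-shift cutoff for the strict flag.
#'   Default 0.1.
#' @param rho Overdispersion handling: `"common"` (default) estimates a
#'   single shared `rho` across all introns of the comparison with
#'   [estimate_common_rho()] and holds it fixed in every per-intron
#'   test (few replicates per intron make per-intron dispersion
#'   estimates unstable; sharing is the standard remedy);
#'   `"per_intron"` estimates `rho` per intron by maximum likelihood;
#'   a number fixes `rho` (0 gives the binomial test).
#' @return Tibble `intron_id`, `delta_psi`, `statistic`, `p`, `p_adj`,
#'   `affected_ir`, `affected_strict`, `method`, with the common `rho`
#'   (when used) in attribute `"rho"`.
#' @export
test_differential_ir <- function(counts, design, control = NULL,
                                 treatment = NULL, alpha = 0.05,
                                 dpsi_cutoff = 0.1, rho = "common") {
  conds <- sort(unique(design$condition))
  if (length(conds) != 2L) {
    stop("design must contain exactly two conditions", call. = FALSE)
  }
  control <- control %||% conds[1]
  treatment <- treatment %||% conds[2]
  dat <- counts |>
    inner_join(design, by = "sample_id") |>
    mutate(retained = .data$B / 2,
           total = .data$B / 2 + .data$J)
  rho_common <- NA_real_
  if (identical(rho, "common")) {
    rho <- estimate_common_rho(dat$retained, dat$total,
                               paste(dat$intron_id, dat$condition))
    rho_common <- rho
  } else if (identical(rho, "per_intron")) {
    rho <- NULL
  } else if (!is.null(rho) && !is.numeric(rho)) {
    stop("rho must be \"common\", \"per_intron\" or a number",
         call. = FALSE)
  }
  res <- dat |>
    group_by(.data$intron_id) |>
    dplyr::group_modify(function(d, key) {
      cc <- d |> dplyr::filter(.data$condition == control)
      tt <- d |> dplyr::filter(.data$condition == treatment)
      fit <- betabin_test(cc$retained, cc$total, tt$retained, tt$total,
                          rho = rho)
      tibble(delta_psi = fit$delta_psi, statistic = fit$statistic,
             p = fit$p.value, method = fit$method)
    }) |>
    ungroup()
  out <- res |>
    mutate(p_adj = adjust_bh(.data$p),
           affected_ir = !is.na(.data$p_adj) & .data$p_adj < alpha,
           affected_strict = .data$affected_ir &
             !is.na(.data$delta_psi) & .data$delta_psi > dpsi_cutoff) |>
    select("intron_id", "delta_psi", "statistic", "p", "p_adj",
           "affected_ir", "affected_strict", "method")
  attr(out, "rho") <- rho_common
  out
}

#' Subtype-stratified summary of differential retention
#'
#' Restricts results to minor introns of the A (AT-AN) and G (GT-AN /
#' GC-AG) subtypes and reports, per subtype, the number analyzed, the
#' fraction affected, and the mean and median retention shift, plus a
#' two-sided Mann-Whitney comparison of the A vs G `delta_psi`
#' distributions.
#'
#' @param results Tibble from [test_differential_ir()].
#' @param classifications Tibble from [classify_introns()].
#' @param affected Which flag defines "affected": `"ir"`
#'   (`affected_ir`), `"strict"` (`affected_strict`) or
#'   `"ir_or_cryptic"` (union of `affected_ir` and cryptic activation;
#'   requires `cryptic`).
#' @param cryptic Optional tibble from [detect_cryptic()]; used by
#'   `"ir_or_cryptic"`.
#' @return Tibble with one row per subtype: `subtype`, `n`,
#'   `n_affected`, `fraction_affected`, `mean_delta_psi`,
#'   `median_delta_psi`, and the shared `mw_U`, `mw_p` of the A-vs-G
#'   comparison (`NA` when a subtype is empty).
#' @export
summarize_by_subtype <- function(results, classifications,
                                 affected = c("ir", "strict",
                                              "ir_or_cryptic"),
                                 cryptic = NULL) {
  affected <- match.arg(affected)
  dat <- results |>
    inner_join(classifications |> select("intron_id", "spliceosome_type",
                                         "subtype"),
               by = "intron_id") |>
    dplyr::filter(.data$spliceosome_type == "minor",
                  .data$subtype %in% c("A", "G"))
  if (affected == "ir_or_cryptic") {
    activated <- if (is.null(cryptic) || nrow(cryptic) == 0L) character(0)
      else unique(cryptic$intron_id[cryptic$activated])
    dat <- dat |> mutate(is_affected = .data$affected_ir |
                           .data$intron_id %in% activated)
  } else if (affected == "strict") {
    dat <- dat |> mutate(is_affected = .data$affected_strict)
  } else {
    dat <- dat |> mutate(is_affected = .data$affected_ir)
  }
  out <- tibble(subtype = c("A", "G")) |>
    left_join(
      dat |>
        group_by(.data$subtype) |>
        summarise(n = dplyr::n(),
                  n_affected = sum(.data$is_affected),
                  fraction_affected = mean(.data$is_affected),
                  mean_delta_psi = mean(.data$delta_psi, na.rm = TRUE),
                  median_delta_psi = median(.data$delta_psi, na.rm = TRUE),
                  .groups = "drop"),
      by = "subtype"
    ) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  da <- dat$delta_psi[dat$subtype == "A" & !is.na(dat$delta_psi)]
  dg <- dat$delta_psi[dat$subtype == "G" & !is.na(dat$delta_psi)]
  if (length(da) > 0L && length(dg) > 0L) {
    mw <- mann_whitney(da, dg)
    out$mw_U <- mw$U
    out$mw_p <- mw$p.value
  } else {
    out$mw_U <- NA_real_
    out$mw_p <- NA_real_
  }
  out
}

#' Hierarchical clustering of retention profiles
#'
#' Agglomerative average-linkage clustering of introns on Euclidean
#' distances between their per-sample retention (psi) profiles. Rows
#' containing missing values are dropped with a warning.
#'
#' @param psi_matrix Numeric matrix, introns (rows, named) x samples.
#' @return List with `tree` (an [stats::hclust] object, `NULL` for fewer
#'   than 2 usable rows), `leaf_order` (row names in dendrogram order)
#'   and `dropped` (row names removed for missingness).
#' @export
cluster_retention <- function(psi_matrix) {
  stopifnot(is.matrix(psi_matrix))
  if (is.null(rownames(psi_matrix))) {
    rownames(psi_matrix) <- as.character(seq_len(nrow(psi_matrix)))
  }
  ok <- stats::complete.cases(psi_matrix)
  dropped <- rownames(psi_matrix)[!ok]
  if (length(dropped) > 0L) {
    warning(length(dropped), " row(s) with missing psi dropped")
  }
  m <- psi_matrix[ok, , drop = FALSE]
  if (nrow(m) < 2L) {
    return(list(tree = NULL, leaf_order = rownames(m), dropped = dropped))
  }
  tree <- hclust(dist(m, method = "euclidean"), method = "average")
  list(tree = tree, leaf_order = rownames(m)[tree$order],
       dropped = dropped)
}

#' Detect activation of alternative (cryptic) splice sites
#'
#' For each minor intron, any observed junction sharing the contig, with
#' one boundary within `w` nt of a canonical intron boundary but not
#' identical to the canonical junction, is a candidate alternative splice
#' event. Usage of the alternative relative to the canonical junction,
#' `psi_alt = J_alt / (J_alt + J_canonical)`, is compared between
#' conditions with the beta-binomial test; events with
#' `p_adj < alpha` and `|delta_psi_alt| > dpsi_cutoff` are flagged
#' activated.
#'
#' @param junctions Junction counts (`contig`, `start`, `end`,
#'   `sample_id`, `count`), e.g. from [junction_counts()] or the
#'   simulator.
#' @param introns Intron catalog restricted (by the caller or via
#'   `classifications`) to the introns of interest.
#' @param design Tibble `sample_id`, `condition`.
#' @param classifications Optional tibble from [classify_introns()]; if
#'   given, only minor introns are screened.
#' @param w Flank window (nt) for matching candidate boundaries.
#'   Default 50.
#' @param control,treatment Condition labels (defaults as in
#'   [test_differential_ir()]).
#' @param alpha,dpsi_cutoff Activation cutoffs. Defaults 0.05 and 0.1.
#' @param rho Passed to [betabin_test()].
#' @return Tibble with one row per (intron, alternative junction):
#'   `intron_id`, `alt_start`, `alt_end`, `psi_alt_control`,
#'   `psi_alt_treat`, `delta_psi_alt`, `p`, `p_adj`, `activated`.
#' @export
detect_cryptic <- function(junctions, introns, design,
                           classifications = NULL, w = 50L,
                           control = NULL, treatment = NULL,
                           alpha = 0.05, dpsi_cutoff = 0.1, rho = NULL) {
  conds <- sort(unique(design$condition))
  control <- control %||% conds[1]
  treatment <- treatment %||% conds[2]
  if (!is.null(classifications)) {
    minor_ids <- classifications$intron_id[
      classifications$spliceosome_type == "minor"]
    introns <- introns |> dplyr::filter(.data$intron_id %in% minor_ids)
  }
  empty <- tibble(
    intron_id = character(), alt_start = integer(), alt_end = integer(),
    psi_alt_control = numeric(), psi_alt_treat = numeric(),
    delta_psi_alt = numeric(), p = numeric(), p_adj = numeric(),
    activated = logical()
  )
  if (nrow(introns) == 0L || nrow(junctions) == 0L) return(empty)

  cand <- introns |>
    select("intron_id", "contig", canon_start = "start",
           canon_end = "end") |>
    inner_join(junctions, by = "contig",
               relationship = "many-to-many") |>
    dplyr::filter(!(.data$start == .data$canon_start &
                      .data$end == .data$canon_end),
                  abs(.data$start - .data$canon_start) <= w |
                    abs(.data$end - .data$canon_end) <= w) |>
    distinct(.data$intron_id, .data$contig, .data$canon_start,
             .data$canon_end, alt_start = .data$start,
             alt_end = .data$end)
  if (nrow(cand) == 0L) return(empty)

  samples <- unique(design$sample_id)
  get_counts <- function(ctg, s, e) {
    j <- junctions |>
      dplyr::filter(.data$contig == .env$ctg, .data$start == .env$s,
                    .data$end == .env$e) |>
      select("sample_id", "count")
    setNames(j$count[match(samples, j$sample_id)], samples) |>
      tidyr::replace_na(0)
  }
  res <- purrr::pmap_dfr(cand, function(intron_id, contig, canon_start,
                                        canon_end, alt_start, alt_end) {
    j_alt <- get_counts(contig, alt_start, alt_end)
    j_can <- get_counts(contig, canon_start, canon_end)
    is_ctrl <- design$condition[match(samples, design$sample_id)] == control
    tot <- j_alt + j_can
    fit <- betabin_test(j_alt[is_ctrl], tot[is_ctrl],
                        j_alt[!is_ctrl], tot[!is_ctrl], rho = rho)
    pool <- function(sel) {
      if (sum(tot[sel]) > 0) sum(j_alt[sel]) / sum(tot[sel]) else NA_real_
    }
    tibble(intron_id = intron_id, alt_start = alt_start,
           alt_end = alt_end,
           psi_alt_control = pool(is_ctrl),
           psi_alt_treat = pool(!is_ctrl),
           delta_psi_alt = pool(!is_ctrl) - pool(is_ctrl),
           p = fit$p.value)
  })
  res |>
    mutate(p_adj = adjust_bh(.data$p),
           activated = !is.na(.data$delta_psi_alt) &
             .data$p_adj < alpha &
             abs(.data$delta_psi_alt) > dpsi_cutoff)
}
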