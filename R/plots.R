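#' Density plot of retention shifts by subtype
#'
#' Mirrors the usual presentation of differential intron retention:
#' per-subtype densities of delta-psi for minor A- and G-type introns.
#'
#' @param results Tibble from [test_differential_ir()].
#' @param classifications Tibble from [classify_introns()].
#' @return A ggplot object.
#' @export
plot_delta_psi <- function(results, classifications) {
  dat <- results |>
    inner_join(classifications |> select("intron_id", "spliceosome_type",
                                         "subtype"),
               by = "intron_id") |>
    dplyr::filter(.data$spliceosome_type == "minor",
                  .data$subtype %in% c("A", "G"),
                  !is.na(.data$delta_psi))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta_psi,
                                    fill = .data$subtype)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Delta * psi ~ "(treatment - control)"),
                  y = "density", fill = "subtype") +
    ggplot2::theme_minimal()
}

#' Heatmap of retention profiles in clustering order
#'
#' @param psi_matrix Introns x samples matrix of psi values.
#' @param clustering Optional result of [cluster_retention()]; computed
#'   if missing.
#' @return A ggplot object.
#' @export
plot_psi_heatmap <- function(psi_matrix, clustering = NULL) {
  clustering <- clustering %||% cluster_retention(psi_matrix)
  ord <- clustering$leaf_order
  dat <- as_tibble(psi_matrix[ord, , drop = FALSE], rownames = "intron_id") |>
    tidyr::pivot_longer(-"intron_id", names_to = "sample_id",
                        values_to = "psi") |>
    mutate(intron_id = factor(.data$intron_id, levels = rev(ord)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id,
                                    y = .data$intron_id,
                                    fill = .data$psi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(psi)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Presence/absence heatmap of top co-occurring genes
#'
#' @param profiles Profile tibble (`gene` + species columns).
#' @param results Tibble from [profile_correlation()].
#' @param top Number of top-ranked genes to show. Default 15.
#' @return A ggplot object.
#' @export
plot_profile_cooccurrence <- function(profiles, results, top = 15L) {
  genes <- head(results$gene, top)
  dat <- profiles |>
    dplyr::filter(.data$gene %in% genes) |>
    tidyr::pivot_longer(-"gene", names_to = "species",
                        values_to = "present") |>
    mutate(gene = factor(.data$gene, levels = rev(genes)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$species, y = .data$gene,
                                    fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "#2171b5"),
                               labels = c("absent", "present")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
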