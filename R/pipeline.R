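#' Run the full analysis pipeline
#'
#' Orchestrates intron extraction, minor/major classification, retention
#' quantification, read-support filtering, differential testing and
#' subtype summarising (plus, optionally, the co-occurrence screen) and
#' writes each stage's table as TSV into `out_dir` together with a JSON
#' manifest recording the package version, a hash of the configuration,
#' the seed and per-stage row counts. Reruns with an identical
#' configuration produce byte-identical TSVs.
#'
#' The configuration is a named list. Either supply
#' `simulate = TRUE` with an optional `sim` ([sim_config()]) to analyse a
#' synthetic data set, or supply paths `genome` (FASTA), `gtf`, and
#' either `sam` (character vector of per-sample SAM files, with
#' `design` = data frame or TSV path mapping `sample_id` to `condition`)
#' or `counts` (TSV with `intron_id`, `sample_id`, `J`, `B`, `R`, plus
#' `design`). Optional elements: thresholds `theta5` (0.07), `theta_bps`
#' (0.14), `min_junction` (5), `alpha` (0.05), `dpsi` (0.1), `anchor`
#' (8), `seed` (1), and `profiles`/`query` (TSV path and gene id) to run
#' the co-occurrence stage with `r_min` (0.5).
#'
#' @param config Named list, see Details.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stages <- list()
  t0 <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- if (is.data.frame(res)) nrow(res) else NA_integer_
    res
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  theta5 <- config$theta5 %||% 0.07
  theta_bps <- config$theta_bps %||% 0.14
  min_junction <- config$min_junction %||% 5
  alpha <- config$alpha %||% 0.05
  dpsi <- config$dpsi %||% 0.1
  anchor <- config$anchor %||% 8L

  if (isTRUE(config$simulate)) {
    sim <- config$sim %||% sim_config(seed = seed)
    gen <- t0("simulate_genome", simulate_genome(sim))
    genome <- gen$genome
    transcripts <- gen$transcripts
    cts <- simulate_counts(gen$truth, sim)
    counts_raw <- cts$counts
    design <- cts$design
    stages[["simulate_counts"]] <- nrow(counts_raw)
  } else {
    if (is.null(config$genome) || !file.exists(config$genome)) {
      stop("pipeline stage 'annotate' failed: genome FASTA not found: ",
           config$genome %||% "<missing>", call. = FALSE)
    }
    genome <- read_genome(config$genome)
    transcripts <- t0("read_annotation", read_annotation(config$gtf))
    design <- if (is.character(config$design)) {
      readr::read_tsv(config$design, col_types = "cc", progress = FALSE)
    } else {
      as_tibble(config$design)
    }
    counts_raw <- NULL
  }

  introns <- t0("introns", extract_introns(transcripts, genome))
  readr::write_tsv(introns, file.path(out_dir, "introns.tsv"))
  write_intron_bed(introns, file.path(out_dir, "introns.bed"))

  classifications <- t0("classify", classify_introns(
    introns, theta5 = theta5, theta_bps = theta_bps))
  readr::write_tsv(classifications,
                   file.path(out_dir, "classification.tsv"))

  if (is.null(counts_raw)) {
    if (!is.null(config$counts)) {
      counts_raw <- readr::read_tsv(config$counts, col_types = "cciii",
                                    progress = FALSE)
    } else {
      blocks <- bind_rows(lapply(config$sam, read_alignments))
      counts_raw <- count_intron_evidence(blocks, introns, k = anchor)
    }
    stages[["quantify"]] <- nrow(counts_raw)
  }
  readr::write_tsv(counts_raw, file.path(out_dir, "counts.tsv"))

  counts <- t0("filter", filter_introns(counts_raw, "junction",
                                        min_junction = min_junction))
  psi <- compute_psi(counts, design, mode = "boundary")
  readr::write_tsv(psi, file.path(out_dir, "psi.tsv"))
  stages[["psi"]] <- nrow(psi)

  diff <- t0("differential", test_differential_ir(
    counts, design, alpha = alpha, dpsi_cutoff = dpsi))
  readr::write_tsv(diff, file.path(out_dir, "differential.tsv"))

  summ <- t0("summarize", summarize_by_subtype(diff, classifications,
                                               affected = "ir"))
  readr::write_tsv(summ, file.path(out_dir, "subtype_summary.tsv"))

  if (!is.null(config$profiles)) {
    profiles <- read_profile_matrix(config$profiles)
    co <- t0("coevolve", profile_correlation(profiles, config$query))
    readr::write_tsv(co, file.path(out_dir, "cooccurrence.tsv"))
  }

  manifest <- list(
    package = "minorlens",
    version = as.character(utils::packageVersion("minorlens")),
    seed = seed,
    config_hash = rlang::hash(config),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
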