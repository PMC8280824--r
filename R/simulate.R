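#' Simulation configuration
#'
#' Collects the parameters of the synthetic study: a toy genome whose
#' genes carry minor A-type, minor G-type, major, and major AT-AC introns
#' with planted splice-site motifs, and a two-condition read-count design
#' with subtype-dependent retention shifts and overdispersed replicate
#' noise. The defaults encode the study conditions: baseline retention
#' around 0.10 for minor introns (control-cell psi of minor introns is of
#' order 0.08-0.13), treatment shifts of +0.36 for A-type and +0.07 for
#' G-type minor introns and none for major introns, three replicates per
#' condition, and negative-binomial coverage averaging 70 informative
#' units per replicate (about 200 pooled per condition).
#'
#' @param seed Integer seed; all generators are deterministic given the
#'   config.
#' @param n_minor_A,n_minor_G,n_major,n_major_atac Intron counts per
#'   class. Major AT-AC introns carry AT-AC terminal dinucleotides but
#'   major-type (non-U12) splice signals.
#' @param introns_per_gene Introns per simulated gene.
#' @param exon_length,intron_length Element lengths (nt);
#'   `intron_length` must be at least 60 so the branch-point window
#'   never collides with the donor motif.
#' @param baseline_psi,delta_psi Named numeric vectors over classes
#'   `minor_A`, `minor_G`, `major`, `major_atac`: control retention and
#'   treatment shift (clipped to [0, 1]).
#' @param coverage_mean,coverage_size Negative-binomial mean and size
#'   (dispersion) of per-replicate informative coverage.
#' @param rho Beta-binomial intra-replicate correlation of retained
#'   counts. Default 0.02.
#' @param n_control,n_treatment Replicates per condition. Default 3.
#' @param read_length Read length for SAM emission. Default 50.
#' @param contig Contig name of the toy genome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_minor_A = 25L, n_minor_G = 25L,
                       n_major = 180L, n_major_atac = 20L,
                       introns_per_gene = 3L, exon_length = 100L,
                       intron_length = 120L,
                       baseline_psi = c(minor_A = 0.10, minor_G = 0.10,
                                        major = 0.02, major_atac = 0.02),
                       delta_psi = c(minor_A = 0.36, minor_G = 0.07,
                                     major = 0, major_atac = 0),
                       coverage_mean = 70, coverage_size = 8,
                       rho = 0.02, n_control = 3L, n_treatment = 3L,
                       read_length = 50L, contig = "chrS") {
  classes <- c("minor_A", "minor_G", "major", "major_atac")
  stopifnot(
    all(classes %in% names(baseline_psi)),
    all(classes %in% names(delta_psi)),
    all(baseline_psi >= 0 & baseline_psi <= 1),
    intron_length >= 60L, exon_length >= read_length,
    introns_per_gene >= 1L, n_control >= 1L, n_treatment >= 1L,
    rho >= 0, rho < 1, coverage_mean > 0
  )
  structure(
    list(seed = as.integer(seed), n_minor_A = n_minor_A,
         n_minor_G = n_minor_G, n_major = n_major,
         n_major_atac = n_major_atac, introns_per_gene = introns_per_gene,
         exon_length = exon_length, intron_length = intron_length,
         baseline_psi = baseline_psi[classes],
         delta_psi = delta_psi[classes],
         coverage_mean = coverage_mean, coverage_size = coverage_size,
         rho = rho, n_control = n_control, n_treatment = n_treatment,
         read_length = read_length, contig = contig),
    class = "sim_config"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Planted motifs: the U12 consensus for minor introns (scores exactly 1
# under the bundled matrices); major donors follow the major-spliceosome
# consensus and carry no U12 signal.
planted_donors <- function(class) {
  switch(class,
    minor_A = "ATATCCTTT",
    minor_G = "GTATCCTTT",
    major = c("GTAAGTGGG", "GTAAGTAAG", "GTGAGTGAG"),
    major_atac = NA_character_
  )
}
planted_bps <- function() "TTCCTTAAC"

# Build one transcribed intron sequence of the given class; returns the
# sequence and the planted branch-point offset (NA for major classes).
make_intron_seq <- function(class, len, bps_len = 9L) {
  terminal <- switch(class,
    minor_A = "AC", minor_G = "AG", major = "AG", major_atac = "AC")
  donor <- switch(class,
    major_atac = paste0("AT", random_dna(7L)),
    sample(planted_donors(class), 1L)
  )
  mid_len <- len - nchar(donor) - 2L
  body <- random_dna(mid_len)
  offset <- NA_integer_
  if (class %in% c("minor_A", "minor_G")) {
    # plant a branch point wholly inside the -40..-3 window
    offset <- -sample(seq.int(bps_len + 2L, 40L), 1L)
    bps <- sample(planted_bps(), 1L)
    # 1-based position in the full intron of the window start
    p <- len + offset + 1L
    rel <- p - nchar(donor)  # position within `body`
    substr(body, rel, rel + bps_len - 1L) <- bps
  }
  list(seq = paste0(donor, body, terminal), bps_offset = offset)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a toy genome with planted intron classes
#'
#' Generates a single-contig genome whose genes (alternating strand)
#' carry introns of four classes: minor A-type (AT..AC with planted
#' U12-type 5'ss and branch-point motifs), minor G-type (GT..AG with the
#' same planted signals), major (GT..AG with a major-type donor and no
#' U12 signals) and major AT-AC (AT..AC terminal dinucleotides but random
#' internal sequence). Class labels are assigned to gene intron slots in
#' a seeded random order. Deterministic for a fixed config.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (DNAStringSet), `transcripts` (exon tibble
#'   as from [read_annotation()]), and `truth` (tibble per intron:
#'   `intron_id`, genomic coordinates, `host_gene`, `class`, `subtype`,
#'   `psi_control`, `psi_treatment`, `bps_offset`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- c(rep("minor_A", config$n_minor_A),
               rep("minor_G", config$n_minor_G),
               rep("major", config$n_major),
               rep("major_atac", config$n_major_atac))
  n_intron <- length(classes)
  if (n_intron == 0L) stop("config contains no introns", call. = FALSE)
  classes <- sample(classes)
  n_genes <- ceiling(n_intron / config$introns_per_gene)
  el <- config$exon_length; il <- config$intron_length
  spacer <- 100L

  seqs <- character(0)
  tr_rows <- list(); truth_rows <- list()
  offset <- 0L; ci <- 1L
  for (g in seq_len(n_genes)) {
    k <- min(config$introns_per_gene, n_intron - ci + 1L)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("gene%03d", g)
    gene_classes <- classes[ci:(ci + k - 1L)]
    ci <- ci + k
    introns <- lapply(gene_classes, function(cl) make_intron_seq(cl, il))
    exons <- replicate(k + 1L, random_dna(el))
    pieces <- character(2L * k + 1L)
    pieces[seq(1L, 2L * k + 1L, by = 2L)] <- exons
    pieces[seq(2L, 2L * k, by = 2L)] <- vapply(introns, `[[`, "", "seq")
    tseq <- paste(pieces, collapse = "")
    L <- nchar(tseq)
    gseq <- if (strand == "+") tseq else revcomp_chr(tseq)
    gene_off <- offset + spacer
    # transcribed-coordinate element boundaries
    t_starts <- cumsum(c(0L, rep(c(el, il), k)))
    ex_t <- cbind(t_starts[seq(1L, 2L * k + 1L, by = 2L)],
                  t_starts[seq(1L, 2L * k + 1L, by = 2L)] + el)
    in_t <- cbind(t_starts[seq(2L, 2L * k, by = 2L)],
                  t_starts[seq(2L, 2L * k, by = 2L)] + il)
    to_genomic <- function(t0, t1) {
      if (strand == "+") c(gene_off + t0, gene_off + t1)
      else c(gene_off + L - t1, gene_off + L - t0)
    }
    ex_g <- t(apply(ex_t, 1L, function(z) to_genomic(z[1], z[2])))
    in_g <- t(apply(in_t, 1L, function(z) to_genomic(z[1], z[2])))
    tr_rows[[g]] <- tibble(
      transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
      contig = config$contig, strand = strand,
      exon_start = as.integer(ex_g[, 1]), exon_end = as.integer(ex_g[, 2])
    )
    psi0 <- config$baseline_psi[gene_classes]
    psi1 <- pmin(1, pmax(0, psi0 + config$delta_psi[gene_classes]))
    truth_rows[[g]] <- tibble(
      intron_id = intron_key(config$contig, as.integer(in_g[, 1]),
                             as.integer(in_g[, 2]), strand),
      contig = config$contig,
      start = as.integer(in_g[, 1]), end = as.integer(in_g[, 2]),
      strand = strand, host_gene = gene_id,
      intron_index = seq_len(k),
      class = gene_classes,
      subtype = dplyr::case_when(gene_classes == "minor_A" ~ "A",
                                 gene_classes == "minor_G" ~ "G",
                                 TRUE ~ "not_applicable"),
      psi_control = unname(psi0), psi_treatment = unname(psi1),
      bps_offset = vapply(introns, function(x) as.numeric(x$bps_offset),
                          numeric(1))
    )
    seqs <- c(seqs, random_dna(spacer), gseq)
    offset <- gene_off + L
  }
  seqs <- c(seqs, random_dna(spacer))
  genome <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(genome) <- config$contig
  list(genome = genome,
       transcripts = bind_rows(tr_rows) |>
         arrange(.data$transcript_id, .data$exon_start),
       truth = bind_rows(truth_rows))
}

#' Simulate two-condition retention counts
#'
#' Per intron and replicate, informative coverage `n` is drawn from a
#' negative binomial and the retained count `r` from a beta-binomial with
#' the intron's true condition psi and intra-replicate correlation `rho`
#' (biological replicate overdispersion). Counts are emitted in the
#' boundary/junction parameterization: `J = n - r` spliced junction
#' reads, `B = 2 r` boundary reads (a retained molecule presents two
#' exon-intron boundaries) and `R = r` intron-body reads. Deterministic
#' for a fixed config.
#'
#' @param truth Truth tibble from [simulate_genome()] (needs `intron_id`,
#'   `psi_control`, `psi_treatment`).
#' @param config A [sim_config()].
#' @return List with `counts` (`intron_id`, `sample_id`, `J`, `B`, `R`)
#'   and `design` (`sample_id`, `condition`).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  design <- tibble(
    sample_id = c(sprintf("control_%d", seq_len(config$n_control)),
                  sprintf("treatment_%d", seq_len(config$n_treatment))),
    condition = c(rep("control", config$n_control),
                  rep("treatment", config$n_treatment))
  )
  draw <- function(psi) {
    n <- rnbinom(1L, mu = config$coverage_mean, size = config$coverage_size)
    p <- psi
    if (config$rho > 0 && psi > 0 && psi < 1) {
      a <- psi * (1 - config$rho) / config$rho
      b <- (1 - psi) * (1 - config$rho) / config$rho
      p <- rbeta(1L, a, b)
    }
    r <- rbinom(1L, n, p)
    c(n = n, r = r)
  }
  grid <- tidyr::expand_grid(
    truth |> select("intron_id", "psi_control", "psi_treatment"),
    design
  )
  nr <- t(vapply(seq_len(nrow(grid)), function(i) {
    psi <- if (grid$condition[i] == "control") grid$psi_control[i]
           else grid$psi_treatment[i]
    draw(psi)
  }, c(n = 0, r = 0)))
  counts <- grid |>
    mutate(J = as.integer(nr[, "n"] - nr[, "r"]),
           B = as.integer(2L * nr[, "r"]),
           R = as.integer(nr[, "r"])) |>
    select("intron_id", "sample_id", "J", "B", "R")
  list(counts = counts, design = design)
}

#' Realize simulated counts as SAM alignments
#'
#' Writes one SAM file per sample whose gapped alignments reproduce the
#' simulated evidence exactly: `J` junction reads spliced at the intron
#' boundaries, `B / 2` reads crossing each exon-intron boundary, and `R`
#' reads fully inside the intron, all with at least `k` aligned nt on
#' each side of any junction or boundary. Read starts are uniform within
#' the anchor constraints; no sequencing error is modelled.
#'
#' @param counts,design From [simulate_counts()].
#' @param truth Truth tibble from [simulate_genome()] (intron
#'   coordinates).
#' @param genome Toy genome from [simulate_genome()].
#' @param config The [sim_config()].
#' @param dir Output directory (created if needed).
#' @param k Anchor length. Default 8.
#' @return Named character vector of SAM paths, one per sample.
#' @export
simulate_sam <- function(counts, design, truth, genome, config, dir,
                         k = 8L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- config$read_length
  stopifnot(L >= 2L * k)
  contig_seq <- as.character(genome[[config$contig]])
  clen <- nchar(contig_seq)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", config$contig, "\tLN:", clen))
  fetch <- function(p0, len) substr(contig_seq, p0 + 1L, p0 + len)
  paths <- setNames(character(nrow(design)), design$sample_id)
  dat <- counts |>
    inner_join(truth |> select("intron_id", "start", "end"),
               by = "intron_id")
  for (s in design$sample_id) {
    ds <- dat |> dplyr::filter(.data$sample_id == s)
    recs <- character(0); rid <- 0L
    for (i in seq_len(nrow(ds))) {
      st <- ds$start[i]; en <- ds$end[i]; glen <- en - st
      # junction reads
      if (ds$J[i] > 0L) {
        a <- sample(seq.int(k, L - k), ds$J[i], replace = TRUE)
        for (aa in a) {
          rid <- rid + 1L
          pos0 <- st - aa
          cig <- paste0(aa, "M", glen, "N", L - aa, "M")
          seq <- paste0(fetch(pos0, aa), fetch(en, L - aa))
          recs <- c(recs, sam_line(sprintf("%s_r%06d", s, rid),
                                   config$contig, pos0, cig, seq))
        }
      }
      # boundary reads, B/2 per boundary
      nb <- ds$B[i] %/% 2L
      for (b in c(st, en)) {
        if (nb > 0L) {
          ell <- sample(seq.int(k, L - k), nb, replace = TRUE)
          for (e1 in ell) {
            rid <- rid + 1L
            pos0 <- b - e1
            recs <- c(recs, sam_line(sprintf("%s_r%06d", s, rid),
                                     config$contig, pos0,
                                     paste0(L, "M"), fetch(pos0, L)))
          }
        }
      }
      # intron-body reads
      if (ds$R[i] > 0L && glen >= L) {
        pos <- sample(seq.int(st, en - L), ds$R[i], replace = TRUE)
        for (p0 in pos) {
          rid <- rid + 1L
          recs <- c(recs, sam_line(sprintf("%s_r%06d", s, rid),
                                   config$contig, p0,
                                   paste0(L, "M"), fetch(p0, L)))
        }
      }
    }
    path <- file.path(dir, paste0(s, ".sam"))
    writeLines(c(header, recs), path)
    paths[s] <- path
  }
  paths
}

sam_line <- function(qname, contig, pos0, cigar, seq) {
  paste(qname, 0L, contig, pos0 + 1L, 60L, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}

#' Simulate phylogenetic profiles with a planted co-occurring module
#'
#' One random loss/retention pattern over species is shared by all
#' `module_size` module genes (the query gene is the first of them);
#' every other gene receives an independent random profile. Each matrix
#' entry is then flipped with probability `flip_prob`. Deterministic for
#' a fixed seed.
#'
#' @param n_genes Total genes (module included). Default 200.
#' @param n_species Number of species. Default 60.
#' @param module_size Planted module size (>= 1). Default 10.
#' @param flip_prob Per-entry flip probability. Default 0.05.
#' @param seed Integer seed.
#' @return List with `profiles` (tibble: `gene` + one 0/1 column per
#'   species), `truth` (tibble `gene`, `in_module`) and `query` (the
#'   query gene id, a module member).
#' @export
simulate_profiles <- function(n_genes = 200L, n_species = 60L,
                              module_size = 10L, flip_prob = 0.05,
                              seed = 1L) {
  stopifnot(module_size >= 1L, module_size <= n_genes, n_species >= 2L)
  set.seed(seed)
  base <- rbinom(n_species, 1L, 0.5)
  while (length(unique(base)) == 1L) base <- rbinom(n_species, 1L, 0.5)
  mat <- matrix(rbinom(n_genes * n_species, 1L, 0.5),
                nrow = n_genes, ncol = n_species)
  mat[seq_len(module_size), ] <- matrix(rep(base, each = module_size),
                                        nrow = module_size)
  if (flip_prob > 0) {
    flips <- matrix(rbinom(n_genes * n_species, 1L, flip_prob),
                    nrow = n_genes)
    mat <- (mat + flips) %% 2L
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  profiles <- as_tibble(mat, .name_repair = ~ sprintf("sp%03d",
                                                      seq_len(n_species)))
  profiles <- bind_cols(tibble(gene = genes), profiles)
  list(profiles = profiles,
       truth = tibble(gene = genes,
                      in_module = seq_len(n_genes) <= module_size),
       query = genes[1])
}

#' Write transcripts as GTF
#'
#' Writes exon features (1-based inclusive coordinates) with `gene_id`
#' and `transcript_id` attributes.
#'
#' @param transcripts Exon tibble (columns as from [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  lines <- transcripts |>
    arrange(.data$transcript_id, .data$exon_start) |>
    mutate(line = paste(
      .data$contig, "minorlens", "exon",
      .data$exon_start + 1L, .data$exon_end, ".", .data$strand, ".",
      paste0("gene_id \"", .data$gene_id, "\"; transcript_id \"",
             .data$transcript_id, "\";"),
      sep = "\t")) |>
    pull("line")
  writeLines(lines, path)
  invisible(path)
}
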