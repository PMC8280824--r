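# In-code fixtures shared across test files.

write_fasta_tmp <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}

gtf_line <- function(contig, start1, end1, strand, gene, tx,
                     feature = "exon") {
  paste(contig, "test", feature, start1, end1, ".", strand, ".",
        paste0("gene_id \"", gene, "\"; transcript_id \"", tx, "\";"),
        sep = "\t")
}

write_gtf_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_sam_tmp <- function(records, contig = "chr1", contig_len = 100000L) {
  path <- withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:", contig, "\tLN:", contig_len),
               records), path)
  path
}

# Minimal SAM record; pos0 is 0-based.
sam_rec <- function(qname, pos0, cigar, flag = 0L, contig = "chr1") {
  paste(qname, flag, contig, pos0 + 1L, 60L, cigar, "*", 0L, 0L, "*", "*",
        sep = "\t")
}

# A bare intron-catalog row for counting tests (no sequences needed).
intron_row <- function(contig, start, end, strand = "+", gene = "g1",
                       index = 1L) {
  tibble::tibble(
    intron_id = intron_key(contig, start, end, strand),
    contig = contig, start = start, end = end, strand = strand,
    host_gene = gene, intron_index = index
  )
}

# Independent brute-force branch-point scan used as an oracle: scores
# every window of the -40..-3 region by direct per-position lookup.
brute_force_bps <- function(pwm, region) {
  m <- pwm$motif_length
  if (nchar(region) > 40L) {
    region <- substr(region, nchar(region) - 39L, nchar(region))
  }
  L <- nchar(region)
  if (L < m + 2L) return(list(score = 0, offset = NA_real_))
  best <- -Inf; best_off <- NA_real_
  for (s in seq.int(-L, -(m + 2L))) {
    w <- substr(region, L + s + 1L, L + s + m)
    sc <- score_sequence(pwm, w)
    if (sc >= best) {  # >= keeps the window closest to the 3'ss on ties
      best <- sc; best_off <- s
    }
  }
  list(score = best, offset = best_off)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent binomial likelihood-ratio oracle for the rho = 0 path of
# the beta-binomial test.
oracle_binom_lrt_p <- function(rc, nc, rt, nt) {
  ll <- function(r, n) {
    r <- sum(r); n <- sum(n)
    if (n == 0) return(0)
    p <- r / n
    out <- 0
    if (r > 0) out <- out + r * log(p)
    if (n - r > 0) out <- out + (n - r) * log(1 - p)
    out
  }
  stat <- 2 * (ll(rc, nc) + ll(rt, nt) - ll(c(rc, rt), c(nc, nt)))
  pchisq(max(0, stat), df = 1, lower.tail = FALSE)
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all group
# labelings of the pooled sample.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(m))
  centre <- m * (N - m) / 2
  combos <- utils::combn(N, m)
  us <- apply(combos, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Direct 2x2 phi coefficient, the oracle for profile correlations.
oracle_phi <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

profiles_from_matrix <- function(mat, genes) {
  dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(mat,
                      .name_repair = ~ paste0("sp", seq_len(ncol(mat))))
  )
}
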