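test_that("read_genome loads records, upper-cases and validates", {
  path <- write_fasta_tmp(list(chr1 = "ACGT", chr2 = "acgT"))
  g <- read_genome(path)
  expect_setequal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGT")
  expect_equal(as.character(g[["chr2"]]), "ACGT")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">chr1"), bad)
  expect_error(read_genome(bad), "line 1")
})

test_that("genome_fetch is strand-aware with 0-based half-open intervals", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTT"))
  expect_equal(genome_fetch(g, "chr1", 0, 4, "+"), "AACC")
  expect_equal(genome_fetch(g, "chr1", 0, 4, "-"), "GGTT")
  expect_equal(genome_fetch(g, "chr1", 1, 5, "-"), "CGGT")
  expect_error(genome_fetch(g, "chr1", 0, 9, "+"), "outside contig")
  expect_error(genome_fetch(g, "chrX", 0, 2, "+"), "absent")
})

test_that("read_annotation converts GTF 1-based to 0-based half-open", {
  path <- write_gtf_tmp(c(
    gtf_line("chr1", 1, 100, "+", "gA", "tx1"),
    gtf_line("chr1", 201, 300, "+", "gA", "tx1")
  ))
  tr <- read_annotation(path)
  expect_equal(tr$exon_start, c(0L, 200L))
  expect_equal(tr$exon_end, c(100L, 300L))
  expect_equal(unique(tr$gene_id), "gA")
})

test_that("transcripts of one gene may share exons; exotic GTFs error or warn", {
  path <- write_gtf_tmp(c(
    gtf_line("chr1", 1, 100, "+", "gA", "tx1"),
    gtf_line("chr1", 1, 100, "+", "gA", "tx2"),
    gtf_line("chr1", 201, 260, "+", "gA", "tx2")
  ))
  tr <- read_annotation(path)
  expect_equal(sort(unique(tr$transcript_id)), c("tx1", "tx2"))
  expect_equal(unique(tr$gene_id), "gA")

  gene_only <- write_gtf_tmp(
    gtf_line("chr1", 1, 500, "+", "gA", "tx1", feature = "gene"))
  expect_warning(empty <- read_annotation(gene_only), "no exon")
  expect_equal(nrow(empty), 0L)

  overlapping <- write_gtf_tmp(c(
    gtf_line("chr1", 1, 100, "+", "gA", "tx1"),
    gtf_line("chr1", 50, 200, "+", "gA", "tx1")
  ))
  expect_error(read_annotation(overlapping), "overlapping")

  no_tx <- write_gtf_tmp(paste(
    "chr1", "test", "exon", 1, 100, ".", "+", ".", "gene_id \"gA\";",
    sep = "\t"))
  expect_error(read_annotation(no_tx), "transcript_id")
})

test_that("extract_introns finds the gap with its terminal dinucleotides", {
  # plus strand: exons [0,60), [100,160); intron [60,100) reads GT..AG
  intron_seq <- paste0("GT", strrep("C", 36), "AG")
  seq <- paste0(strrep("A", 60), intron_seq, strrep("A", 60))
  g <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  tr <- tibble::tibble(
    transcript_id = "tx1", gene_id = "gA", contig = "chr1", strand = "+",
    exon_start = c(0L, 100L), exon_end = c(60L, 160L)
  )
  introns <- extract_introns(tr, g)
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$start, 60L)
  expect_equal(introns$end, 100L)
  expect_equal(introns$donor_dinucleotide, "GT")
  expect_equal(introns$acceptor_dinucleotide, "AG")
  expect_equal(introns$terminal_label, "GT-AG")
  expect_equal(introns$intron_index, 1L)
  expect_equal(nchar(introns$three_prime_region_seq), 40L)
})

test_that("minus-strand introns are extracted in transcribed orientation", {
  # transcribed: exon1 (10) + intron AT..AC (34) + exon2 (10)
  intron_tx <- paste0("AT", strrep("G", 30), "AC")
  transcribed <- paste0(strrep("C", 10), intron_tx, strrep("C", 10))
  genome_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(transcribed)))
  g <- Biostrings::DNAStringSet(setNames(genome_seq, "chr1"))
  L <- nchar(transcribed)
  tr <- tibble::tibble(
    transcript_id = "tx1", gene_id = "gA", contig = "chr1", strand = "-",
    exon_start = c(0L, L - 10L), exon_end = c(10L, L)
  )
  introns <- extract_introns(tr, g)
  expect_equal(introns$terminal_label, "AT-AC")
  expect_equal(introns$donor_region_seq,
               substr(intron_tx, 1, 9))
  expect_equal(introns$three_prime_region_seq,
               substr(intron_tx, 34 - 39, 34))
})

test_that("shared introns are deduplicated across transcripts", {
  intron_seq <- paste0("GT", strrep("C", 36), "AG")
  seq <- paste0(strrep("A", 60), intron_seq, strrep("A", 60))
  g <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  tr <- dplyr::bind_rows(lapply(c("tx1", "tx2", "tx3"), function(tx) {
    tibble::tibble(transcript_id = tx, gene_id = "gA", contig = "chr1",
                   strand = "+", exon_start = c(0L, 100L),
                   exon_end = c(60L, 160L))
  }))
  introns <- extract_introns(tr, g)
  expect_equal(nrow(introns), 1L)
})

test_that("short introns are skipped with a warning", {
  seq <- strrep("A", 200)
  g <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  tr <- tibble::tibble(
    transcript_id = "tx1", gene_id = "gA", contig = "chr1", strand = "+",
    exon_start = c(0L, 70L), exon_end = c(50L, 120L)  # 20 nt gap
  )
  expect_warning(introns <- extract_introns(tr, g), "shorter")
  expect_equal(nrow(introns), 0L)
})

test_that("exons and introns tile each transcript exactly once", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_minor_A = 4L, n_minor_G = 4L,
                    n_major = 8L, n_major_atac = 2L)
  gen <- simulate_genome(cfg)
  introns <- extract_introns(gen$transcripts, gen$genome)
  for (tx in unique(gen$transcripts$transcript_id)) {
    ex <- gen$transcripts[gen$transcripts$transcript_id == tx, ]
    gaps <- introns[introns$host_gene == ex$gene_id[1], ]
    ivs <- rbind(cbind(ex$exon_start, ex$exon_end),
                 cbind(gaps$start, gaps$end))
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    expect_equal(ivs[1, 1], min(ex$exon_start))
    expect_equal(ivs[nrow(ivs), 2], max(ex$exon_end))
    if (nrow(ivs) > 1) {
      expect_equal(ivs[-1, 1], ivs[-nrow(ivs), 2])
    }
  }
})

test_that("transcribed intron sequences are invariant to strand mirroring", {
  # a construct and its reverse-complemented, coordinate-mirrored copy
  intron_tx <- paste0("GT", strrep("A", 20), "TTCCTTAAC",
                      strrep("G", 5), "AG")
  transcribed <- paste0(strrep("C", 20), intron_tx, strrep("T", 20))
  L <- nchar(transcribed)
  g_plus <- Biostrings::DNAStringSet(setNames(transcribed, "chr1"))
  g_minus <- Biostrings::DNAStringSet(setNames(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(transcribed))), "chr1"))
  tr_plus <- tibble::tibble(
    transcript_id = "tx1", gene_id = "gA", contig = "chr1", strand = "+",
    exon_start = c(0L, L - 20L), exon_end = c(20L, L))
  tr_minus <- tr_plus
  tr_minus$strand <- "-"
  a <- extract_introns(tr_plus, g_plus)
  b <- extract_introns(tr_minus, g_minus)
  expect_equal(a$donor_region_seq, b$donor_region_seq)
  expect_equal(a$three_prime_region_seq, b$three_prime_region_seq)
  expect_equal(a$terminal_label, b$terminal_label)
})

test_that("BED round trip preserves intron intervals", {
  cfg <- sim_config(seed = 5, n_minor_A = 3L, n_minor_G = 3L,
                    n_major = 6L, n_major_atac = 0L)
  gen <- simulate_genome(cfg)
  introns <- extract_introns(gen$transcripts, gen$genome)
  path <- withr::local_tempfile(fileext = ".bed")
  write_intron_bed(introns, path)
  back <- read_intron_bed(path)
  expect_equal(
    sort(intron_key(back$contig, back$start, back$end, back$strand)),
    sort(introns$intron_id)
  )
})
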