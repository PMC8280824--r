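#' Build a position weight matrix from aligned k-mers
#'
#' Per-position base probabilities are estimated from an alignment of
#' equal-length sequences with pseudocount smoothing:
#' `probs[base, pos] = (count + pseudocount) / (n + 4 * pseudocount)`.
#' An `N` in the input distributes 1/4 of a count to each base.
#'
#' @param sequences Character vector of equal-length DNA k-mers over
#'   `{A,C,G,T,N}`.
#' @param pseudocount Non-negative smoothing constant added per base.
#'   Default 0.25.
#' @param label Optional label, e.g. `"five_prime_ss"` or `"branch_point"`.
#' @return An object of class `splice_pwm`: a list with `probs`
#'   (4 x L matrix, rows A/C/G/T), `motif_length` and `label`.
#' @export
build_pwm <- function(sequences, pseudocount = 0.25,
                      label = "five_prime_ss") {
  if (length(sequences) == 0L) stop("no training sequences", call. = FALSE)
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("training sequences have ragged lengths: ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  }
  L <- lens[1]
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  nrow = length(sequences), ncol = L, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid base(s) in training sequences: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(L), function(j) {
    col <- chars[, j]
    ct <- vapply(bases, function(b) sum(col == b), numeric(1))
    ct + sum(col == "N") / 4  # N spread uniformly
  }, numeric(4))
  probs <- (counts + pseudocount) / (length(sequences) + 4 * pseudocount)
  rownames(probs) <- bases
  structure(list(probs = probs, motif_length = L, label = label),
            class = "splice_pwm")
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat("<splice_pwm> label=", x$label, " length=", x$motif_length, "\n",
      sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' Score a sequence against a PWM
#'
#' The score is the normalized likelihood ratio
#' `prod(probs[seq[pos], pos]) / prod(max(probs[, pos]))`, which is 1 for
#' any per-position-argmax (consensus) sequence and lies in (0, 1]
#' elsewhere. An `N` contributes the 0.25 background probability in the
#' numerator.
#'
#' @param pwm A `splice_pwm` from [build_pwm()].
#' @param seq Character vector of sequences, each of the motif length.
#' @return Numeric vector of scores in (0, 1].
#' @export
score_sequence <- function(pwm, seq) {
  stopifnot(inherits(pwm, "splice_pwm"))
  seq <- toupper(seq)
  if (any(nchar(seq) != pwm$motif_length)) {
    stop("sequence length differs from motif length ", pwm$motif_length,
         call. = FALSE)
  }
  maxlog <- sum(log(apply(pwm$probs, 2, max)))
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    p <- vapply(seq_along(ch), function(j) {
      if (ch[j] == "N") 0.25 else {
        pr <- pwm$probs[ch[j], j]
        if (is.na(pr)) stop("invalid base '", ch[j], "' in sequence ", s,
                            call. = FALSE)
        pr
      }
    }, numeric(1))
    exp(sum(log(p)) - maxlog)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan the branch-point window of an intron
#'
#' Scores every motif-length window of the intron's 3'-terminal region
#' whose bases all lie within transcribed positions -40..-3 (offset -1 is
#' the last intronic base), and returns the best score with its window
#' start offset. Ties are broken in favour of the window closest to the
#' 3' splice site. A region too short for any window yields score 0 and
#' an `NA` offset, so the intron cannot be called minor by scoring.
#'
#' @param pwm `splice_pwm` for the branch point (motif length <= 38).
#' @param region Character vector of 3'-terminal intronic sequences
#'   (each at most 40 nt; the last character is offset -1).
#' @return Tibble with one row per region: `bps_score`, `bps_offset`.
#' @export
scan_branch_point <- function(pwm, region) {
  stopifnot(inherits(pwm, "splice_pwm"))
  m <- pwm$motif_length
  if (m > 38L) stop("branch-point motif longer than the -40..-3 window",
                    call. = FALSE)
  maxlog <- sum(log(apply(pwm$probs, 2, max)))
  logp <- log(pwm$probs)
  one <- function(seq) {
    if (nchar(seq) > 40L) {  # keep the 40 nt nearest the 3'ss
      seq <- substr(seq, nchar(seq) - 39L, nchar(seq))
    }
    L <- nchar(seq)
    # window start offsets s (relative to 3'ss) with s >= -L and
    # window end s + m - 1 <= -3
    if (L < m + 2L) {
      return(c(score = 0, offset = NA_real_))
    }
    starts <- seq.int(from = -L, to = -(m + 2L))
    ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    scores <- vapply(starts, function(s) {
      idx <- (L + s + 1L):(L + s + m)  # 1-based positions in region
      w <- ch[idx]
      lp <- vapply(seq_len(m), function(j) {
        if (w[j] == "N") log(0.25) else logp[w[j], j]
      }, numeric(1))
      exp(sum(lp) - maxlog)
    }, numeric(1))
    best <- max(scores)
    # tie-break: window closest to the 3'ss = largest start offset
    c(score = best, offset = starts[max(which(scores == best))])
  }
  res <- t(vapply(region, one, c(score = 0, offset = 0), USE.NAMES = FALSE))
  tibble(bps_score = res[, 1L], bps_offset = res[, 2L])
}

#' Bundled U12-type training alignments
#'
#' Small curated alignments of U12-type 5' splice-site and branch-point
#' consensus variants, used to build the default scoring matrices. The 5'
#' splice-site set covers both AT- and GT/GC-initiated donors over the
#' extended `RTATCCTTT`-like consensus; the branch-point set covers
#' `TTCCTTAAC`-like variants with the branch adenosine at position 8.
#' Users with organism-specific alignments should supply their own via
#' [build_pwm()].
#'
#' @return Named list with character vectors `five_prime_ss` (9-mers) and
#'   `branch_point` (9-mers).
#' @export
u12_training_sets <- function() {
  list(
    five_prime_ss = c(
      "ATATCCTTT", "ATATCCTTT", "ATATCCTTT", "ATATCCTTC",
      "ATATCCTTA", "ATATCTTTT", "ATACCCTTT",
      "GTATCCTTT", "GTATCCTTT", "GTATCCTTT", "GTATCCTTC",
      "GTATCCTTA", "GTATCTTTT",
      "GCATCCTTT", "ATATCCTTG", "GTATCCCTT"
    ),
    branch_point = c(
      "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAT",
      "TTCCTTGAC", "TTCCTCAAC", "TTTCTTAAC", "CTCCTTAAC",
      "TCCCTTAAC", "TTCCTTAAG", "TTACTTAAC", "TTCTTTAAC"
    )
  )
}

#' Default U12 scoring matrices
#'
#' @param pseudocount Passed to [build_pwm()].
#' @return List with elements `five_prime_ss` and `branch_point`, each a
#'   `splice_pwm` built from [u12_training_sets()].
#' @export
u12_default_pwms <- function(pseudocount = 0.25) {
  tr <- u12_training_sets()
  list(
    five_prime_ss = build_pwm(tr$five_prime_ss, pseudocount,
                              label = "five_prime_ss"),
    branch_point = build_pwm(tr$branch_point, pseudocount,
                             label = "branch_point")
  )
}
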