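#' Classify introns as minor (U12-type) or major (U2-type)
#'
#' Scores each intron's 5' splice site and branch point against position
#' weight matrices and calls an intron *minor* when both scores reach
#' their thresholds (defaults 0.07 for the 5'ss and 0.14 for the branch
#' point) or when the intron appears on a user-supplied allowlist of
#' previously established minor introns. Minor introns are subtyped by
#' their donor dinucleotide: `AT` gives the A-type (AT-AN) class, `GT` or
#' `GC` the G-type class. Terminal dinucleotides alone never decide the
#' spliceosome type: AT-AC introns with major-like splice signals stay
#' major.
#'
#' @param introns Intron catalog from [extract_introns()].
#' @param pwm5,pwm_bps `splice_pwm` objects for the 5' splice site and
#'   branch point; default [u12_default_pwms()].
#' @param theta5,theta_bps Minimum 5'ss and branch-point scores for a
#'   scored minor call. Defaults 0.07 and 0.14.
#' @param allowlist Optional tibble with `contig`, `start`, `end`,
#'   `strand` of introns to force-call minor. Entries absent from the
#'   catalog are skipped with a warning.
#' @return Tibble with `intron_id`, `s5`, `s_bps`, `bps_offset`,
#'   `spliceosome_type` (`"minor"`/`"major"`), `subtype` (`"A"`, `"G"` or
#'   `"not_applicable"`), `terminal_label`, `source` (`"scored"` or
#'   `"allowlist"`).
#' @export
classify_introns <- function(introns, pwm5 = NULL, pwm_bps = NULL,
                             theta5 = 0.07, theta_bps = 0.14,
                             allowlist = NULL) {
  if (is.null(pwm5) || is.null(pwm_bps)) {
    pwms <- u12_default_pwms()
    pwm5 <- pwm5 %||% pwms$five_prime_ss
    pwm_bps <- pwm_bps %||% pwms$branch_point
  }
  if (nrow(introns) == 0L) {
    return(tibble(
      intron_id = character(), s5 = numeric(), s_bps = numeric(),
      bps_offset = numeric(), spliceosome_type = character(),
      subtype = character(), terminal_label = character(),
      source = character()
    ))
  }
  donor_seq <- substr(introns$donor_region_seq, 1L, pwm5$motif_length)
  scorable <- nchar(donor_seq) == pwm5$motif_length
  s5 <- rep(0, nrow(introns))
  s5[scorable] <- score_sequence(pwm5, donor_seq[scorable])
  bps <- scan_branch_point(pwm_bps, introns$three_prime_region_seq)

  allowed <- rep(FALSE, nrow(introns))
  if (!is.null(allowlist) && nrow(allowlist) > 0L) {
    keys <- intron_key(allowlist$contig, allowlist$start, allowlist$end,
                       allowlist$strand)
    missing <- setdiff(keys, introns$intron_id)
    if (length(missing) > 0L) {
      warning(length(missing),
              " allowlisted intron(s) absent from the catalog, skipped: ",
              paste(head(missing, 3L), collapse = ", "))
    }
    allowed <- introns$intron_id %in% keys
  }

  scored_minor <- s5 >= theta5 & bps$bps_score >= theta_bps
  minor <- scored_minor | allowed
  subtype <- dplyr::case_when(
    !minor ~ "not_applicable",
    introns$donor_dinucleotide == "AT" ~ "A",
    introns$donor_dinucleotide %in% c("GT", "GC") ~ "G",
    TRUE ~ "not_applicable"
  )
  tibble(
    intron_id = introns$intron_id,
    s5 = s5,
    s_bps = bps$bps_score,
    bps_offset = bps$bps_offset,
    spliceosome_type = if_else(minor, "minor", "major"),
    subtype = subtype,
    terminal_label = introns$terminal_label,
    source = if_else(scored_minor, "scored",
                     if_else(allowed, "allowlist", "scored"))
  )
}
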