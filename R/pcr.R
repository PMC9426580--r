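# In-silico PCR: predict amplicons of a primer pair on a (possibly
# circular) template. Primer matching is uniform-mismatch (no 3'-end
# weighting); hits are located with Biostrings::matchPattern.

#' Predict PCR products on a template
#'
#' Finds all sites where the forward primer matches the plus strand and
#' the reverse primer's reverse complement matches downstream, and reports
#' every orientation-compatible pair whose product length does not exceed
#' `max_product`. Circular templates are scanned across the origin, and a
#' product spanning the origin is reported with its modular length.
#'
#' @param template Template sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @param fwd,rev Primer sequences, 5' to 3', at least 15 nt.
#' @param max_mismatch Maximum number of mismatches allowed per primer
#'   site (uniform over positions; default 0 = exact).
#' @param circular Is the template circular?
#' @param max_product Maximum reported product length in bp.
#' @return A tibble with columns `start` (0-based position of the forward
#'   site), `end` (0-based exclusive end of the reverse site; exceeds the
#'   template length for origin-spanning products) and `length`
#'   (`end - start`). Zero rows when no product is predicted.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatch = 0L,
                         circular = FALSE, max_product = 10000L) {
  template <- str_to_upper(as.character(template))
  fwd <- str_to_upper(as.character(fwd))
  rev <- str_to_upper(as.character(rev))
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    stop_ecr("primers must be at least 15 nt long")
  }
  L <- nchar(template)
  empty <- tibble(start = integer(), end = integer(), length = integer())
  if (L < nchar(fwd) + nchar(rev)) return(empty)

  subject <- if (circular) {
    # append enough sequence past the origin that any product of length
    # <= min(max_product, L) starting before the origin is seen linearly
    ext <- min(max_product, L) - 1L
    paste0(template, substr(template, 1L, ext))
  } else template
  subj <- Biostrings::DNAString(subject)

  fwd_hits <- Biostrings::start(
    Biostrings::matchPattern(fwd, subj, max.mismatch = max_mismatch)) - 1L
  rev_hits <- Biostrings::end(
    Biostrings::matchPattern(revcomp(rev), subj, max.mismatch = max_mismatch))
  if (circular) fwd_hits <- fwd_hits[fwd_hits < L]  # dedupe modular starts
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) return(empty)

  pairs <- tidyr::expand_grid(start = fwd_hits, end = rev_hits) |>
    mutate(length = .data$end - .data$start) |>
    filter(.data$length >= nchar(fwd) + nchar(rev),
           .data$length <= min(max_product, if (circular) L else Inf)) |>
    distinct() |>
    arrange(.data$start, .data$length)
  as_tibble(pairs)
}
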