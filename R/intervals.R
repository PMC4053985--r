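#' Construct a genomic-interval table
#'
#' Intervals use the BED convention: 0-based, half-open `[start, end)`.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param name optional feature names (e.g. chromatin-state labels).
#' @param strand optional strand, `"+"`, `"-"` or `NA`.
#' @return a `data.frame` with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stopf("interval start < 0")
  if (any(start >= end)) stopf("interval with start >= end")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = rep_len(name, length(start)),
             strand = rep_len(strand, length(start)),
             stringsAsFactors = FALSE)
}

## TRUE for each position contained in any interval (positions 0-based).
points_in_intervals <- function(chrom, p0, iv) {
  res <- logical(length(p0))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(ivc) == 0) next
    ivc <- ivc[order(ivc$start), , drop = FALSE]
    idx <- findInterval(p0[sel], ivc$start)
    hit <- idx >= 1 & p0[sel] < ivc$end[pmax(idx, 1)]
    res[sel] <- hit
  }
  res
}

## Check intervals are pairwise disjoint within each chromosome.
intervals_disjoint <- function(iv) {
  for (ch in unique(iv$chrom)) {
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    ivc <- ivc[order(ivc$start), , drop = FALSE]
    if (nrow(ivc) > 1 && any(ivc$start[-1] < ivc$end[-nrow(ivc)])) return(FALSE)
  }
  TRUE
}

## Place n disjoint intervals of given lengths on [0, chrom_len) by slotting.
place_disjoint <- function(n, len_min, len_max, chrom_len, min_gap = 0) {
  if (n == 0) return(numeric(0))
  slot <- floor(chrom_len / n)
  if (slot < len_max + min_gap)
    stopf("chromosome too short: %d intervals of length up to %d need > %d bp",
          n, len_max, n * (len_max + min_gap))
  lens <- floor(runif(n, len_min, len_max + 1))
  offs <- floor(runif(n, 0, slot - lens - min_gap + 1))
  start <- (seq_len(n) - 1) * slot + offs
  cbind(start = start, end = start + lens)
}
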