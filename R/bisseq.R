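#' In-silico bisulfite conversion of a reference sequence
#'
#' Converts every plus-strand cytosine to thymine and records the original
#' CpG cytosine positions (1-based). The first C of a "CC G" run is
#' converted like any non-CpG C; only the C directly followed by G is
#' indexed.
#'
#' @param seq reference sequence (ACGTN alphabet, uppercase).
#' @return list: `converted` (sequence with C -> T), `cpg_index`
#'   (1-based positions of CpG cytosines).
#' @export
convert_reference <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0) stopf("non-ACGTN character at offset %d", as.integer(bad))
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  cpg <- if (hits[1] == -1) integer(0) else as.integer(hits)
  list(converted = chartr("C", "T", seq), cpg_index = cpg)
}

#' Convert reads into bisulfite mapping space
#'
#' Forward-mate reads have C converted to T in place. Reverse-mate reads
#' are reverse-complemented (with qualities reversed) first, then
#' converted, so both mates align to the converted forward strand.
#'
#' @param seq,qual character vectors of read sequences and phred+33
#'   quality strings.
#' @param mate `"fwd"` or `"rev"` per read.
#' @return list(seq, qual) in mapping space.
#' @export
convert_reads <- function(seq, qual, mate) {
  mate <- rep_len(mate, length(seq))
  rev <- mate == "rev"
  if (any(rev)) {
    seq[rev] <- revcomp_chr(seq[rev])
    qual[rev] <- vapply(strsplit(qual[rev], ""), function(q)
      paste(rev(q), collapse = ""), character(1))
  }
  list(seq = chartr("C", "T", seq), qual = qual)
}

#' Map converted reads to converted targets by exact substring match
#'
#' Forward orientation only (capture selects the original top strand; no
#' reverse-complement mapping). A read mapping to exactly one offset of
#' one target is mapped; zero hits is unmapped; two or more hits anywhere
#' (any target, any offset) is ambiguous and discarded. Reads of equal
#' length are matched with a Biostrings dictionary; mixed lengths fall
#' back to per-read substring search.
#'
#' @param reads data frame with `read_id`, `sample_id`, `mate`, `seq`,
#'   `qual` (original, unconverted reads).
#' @param targets target table (`target_id`, `chrom`, `start`, `seq`).
#' @return list: `mapped` (reads with `target_id` and 1-based `offset`
#'   into the target, original sequences retained), `n_unmapped`,
#'   `n_ambiguous`.
#' @export
map_reads <- function(reads, targets) {
  conv_t <- vapply(targets$seq, function(s) convert_reference(s)$converted,
                   character(1))
  cr <- convert_reads(reads$seq, reads$qual, reads$mate)
  n <- nrow(reads)
  hit_n <- integer(n)
  hit_target <- rep(NA_integer_, n)
  hit_off <- rep(NA_integer_, n)
  widths <- nchar(cr$seq)
  if (n > 0 && length(unique(widths)) == 1) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(cr$seq))
    for (ti in seq_along(conv_t)) {
      mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(conv_t[ti]))
      starts <- Biostrings::startIndex(mi)
      cnt <- lengths(starts)
      hit_n <- hit_n + cnt
      one <- cnt >= 1
      hit_target[one] <- ti
      hit_off[one] <- vapply(starts[one], `[`, integer(1), 1)
    }
  } else {
    for (ri in seq_len(n)) {
      for (ti in seq_along(conv_t)) {
        m <- gregexpr(cr$seq[ri], conv_t[ti], fixed = TRUE)[[1]]
        if (m[1] != -1) {
          hit_n[ri] <- hit_n[ri] + length(m)
          hit_target[ri] <- ti
          hit_off[ri] <- m[1]
        }
      }
    }
  }
  mapped <- reads[hit_n == 1, , drop = FALSE]
  mapped$target_id <- targets$target_id[hit_target[hit_n == 1]]
  mapped$offset <- hit_off[hit_n == 1]
  ## reverse mates are carried in mapping orientation so that offsets and
  ## base columns line up with the reference
  rev_sel <- which(hit_n == 1 & reads$mate == "rev")
  if (length(rev_sel)) {
    keep_idx <- match(rev_sel, which(hit_n == 1))
    mapped$seq[keep_idx] <- revcomp_chr(reads$seq[rev_sel])
    mapped$qual[keep_idx] <- vapply(strsplit(reads$qual[rev_sel], ""),
                                    function(q) paste(rev(q), collapse = ""),
                                    character(1))
  }
  rownames(mapped) <- NULL
  list(mapped = mapped, n_unmapped = sum(hit_n == 0),
       n_ambiguous = sum(hit_n > 1))
}

#' Remove duplicate reads
#'
#' Among reads sharing (sample, target, offset, mate) the read with the
#' highest mean base quality is kept; ties are broken by read id.
#'
#' @param mapped mapped read table from [map_reads()].
#' @return deduplicated table.
#' @export
dedupe <- function(mapped) {
  if (nrow(mapped) == 0) return(mapped)
  meanq <- vapply(phred_to_int(mapped$qual), mean, numeric(1))
  ord <- order(mapped$sample_id, mapped$target_id, mapped$offset,
               mapped$mate, -meanq, mapped$read_id)
  m <- mapped[ord, , drop = FALSE]
  key <- paste(m$sample_id, m$target_id, m$offset, m$mate, sep = "\r")
  out <- m[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-CpG methylation calls from mapped bisulfite reads
#'
#' Pileups use the original (unconverted) read sequences re-attached after
#' mapping. At each reference CpG cytosine covered by a read, an original
#' C base with phred >= `min_q` counts as methylated and a T as
#' unmethylated; other bases or low-quality bases are ignored. Percentage
#' methylation is reported only at `depth >= min_depth`, otherwise
#' missing (counts are always reported).
#'
#' @param mapped deduplicated mapped reads.
#' @param targets target table (`target_id`, `chrom`, `start`, `seq`).
#' @param min_q phred threshold (default 30).
#' @param min_depth minimum depth for a percentage call (default 20).
#' @return data frame: sample_id, target_id, chrom, pos (1-based genomic
#'   CpG cytosine), n_meth, n_unmeth, depth, pct.
#' @export
call_methylation <- function(mapped, targets, min_q = 30, min_depth = 20) {
  cpg_by_target <- lapply(seq_len(nrow(targets)), function(i)
    convert_reference(targets$seq[i])$cpg_index)
  names(cpg_by_target) <- targets$target_id
  rows <- list()
  for (ri in seq_len(nrow(mapped))) {
    tid <- mapped$target_id[ri]
    cpg <- cpg_by_target[[tid]]
    off <- mapped$offset[ri]
    w <- nchar(mapped$seq[ri])
    cov <- cpg[cpg >= off & cpg <= off + w - 1]
    if (length(cov) == 0) next
    at <- cov - off + 1
    base <- substring(mapped$seq[ri], at, at)
    q <- utf8ToInt(mapped$qual[ri])[at] - 33L
    keep <- q >= min_q & base %in% c("C", "T")
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = mapped$sample_id[ri], target_id = tid,
      local_pos = cov[keep], meth = base[keep] == "C",
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(sample_id = character(0), target_id = character(0),
                      chrom = character(0), pos = numeric(0),
                      n_meth = integer(0), n_unmeth = integer(0),
                      depth = integer(0), pct = numeric(0))
  if (length(rows) == 0) return(empty)
  dt <- data.table::rbindlist(rows)
  calls <- dt[, list(n_meth = sum(meth), n_unmeth = sum(!meth)),
              by = c("sample_id", "target_id", "local_pos")]
  calls <- as.data.frame(calls)
  ti <- match(calls$target_id, targets$target_id)
  calls$chrom <- targets$chrom[ti]
  calls$pos <- targets$start[ti] + calls$local_pos
  calls$depth <- calls$n_meth + calls$n_unmeth
  calls$pct <- ifelse(calls$depth >= min_depth,
                      100 * calls$n_meth / calls$depth, NA_real_)
  calls <- calls[order(calls$sample_id, calls$target_id, calls$pos), ]
  rownames(calls) <- NULL
  calls[, c("sample_id", "target_id", "chrom", "pos", "n_meth", "n_unmeth",
            "depth", "pct")]
}

#' Young-minus-old methylation deltas per CpG
#'
#' `delta = median(young pct) - median(old pct)` per CpG, using only
#' samples with a non-missing percentage call; missing when a whole group
#' lacks calls at the CpG.
#'
#' @param calls methylation call table from [call_methylation()].
#' @param young,old character vectors of sample ids.
#' @return data frame: target_id, chrom, pos, median_young, median_old,
#'   delta.
#' @export
delta_young_old <- function(calls, young, old) {
  if (length(young) == 0 || length(old) == 0)
    stopf("both groups must be nonempty")
  d <- calls[!is.na(calls$pct), , drop = FALSE]
  d$group <- ifelse(d$sample_id %in% young, "young",
                    ifelse(d$sample_id %in% old, "old", NA_character_))
  d <- d[!is.na(d$group), , drop = FALSE]
  med <- aggregate(pct ~ target_id + chrom + pos + group, data = d,
                   FUN = median)
  wide <- merge(
    stats::setNames(med[med$group == "young",
                        c("target_id", "chrom", "pos", "pct")],
                    c("target_id", "chrom", "pos", "median_young")),
    stats::setNames(med[med$group == "old",
                        c("target_id", "chrom", "pos", "pct")],
                    c("target_id", "chrom", "pos", "median_old")),
    by = c("target_id", "chrom", "pos"), all = TRUE)
  wide$delta <- wide$median_young - wide$median_old
  wide[order(wide$target_id, wide$pos), ]
}

#' Bland-Altman limits of agreement
#'
#' For paired measurements, the mean difference and the limits
#' `mean +/- 1.96 * sd` (sample sd, n - 1 denominator).
#'
#' @param x,y paired numeric vectors (percent methylation by two methods).
#' @return list(mean_diff, loa_low, loa_high, n).
#' @export
bland_altman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (length(d) < 2) stopf("need >= 2 paired observations")
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d))
}

#' Concordance between sequencing and array methylation
#'
#' Per-sample Pearson correlation over shared CpGs plus pooled fractions
#' of sample-CpG pairs differing by less than 10 and 15 percentage
#' points. Array beta-scores are rescaled to percent.
#'
#' @param bis data frame `sample_id`, `chrom`, `pos`, `pct` (0-100).
#' @param array data frame `sample_id`, `chrom`, `pos`, `beta` (0-1).
#' @param min_shared minimum shared CpGs per sample (default 3; samples
#'   below it are skipped with a notice).
#' @return list: `per_sample` (sample_id, n, r), `frac_lt10`, `frac_lt15`,
#'   `skipped` (sample ids with too few shared CpGs).
#' @export
platform_concordance <- function(bis, array, min_shared = 3) {
  array$pct_array <- 100 * array$beta
  d <- merge(bis[!is.na(bis$pct), c("sample_id", "chrom", "pos", "pct")],
             array[!is.na(array$beta),
                   c("sample_id", "chrom", "pos", "pct_array")],
             by = c("sample_id", "chrom", "pos"))
  if (nrow(d) == 0) stopf("no shared CpG measurements")
  per <- lapply(split(d, d$sample_id), function(s) {
    if (nrow(s) < min_shared) return(NULL)
    data.frame(sample_id = s$sample_id[1], n = nrow(s),
               r = stats::cor(s$pct, s$pct_array), stringsAsFactors = FALSE)
  })
  skipped <- names(per)[vapply(per, is.null, logical(1))]
  per_sample <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  rownames(per_sample) <- NULL
  dd <- abs(d$pct - d$pct_array)
  list(per_sample = per_sample, frac_lt10 = mean(dd < 10),
       frac_lt15 = mean(dd < 15), skipped = skipped)
}
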