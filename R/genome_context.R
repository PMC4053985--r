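#' Distance from CpGs to the nearest CTCF peak midpoint
#'
#' Peak midpoint is `floor((start + end) / 2)` in 0-based space; the
#' distance is `|p0 - midpoint|` minimized over peaks on the CpG's
#' chromosome. CpGs on chromosomes without peaks get infinite distance
#' (folded into the beyond-5 kb class).
#'
#' @param cpg_pos 1-based CpG coordinates.
#' @param peaks CTCF peak intervals ([genomic_intervals()]).
#' @param chrom chromosome per CpG (recycled).
#' @param far_bp dichotomy threshold in bp (default 5000).
#' @return data frame: cpg_pos, chrom, distance, beyond_5kb.
#' @export
nearest_ctcf_distance <- function(cpg_pos, peaks, chrom = "chrS",
                                  far_bp = 5000) {
  p0 <- as.numeric(cpg_pos) - 1
  chrom <- rep_len(as.character(chrom), length(p0))
  dist <- rep(Inf, length(p0))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0) next
    mid <- sort(floor((pk$start + pk$end) / 2))
    idx <- findInterval(p0[sel], mid)
    d_left <- ifelse(idx >= 1, p0[sel] - mid[pmax(idx, 1)], Inf)
    d_right <- ifelse(idx < length(mid), mid[pmin(idx + 1, length(mid))] -
                        p0[sel], Inf)
    dist[sel] <- pmin(d_left, d_right)
  }
  data.frame(cpg_pos = cpg_pos, chrom = chrom, distance = dist,
             beyond_5kb = dist > far_bp, stringsAsFactors = FALSE)
}

#' CTCF proximity contrast between ageCGs and non-ageCGs
#'
#' Cross-tabulates CpG class against the beyond-5 kb dichotomy and tests
#' association with [pearson_chisq()]. Skipped with a notice when a
#' margin is degenerate (e.g. every CpG within 5 kb).
#'
#' @param age_dist,nonage_dist outputs of [nearest_ctcf_distance()] for
#'   the two CpG classes.
#' @return list(table, test), `test` holding a `notice` when skipped.
#' @export
ctcf_proximity_test <- function(age_dist, nonage_dist) {
  if (nrow(age_dist) == 0 || nrow(nonage_dist) == 0)
    stopf("both classes must be nonempty")
  tab <- rbind(ageCG = table(factor(age_dist$beyond_5kb, c(FALSE, TRUE))),
               nonageCG = table(factor(nonage_dist$beyond_5kb,
                                       c(FALSE, TRUE))))
  colnames(tab) <- c("within_5kb", "beyond_5kb")
  test <- tryCatch(pearson_chisq(tab),
                   error = function(e) list(notice = conditionMessage(e)))
  list(table = tab, test = test)
}

#' LAD membership and normalized edge distance for CpGs
#'
#' A CpG inside a lamina-associated domain gets the distance to the
#' nearest domain edge normalized by domain length (in `[0, 0.5]`) and,
#' when the gene strand is known, an orientation: `"toward"` if moving in
#' the transcription direction from the CpG decreases the distance to the
#' nearest edge, else `"away"`.
#'
#' @param cpg_pos 1-based CpG coordinates.
#' @param lads disjoint LAD intervals.
#' @param strands optional gene strand per CpG (`"+"`, `"-"`, `NA`).
#' @param chrom chromosome per CpG (recycled).
#' @return list: `records` (cpg_pos, in_lad, norm_edge_distance,
#'   orientation), `summary` (fraction of CpGs in LADs).
#' @export
lad_metrics <- function(cpg_pos, lads, strands = NA_character_,
                        chrom = "chrS") {
  if (!intervals_disjoint(lads)) stopf("LADs must be disjoint")
  p0 <- as.numeric(cpg_pos) - 1
  n <- length(p0)
  chrom <- rep_len(as.character(chrom), n)
  strands <- rep_len(as.character(strands), n)
  in_lad <- logical(n)
  ndist <- rep(NA_real_, n)
  orient <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    lc <- lads[lads$chrom == chrom[i] & lads$start <= p0[i] &
                 p0[i] < lads$end, , drop = FALSE]
    if (nrow(lc) == 0) next
    in_lad[i] <- TRUE
    d_start <- p0[i] - lc$start[1]
    d_end <- (lc$end[1] - 1) - p0[i]
    len <- lc$end[1] - lc$start[1]
    ndist[i] <- min(d_start, d_end) / len
    if (!is.na(strands[i])) {
      nearest_right <- d_end < d_start
      orient[i] <- if ((strands[i] == "+") == nearest_right)
        "toward" else "away"
    }
  }
  records <- data.frame(cpg_pos = cpg_pos, chrom = chrom, in_lad = in_lad,
                        norm_edge_distance = ndist, orientation = orient,
                        stringsAsFactors = FALSE)
  list(records = records, summary = list(frac_in_lad = mean(in_lad)))
}

#' Chromatin-state overlap fold enrichment
#'
#' `fold(state) = (fraction of positions in state) / (fraction of tiled
#' genome length in state)` for a segmentation that tiles its chromosomes
#' exactly once. Positions on untiled chromosomes are excluded (count
#' reported); a state with positions but zero genome share is reported
#' missing with a warning.
#'
#' @param cpg_pos 1-based positions of interest.
#' @param segmentation labeled intervals tiling the genome (`name` column
#'   holds the state label).
#' @param chrom chromosome per position (recycled).
#' @return data frame: state, genome_frac, position_frac, fold; attribute
#'   `n_excluded` counts positions on untiled chromosomes.
#' @export
state_overlap_enrichment <- function(cpg_pos, segmentation, chrom = "chrS") {
  seg <- segmentation[order(segmentation$chrom, segmentation$start), ,
                      drop = FALSE]
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)]))
      stopf("segmentation does not tile chromosome %s", ch)
  }
  p0 <- as.numeric(cpg_pos) - 1
  chrom <- rep_len(as.character(chrom), length(p0))
  tiled <- chrom %in% seg$chrom
  n_excluded <- sum(!tiled)
  state_of <- rep(NA_character_, length(p0))
  for (ch in unique(chrom[tiled])) {
    sel <- which(chrom == ch)
    s <- seg[seg$chrom == ch, , drop = FALSE]
    idx <- findInterval(p0[sel], s$start)
    ok <- idx >= 1 & p0[sel] < s$end[pmax(idx, 1)]
    state_of[sel[ok]] <- s$name[idx[ok]]
  }
  lens <- tapply(seg$end - seg$start, seg$name, sum)
  genome_frac <- lens / sum(lens)
  used <- state_of[!is.na(state_of)]
  if (length(used) == 0) stopf("no positions fall on the tiled genome")
  pos_frac <- table(factor(used, levels = names(genome_frac))) / length(used)
  fold <- as.numeric(pos_frac) / as.numeric(genome_frac)
  zero_share <- genome_frac == 0 & pos_frac > 0
  if (any(zero_share)) {
    warnf("state(s) with positions but zero genome share: %s",
          paste(names(genome_frac)[zero_share], collapse = ", "))
    fold[zero_share] <- NA_real_
  }
  out <- data.frame(state = names(genome_frac),
                    genome_frac = as.numeric(genome_frac),
                    position_frac = as.numeric(pos_frac), fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}
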