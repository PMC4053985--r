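#' Simulate a genome annotation bundle on one synthetic chromosome
#'
#' Generates disjoint CpG islands, stranded gene models, CTCF peak
#' intervals, disjoint lamina-associated domains (LADs), and a chromatin
#' state segmentation that tiles the chromosome exactly once, all on a
#' single synthetic chromosome `"chrS"` in 0-based half-open coordinates.
#' Roughly half of the genes are anchored with their transcription start at
#' an island edge so that island probes can be linked to genes.
#'
#' @param config a [sim_config()].
#' @return list with elements `islands`, `genes`, `ctcf`, `lads`,
#'   `segmentation` (interval data frames, see [genomic_intervals()]) and
#'   `chrom_len`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1), {
    L <- config$chrom_len

    islands <- if (config$n_islands > 0) {
      ie <- place_disjoint(config$n_islands, 400, 1500, L, min_gap = 6000)
      genomic_intervals("chrS", ie[, "start"], ie[, "end"],
                        name = sprintf("CGI_%03d", seq_len(nrow(ie))))
    } else genomic_intervals(character(0), numeric(0), numeric(0))

    ## Genes: half anchored at island starts (promoter islands), half free.
    ng <- config$n_genes
    glen <- floor(runif(ng, 2000, 20000))
    n_anchored <- if (config$n_islands > 0) min(ng %/% 2, config$n_islands) else 0
    gstart <- numeric(ng)
    if (n_anchored > 0) {
      anchor <- sample(nrow(islands), n_anchored)
      gstart[seq_len(n_anchored)] <- islands$start[anchor]
    }
    free <- (n_anchored + 1):ng
    gstart[free] <- floor(runif(length(free), 0, L - glen[free]))
    gend <- pmin(gstart + glen, L)
    genes <- genomic_intervals("chrS", gstart, gend,
                               name = sprintf("GENE%04d", seq_len(ng)),
                               strand = sample(c("+", "-"), ng, replace = TRUE))
    genes <- genes[order(genes$start), ]
    rownames(genes) <- NULL

    ctcf <- if (config$n_ctcf > 0) {
      ce <- place_disjoint(config$n_ctcf, 200, 600, L)
      genomic_intervals("chrS", ce[, "start"], ce[, "end"],
                        name = sprintf("CTCF_%03d", seq_len(nrow(ce))))
    } else genomic_intervals(character(0), numeric(0), numeric(0))

    lads <- if (config$n_lads > 0) {
      le <- place_disjoint(config$n_lads, 1e5, min(5e5, floor(L / config$n_lads) - 1), L)
      genomic_intervals("chrS", le[, "start"], le[, "end"],
                        name = sprintf("LAD_%02d", seq_len(nrow(le))))
    } else genomic_intervals(character(0), numeric(0), numeric(0))

    ## Segmentation: exponential segment lengths, states cycled randomly,
    ## truncated so the tiles cover [0, L) exactly.
    seg_start <- numeric(0); seg_end <- numeric(0)
    pos <- 0
    while (pos < L) {
      len <- max(200, ceiling(rexp(1, 1 / 5000)))
      seg_start <- c(seg_start, pos)
      seg_end <- c(seg_end, min(pos + len, L))
      pos <- pos + len
    }
    states <- sprintf("E%d", sample.int(config$n_states, length(seg_start),
                                        replace = TRUE))
    segmentation <- genomic_intervals("chrS", seg_start, seg_end, name = states)

    list(islands = islands, genes = genes, ctcf = ctcf, lads = lads,
         segmentation = segmentation, chrom_len = L)
  })
}
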