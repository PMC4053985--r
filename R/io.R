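## Tabular interchange is TSV with optional "# key: value" header comments.

write_tsv_stage <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_stage <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a beta matrix as TSV
#'
#' Probes in rows, samples in columns, with the processing stage recorded
#' in a header comment.
#'
#' @param beta probes x samples matrix with a `stage` attribute.
#' @param path file path.
#' @return the path (write) or the matrix with stage restored (read).
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  write_tsv_stage(df, path, sprintf("stage: %s",
                                    attr(beta, "stage") %||% "raw"))
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  first <- readLines(path, n = 1)
  stage <- sub("^# stage: ", "", first)
  df <- read_tsv_stage(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  attr(m, "stage") <- if (grepl("^#", first)) stage else "raw"
  m
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param iv interval data frame ([genomic_intervals()]).
#' @param path file path.
#' @export
write_bed <- function(iv, path) {
  df <- data.frame(chrom = iv$chrom, start = format(iv$start, scientific = FALSE,
                                                    trim = TRUE),
                   end = format(iv$end, scientific = FALSE, trim = TRUE),
                   name = ifelse(is.na(iv$name), ".", iv$name),
                   score = 0,
                   strand = ifelse(is.na(iv$strand), ".", iv$strand))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval data frame
#'
#' Accepts 3-6 column BED; start stays 0-based half-open.
#'
#' @param path file path.
#' @return interval data frame.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  nm <- if (ncol(df) >= 4) ifelse(df[[4]] == ".", NA_character_, df[[4]])
        else NA_character_
  st <- if (ncol(df) >= 6) ifelse(df[[6]] == ".", NA_character_, df[[6]])
        else NA_character_
  genomic_intervals(df[[1]], df[[2]], df[[3]], name = nm, strand = st)
}

#' Write / read an intensity panel as a set of TSV files
#'
#' Emits `<prefix>_A.tsv`, `<prefix>_B.tsv` (probe_id, channel, one column
#' per sample), `<prefix>_negctrl.tsv` (channel, control index, samples)
#' and `<prefix>_samples.tsv` (sample_id, batch).
#'
#' @param panel an [intensity_panel()].
#' @param prefix path prefix.
#' @return prefix (write); an [intensity_panel()] (read).
#' @export
write_intensity_tsv <- function(panel, prefix) {
  for (ch in c("A", "B")) {
    df <- data.frame(probe_id = rownames(panel[[ch]]),
                     channel = panel$channel, panel[[ch]],
                     check.names = FALSE)
    write_tsv_stage(df, paste0(prefix, "_", ch, ".tsv"))
  }
  nc <- do.call(rbind, lapply(c("green", "red"), function(ch)
    data.frame(channel = ch, idx = seq_len(nrow(panel$negctrl[[ch]])),
               panel$negctrl[[ch]], check.names = FALSE)))
  write_tsv_stage(nc, paste0(prefix, "_negctrl.tsv"))
  write_tsv_stage(data.frame(sample_id = colnames(panel$A),
                             batch = panel$batch),
                  paste0(prefix, "_samples.tsv"))
  invisible(prefix)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(prefix) {
  rd <- function(suffix) read_tsv_stage(paste0(prefix, "_", suffix, ".tsv"))
  a <- rd("A"); b <- rd("B"); nc <- rd("negctrl"); ss <- rd("samples")
  A <- as.matrix(a[, -(1:2), drop = FALSE]); rownames(A) <- a$probe_id
  B <- as.matrix(b[, -(1:2), drop = FALSE]); rownames(B) <- b$probe_id
  negctrl <- lapply(c(green = "green", red = "red"), function(ch) {
    m <- as.matrix(nc[nc$channel == ch, -(1:2), drop = FALSE])
    rownames(m) <- NULL
    m
  })
  intensity_panel(A = A, B = B, channel = a$channel, negctrl = negctrl,
                  batch = ss$batch)
}

#' Write targets as FASTA / reads as FASTQ
#'
#' FASTA ids are target ids; FASTQ ids carry the inline sample barcode as
#' the first `|`-separated field of the read id; qualities are phred+33.
#'
#' @param targets target table (`target_id`, `seq`).
#' @param reads read table (`read_id`, `sample_id`, `mate`, `seq`, `qual`).
#' @param path file path.
#' @export
write_targets_fasta <- function(targets, path) {
  x <- Biostrings::DNAStringSet(targets$seq)
  names(x) <- targets$target_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_targets_fasta
#' @export
read_targets_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(target_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' @rdname write_targets_fasta
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  ## Biostrings warns that metadata columns are dropped; nothing is lost
  suppressWarnings(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual)))
  invisible(path)
}

#' @rdname write_targets_fasta
#' @export
read_reads_fastq <- function(path) {
  ## Biostrings warns about dropped metadata columns; ids are preserved
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- names(x)
  data.frame(read_id = ids,
             sample_id = vapply(strsplit(ids, "|", fixed = TRUE), `[`,
                                character(1), 1),
             mate = "fwd",
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write a QC / run report as JSON
#'
#' @param x a named list (e.g. the `qc` attribute of [filter_matrix()], or
#'   a pipeline run manifest).
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write an ageCG results table as TSV / BED
#'
#' The TSV carries every age-model column; the BED (0-based half-open,
#' one base per CpG) covers ageCGs only, with `<probe>|<sign>` in the
#' name field so the slope direction is visible in a genome browser.
#'
#' @param results age-model table from [fit_age_models()].
#' @param annot probe annotation with `probe_id`, `chrom`, `cpg_pos`.
#' @param path file path.
#' @export
write_agecg_tsv <- function(results, path) {
  write_tsv_stage(results, path, "ageCG regression results")
}

#' @rdname write_agecg_tsv
#' @export
write_agecg_bed <- function(results, annot, path) {
  age <- results[!is.na(results$class) & results$class == "ageCG", ,
                 drop = FALSE]
  age <- merge(age, annot[, c("probe_id", "chrom", "cpg_pos")],
               by = "probe_id")
  iv <- genomic_intervals(age$chrom, age$cpg_pos - 1, age$cpg_pos,
                          name = paste0(age$probe_id, "|", age$sign))
  write_bed(iv, path)
}
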