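#' @importFrom stats median lm.fit lm pt pnorm pchisq p.adjust aov chisq.test
#'   wilcox.test rnorm runif rbinom rlnorm rexp rpois quantile sd var cor
#'   aggregate complete.cases setNames coef logLik ave
#' @importFrom utils combn head read.delim write.table
NULL

.datatable.aware <- TRUE

clip01 <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream-specific child seed (kept well inside 32-bit range).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), character(1))
}

revcomp_chr <- function(seq) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", seq), ""), function(s)
    paste(rev(s), collapse = ""), character(1))
}
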