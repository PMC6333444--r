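#' Read, write and harmonise GWAS summary-statistics tables
#'
#' Whitespace/tab-delimited summary statistics with columns \code{snpid},
#' \code{chr}, \code{pos}, \code{a1} (effect allele), \code{a0},
#' \code{freq1}, \code{beta1}, \code{se}, \code{p}, \code{n}. Columns are
#' matched by name, so reordering is tolerated; extra columns are kept.
#' The writer is bit-stable for a fixed input.
#'
#' \code{harmoniseSumstats} aligns a second table to the allele coding of
#' the first: where \code{a1}/\code{a0} are swapped the effect sign and
#' allele frequency are flipped; SNPs whose alleles match neither way are
#' dropped, as are strand-ambiguous A/T and C/G SNPs whose frequency lies
#' in \[0.4, 0.6\] (unresolvable orientation).
#'
#' @param file path to a delimited file.
#' @param x,y summary-statistics data.frames (\code{y} is aligned to
#'   \code{x}).
#' @param ambiguousFreqRange frequency band within which strand-ambiguous
#'   SNPs are dropped.
#' @return \code{readSumstats}/\code{harmoniseSumstats} return
#'   data.frames; \code{harmoniseSumstats} returns the merged table with
#'   suffixes \code{.x}/\code{.y} and \code{y}'s effects aligned to
#'   \code{x}'s coding.
#' @export
readSumstats <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("snpid", "a1", "a0", "beta1", "se")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("summary statistics lack columns: ", paste(miss, collapse = ", "))
  tab$snpid <- as.character(tab$snpid)
  tab
}

#' @rdname readSumstats
#' @param stats data.frame to write.
#' @export
writeSumstats <- function(stats, file) {
  write.table(stats, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.flipAllele <- c(A = "T", T = "A", C = "G", G = "C")

#' @rdname readSumstats
#' @export
harmoniseSumstats <- function(x, y, ambiguousFreqRange = c(0.4, 0.6)) {
  m <- merge(x, y, by = "snpid", suffixes = c(".x", ".y"))
  if (nrow(m) == 0) stop("no shared SNPs")
  up <- function(a) toupper(as.character(a))
  a1x <- up(m$a1.x); a0x <- up(m$a0.x)
  a1y <- up(m$a1.y); a0y <- up(m$a0.y)
  same <- a1x == a1y & a0x == a0y
  swap <- a1x == a0y & a0x == a1y
  ambiguous <- a1x == unname(.flipAllele[a0x])
  if (!is.null(m$freq1.x)) {
    inBand <- !is.na(m$freq1.x) & m$freq1.x >= ambiguousFreqRange[1] &
      m$freq1.x <= ambiguousFreqRange[2]
    drop <- ambiguous & inBand
  } else drop <- ambiguous
  keep <- (same | swap) & !drop
  m <- m[keep, , drop = FALSE]
  swap <- swap[keep]
  m$beta1.y[swap] <- -m$beta1.y[swap]
  if (!is.null(m$freq1.y)) m$freq1.y[swap] <- 1 - m$freq1.y[swap]
  m$a1.y <- m$a1.x
  m$a0.y <- m$a0.x
  m
}
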