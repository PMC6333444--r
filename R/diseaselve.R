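#' Greedy pruning of SNPs into independent loci
#'
#' Selects an approximately independent SNP set by ascending p-value: a
#' candidate is rejected if it lies within \code{distanceKb} of an
#' already-kept SNP on the same chromosome, or if its LD r-squared with
#' any kept SNP reaches \code{r2Max} (when an LD matrix is supplied;
#' without one, pruning is by distance only). Ties in p are broken by
#' (chrom, pos), making the output invariant to input order.
#'
#' @param snps data.frame with \code{snpid}, \code{chrom}, \code{pos}
#'   (1-based) and \code{p}.
#' @param distanceKb exclusion window in kilobases (default 500).
#' @param r2Max LD threshold (default 0.1); only used when \code{ld}
#'   given.
#' @param ld optional symmetric r-squared matrix with snpid dimnames.
#' @return The kept rows of \code{snps}, ordered by (chrom, pos).
#' @examples
#' s <- data.frame(snpid = c("a", "b"), chrom = "1",
#'                 pos = c(1e6, 1.4e6), p = c(1e-8, 1e-4))
#' pruneLoci(s)  # 400 kb apart: only the smaller p survives
#' @export
pruneLoci <- function(snps, distanceKb = 500, r2Max = 0.1, ld = NULL) {
  need <- c("snpid", "chrom", "pos", "p")
  if (!all(need %in% colnames(snps)))
    stop("snps must have columns ", paste(need, collapse = ", "))
  if (any(is.na(snps$pos))) stop("missing positions")
  ord <- order(snps$p, snps$chrom, snps$pos)
  cand <- snps[ord, , drop = FALSE]
  keptIdx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (length(keptIdx)) {
      kept <- cand[keptIdx, , drop = FALSE]
      near <- kept$chrom == cand$chrom[i] &
        abs(kept$pos - cand$pos[i]) < distanceKb * 1000
      if (any(near)) ok <- FALSE
      if (ok && !is.null(ld)) {
        have <- kept$snpid %in% rownames(ld) &
          cand$snpid[i] %in% colnames(ld)
        if (any(have) &&
            any(ld[kept$snpid[have], cand$snpid[i]] >= r2Max))
          ok <- FALSE
      }
    }
    if (ok) keptIdx <- c(keptIdx, i)
  }
  out <- cand[keptIdx, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Lifespan variance explained by a biallelic SNP
#'
#' LVE = 2 p q a^2 in squared years, where p is the effect-allele
#' frequency, q = 1 - p, and a is the per-allele effect in years of life:
#' the additive genetic variance in lifespan attributable to the SNP.
#' The returned value is the non-negative magnitude and is invariant to
#' allele relabelling (p <-> q, a <-> -a); the protective direction is
#' carried by the sign of the effect itself.
#'
#' @param freq1 effect-allele frequency in (0, 1).
#' @param betaYears per-allele effect in years.
#' @return LVE in years^2 (vectorised).
#' @examples
#' lifespanVarianceExplained(0.85, 1.0561)  # ~ 0.284
#' @export
lifespanVarianceExplained <- function(freq1, betaYears) {
  if (any(freq1 <= 0 | freq1 >= 1)) stop("freq1 must lie in (0, 1)")
  2 * freq1 * (1 - freq1) * betaYears^2
}

#' One-false-positive FDR rule
#'
#' Benjamini-Hochberg q-values with the significance threshold set to
#' 1/n (truncated to 3 decimals), so the expected number of false
#' positives among the n SNPs passing is at most one. With 45 loci the
#' threshold is q <= 0.022; with 60, q <= 0.016.
#'
#' @param p vector of p-values (n >= 1).
#' @return list: \code{q} (BH q-values), \code{threshold} (1/n to 3
#'   decimals), \code{significant} (logical, q <= threshold).
#' @examples
#' fdrOneFalsePositive(runif(45))$threshold  # 0.022
#' @export
fdrOneFalsePositive <- function(p) {
  n <- length(p)
  if (n < 1) stop("need at least one p-value")
  q <- p.adjust(p, method = "BH")
  threshold <- floor(1000 / n) / 1000
  list(q = q, threshold = threshold, significant = q <= threshold)
}

#' Double-Z pleiotropy classification of disease SNPs
#'
#' A disease SNP is reclassified as secondary-pleiotropic when its
#' association Z with another disease category is at least twice its Z
#' with the nominal category, in the concordant direction — the other
#' disease accounts for more attributable cases. It is flagged
#' antagonistic when the disease-protective allele nevertheless shortens
#' life and a significant opposite-direction association with another
#' disease explains the reversal (the allele trades one disease for
#' another).
#'
#' @param zByCategory numeric matrix, SNPs x disease categories, of
#'   association Z statistics for the disease-protective allele.
#' @param primary character vector giving each SNP's nominal category
#'   (must name columns of \code{zByCategory}).
#' @param lifespanBeta per-SNP lifespan effect (lnPR or years) of the
#'   disease-protective allele.
#' @param zSignificance |Z| needed to call an opposite-direction
#'   association significant (default 1.96).
#' @return data.frame: \code{secondary}, \code{antagonistic} (logicals).
#' @export
classifyPleiotropy <- function(zByCategory, primary, lifespanBeta,
                               zSignificance = qnorm(0.975)) {
  zByCategory <- as.matrix(zByCategory)
  m <- nrow(zByCategory)
  stopifnot(length(primary) == m, length(lifespanBeta) == m,
            all(primary %in% colnames(zByCategory)))
  secondary <- logical(m)
  antagonistic <- logical(m)
  for (i in seq_len(m)) {
    zp <- zByCategory[i, primary[i]]
    zo <- zByCategory[i, setdiff(colnames(zByCategory), primary[i])]
    zo <- zo[!is.na(zo)]
    if (!length(zo) || is.na(zp)) next
    secondary[i] <- any(abs(zo) >= 2 * abs(zp) &
                          sign(zo) == sign(zp))
    antagonistic[i] <- lifespanBeta[i] < 0 &&
      any(abs(zo) >= zSignificance & sign(zo) != sign(zp))
  }
  data.frame(secondary = secondary, antagonistic = antagonistic)
}

#' Total lifespan variance explained per disease category
#'
#' Sums LVE over SNPs with a significant lifespan association that are
#' not flagged secondary-pleiotropic, per nominal disease category, and
#' returns the cumulative LVE curve of the included SNPs ordered by
#' decreasing LVE.
#'
#' @param snps data.frame with \code{category}, \code{lve},
#'   \code{significant} and \code{secondary} columns.
#' @return list: \code{totals} (named numeric, per category, zero for
#'   categories with no qualifying SNPs) and \code{cumulative}
#'   (data.frame of included SNPs with \code{rank} and \code{cumLve}).
#' @export
sumLveByCategory <- function(snps) {
  stopifnot(all(c("category", "lve", "significant", "secondary") %in%
                  colnames(snps)))
  keep <- snps$significant & !snps$secondary
  cats <- unique(snps$category)
  totals <- vapply(cats, function(k)
    sum(snps$lve[keep & snps$category == k]), numeric(1))
  inc <- snps[keep, , drop = FALSE]
  inc <- inc[order(-inc$lve), , drop = FALSE]
  inc$rank <- seq_len(nrow(inc))
  inc$cumLve <- cumsum(inc$lve)
  list(totals = totals, cumulative = inc)
}

#' Fisher's exact enrichment test for two SNP classifications
#'
#' Builds the 2x2 table of two binary memberships (e.g. lifespan
#' association x age-related expression among eQTLs) and returns the
#' conditional odds ratio and the two-sided exact (hypergeometric)
#' p-value.
#'
#' @param setA,setB logical vectors of equal length, or \code{setA} may
#'   be a 2x2 count matrix (then \code{setB} is ignored).
#' @return list: \code{table} (2x2 counts), \code{oddsRatio}
#'   (conditional MLE), \code{p}.
#' @examples
#' fisherEnrichment(matrix(c(20, 5, 5, 20), 2))
#' @export
fisherEnrichment <- function(setA, setB = NULL) {
  if (is.matrix(setA)) {
    tab <- setA
    stopifnot(all(dim(tab) == 2), all(tab >= 0))
  } else {
    stopifnot(length(setA) == length(setB))
    tab <- table(factor(setA, c(TRUE, FALSE)),
                 factor(setB, c(TRUE, FALSE)))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: empty margin")
  ft <- fisher.test(tab)
  list(table = tab, oddsRatio = unname(ft$estimate), p = ft$p.value)
}
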