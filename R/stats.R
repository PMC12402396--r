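#' @include AllClasses.R rate-isi.R
NULL

#' Two-group Kruskal-Wallis test
#'
#' Rank-based H with midrank tie correction and a chi-square p-value
#' (df = 1 for two groups). For two groups this is monotonically related to
#' the Mann-Whitney U; it is kept as the per-timepoint test (see
#' [timepointScan()]), with U exposed through [rankBiserial()].
#'
#' @param a,b numeric samples, each with at least 2 observations.
#' @return List with `H` and `p`. Completely tied data (all values equal)
#'   return `H = 0, p = 1` rather than an error.
#' @export
kruskalWallis <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (length(unique(c(a, b))) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(list(a, b))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Rank-biserial correlation
#'
#' Nonparametric effect size from the Mann-Whitney statistic:
#' `r = (wins - losses) / (nA * nB)` over all between-group pairs, tied
#' pairs counting one half each way. `r > 0` means group A is
#' stochastically larger; -1 and 1 mean complete separation.
#'
#' @param a,b numeric samples, non-empty.
#' @return r in [-1, 1].
#' @export
rankBiserial <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  nA <- length(a); nB <- length(b)
  rk <- rank(c(a, b))              # midranks
  uA <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2
  2 * uA / (nA * nB) - 1
}

#' Effect-size tier
#'
#' Tiers the rank-biserial effect size gated on significance: `ns` when
#' `p >= alpha`, otherwise `low` (|r| < 0.2), `medium` (0.2 <= |r| < 0.5)
#' or `high` (|r| >= 0.5).
#'
#' @param r rank-biserial correlation(s) in [-1, 1].
#' @param p p-value(s), recycled against `r`.
#' @param alpha significance gate (default 0.05).
#' @return Character vector of tiers.
#' @export
classifyEffect <- function(r, p, alpha = 0.05) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  tier <- ifelse(abs(r) >= 0.5, "high",
                 ifelse(abs(r) >= 0.2, "medium", "low"))
  ifelse(p >= alpha, "ns", tier)
}

#' Per-timepoint group comparison of firing-rate series
#'
#' At each point of a regular time grid (default 1-s steps, i.e.
#' non-overlapping boxcar centers), compares the per-animal rate values of
#' two groups with [kruskalWallis()], attaches the [rankBiserial()] effect
#' size and its [classifyEffect()] tier. No multiple-testing correction by
#' default; `adjust = "BH"` applies Benjamini-Hochberg before tiering.
#'
#' @param groupA,groupB lists of [RateSeries-class] (one per animal, same
#'   length and sampling rate), or numeric matrices (animals x timepoints,
#'   then `step`/`fs` index columns directly).
#' @param step grid step in seconds (default 1).
#' @param alpha significance gate (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return data.frame with columns `t`, `H`, `p`, `r`, `tier`.
#' @export
timepointScan <- function(groupA, groupB, step = 1, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  toMat <- function(g) {
    if (is.matrix(g)) return(list(mat = g, t = seq_len(ncol(g)) * step))
    stopifnot(is.list(g), length(g) >= 2L,
              all(vapply(g, is, logical(1), "RateSeries")))
    fs <- g[[1L]]@fs
    len <- length(g[[1L]]@rate)
    win <- g[[1L]]@window
    ok <- vapply(g, function(s) s@fs == fs && length(s@rate) == len,
                 logical(1))
    if (!all(ok)) stop("rate series have mismatched length or sampling rate")
    dur <- len / fs
    tGrid <- seq(win / 2, dur - win / 2, by = step)
    idx <- pmin(round(tGrid * fs) + 1L, len)
    list(mat = t(vapply(g, function(s) s@rate[idx], numeric(length(idx)))),
         t = tGrid)
  }
  A <- toMat(groupA); B <- toMat(groupB)
  if (ncol(A$mat) != ncol(B$mat))
    stop("groups have different numbers of timepoints")
  if (nrow(A$mat) < 2L || nrow(B$mat) < 2L)
    stop("need at least 2 animals per group")
  res <- vapply(seq_len(ncol(A$mat)), function(j) {
    kw <- kruskalWallis(A$mat[, j], B$mat[, j])
    c(kw$H, kw$p, rankBiserial(A$mat[, j], B$mat[, j]))
  }, numeric(3))
  p <- if (adjust == "BH") stats::p.adjust(res[2L, ], "BH") else res[2L, ]
  data.frame(t = A$t, H = res[1L, ], p = p, r = res[3L, ],
             tier = classifyEffect(res[3L, ], p, alpha))
}

.normalityP <- function(x, test) {
  if (stats::sd(x) == 0) return(0)   # constant: treat as non-normal
  if (test == "lilliefors") {
    if (length(x) < 4L) {
      warning("Lilliefors needs n >= 4; using Shapiro-Wilk")
      return(stats::shapiro.test(x)$p.value)
    }
    nortest::lillie.test(x)$p.value
  } else stats::shapiro.test(x)$p.value
}

#' Normality-gated two-group comparison of per-animal means
#'
#' Tests each group for normality (Lilliefors-corrected Kolmogorov-Smirnov
#' by default, the choice for firing-rate summaries; Shapiro-Wilk for
#' behavioral indices). If both pass at `alpha`, an (un)paired t-test is
#' used; otherwise Mann-Whitney U (unpaired) or Wilcoxon signed-rank
#' (paired). Two-tailed throughout; the route taken is recorded.
#'
#' @param a,b numeric vectors of per-animal summaries (>= 3 each; equal
#'   lengths when paired).
#' @param paired logical (default FALSE).
#' @param normalityTest "lilliefors" (default) or "shapiro".
#' @param alpha normality gate level (default 0.05).
#' @param label comparison label carried into the result.
#' @return List of class `"GroupComparison"`: `label`, `testUsed`,
#'   `statistic`, `p`, `meanA`, `sdA`, `meanB`, `sdB`, `normalityP`
#'   (length 2), `paired`.
#' @export
compareGroupMeans <- function(a, b, paired = FALSE,
                              normalityTest = c("lilliefors", "shapiro"),
                              alpha = 0.05, label = "") {
  normalityTest <- match.arg(normalityTest)
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length groups")
  np <- c(.normalityP(a, normalityTest), .normalityP(b, normalityTest))
  normal <- all(np >= alpha)
  if (paired && stats::sd(a - b) == 0) {
    warning("degenerate paired comparison (constant differences)")
    out <- list(testUsed = if (normal) "paired t" else "Wilcoxon signed-rank",
                statistic = if (all(a == b)) 0 else sign(mean(a - b)) * Inf,
                p = if (all(a == b)) 1 else 0)
  } else if (normal) {
    tt <- stats::t.test(a, b, paired = paired)
    out <- list(testUsed = if (paired) "paired t" else "unpaired t",
                statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    out <- list(testUsed = if (paired) "Wilcoxon signed-rank"
                           else "Mann-Whitney U",
                statistic = unname(wt$statistic), p = wt$p.value)
  }
  structure(c(list(label = label), out,
              list(meanA = mean(a), sdA = stats::sd(a),
                   meanB = mean(b), sdB = stats::sd(b),
                   normalityP = np, paired = paired)),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf(
    "%s%s: %.3f +/- %.3f vs %.3f +/- %.3f, %s, stat = %.4g, p = %.4g\n",
    if (nzchar(x$label)) paste0(x$label, " ") else "",
    if (x$paired) "(paired)" else "(unpaired)",
    x$meanA, x$sdA, x$meanB, x$sdB, x$testUsed, x$statistic, x$p))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_A - ECDF_B|` with the asymptotic p-value; used to compare
#' full ISI distributions between groups.
#'
#' @param a,b numeric samples, non-empty.
#' @return List with `D` and `p`.
#' @export
ksTwoSample <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Chi-square comparison of short-ISI proportions
#'
#' Pearson chi-square (df = 1, no continuity correction; expected counts
#' are large in this application) on the 2x2 table of short vs non-short
#' ISI counts in two groups.
#'
#' @param countsA,countsB integer `c(short, nonShort)` per group.
#' @return List: `chi2`, `p`, `table` (2x2), `fractions` (short fraction
#'   per group). Warns when any expected count is below 5.
#' @examples
#' chiSqShortIsi(c(20, 80), c(10, 90))$chi2  # 3.9216
#' @export
chiSqShortIsi <- function(countsA, countsB) {
  stopifnot(length(countsA) == 2L, length(countsB) == 2L,
            all(c(countsA, countsB) >= 0),
            sum(countsA) > 0, sum(countsB) > 0)
  m <- rbind(A = countsA, B = countsB)
  colnames(m) <- c("short", "nonShort")
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expd < 5))
    warning("expected count below 5; consider an exact test")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = m,
       fractions = m[, 1L] / rowSums(m))
}

#' Paired comparison of total spike counts
#'
#' Two-tailed paired t-test on per-animal total spike counts before vs
#' after stimulation.
#'
#' @param countsBefore,countsAfter equal-length per-animal count vectors
#'   (n >= 2).
#' @return A `"GroupComparison"` list (see [compareGroupMeans()]).
#' @export
pairedSpikeCountTest <- function(countsBefore, countsAfter) {
  stopifnot(length(countsBefore) == length(countsAfter),
            length(countsBefore) >= 2L)
  d <- countsBefore - countsAfter
  if (stats::sd(d) == 0) {
    warning("degenerate variance in paired differences")
    out <- list(statistic = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
                p = if (all(d == 0)) 1 else 0)
  } else {
    tt <- stats::t.test(countsBefore, countsAfter, paired = TRUE)
    out <- list(statistic = unname(tt$statistic), p = tt$p.value)
  }
  structure(c(list(label = "total spike count before vs after",
                   testUsed = "paired t"), out,
              list(meanA = mean(countsBefore), sdA = stats::sd(countsBefore),
                   meanB = mean(countsAfter), sdB = stats::sd(countsAfter),
                   normalityP = c(NA_real_, NA_real_), paired = TRUE)),
            class = "GroupComparison")
}
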