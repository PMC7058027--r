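# Shared statistical machinery: rank tests, Dunn's post-hoc with BH
# correction, silhouette-based selection of the cluster number, and a
# Shapiro-Wilk normality gate. Average ranks are used for ties throughout.

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square approximation on k - 1
#' degrees of freedom (delegates to \code{stats::kruskal.test}). When all
#' values are identical the statistic is 0 and p is 1.
#'
#' @param groups list (length >= 2) of numeric vectors, total n >= 3.
#' @return list with \code{statistic} (H), \code{df}, \code{p.value},
#'   \code{method} and \code{groupSizes}.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic  # 7.2
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  n <- lengths(groups)
  if (sum(n) < 3) stop("need at least 3 observations in total")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1,
                method = "Kruskal-Wallis", groupSizes = n))
  g <- factor(rep(seq_along(groups), n))
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value, method = "Kruskal-Wallis", groupSizes = n)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from pooled average ranks with the usual tie
#' correction, two-sided p values, and Benjamini-Hochberg adjustment
#' across all pairs of one family.
#'
#' @param groups named or unnamed list (length >= 2) of numeric vectors.
#' @return data.frame with group1, group2, z, p.value, p.adjusted.
#' @export
dunnPosthoc <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)                                   # average ranks for ties
  g <- rep(seq_len(k), n)
  meanRank <- tapply(r, g, mean)
  tieTab <- table(x)
  tieCorr <- sum(tieTab^3 - tieTab) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (meanRank[i] - meanRank[j]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = as.numeric(z), p.value = p,
             p.adjusted = p.adjust(p, method = "BH"),
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps \code{stats::p.adjust(method = "BH")} with input validation;
#' adjusted values are capped at 1, never below the raw p, and returned in
#' input order.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must be finite and within [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select the number of clusters by mean silhouette width
#'
#' Ward (ward.D2) agglomeration on Euclidean distances of the supplied
#' (already scaled) observation matrix; for each k in \code{kRange} the
#' tree is cut and the mean silhouette width computed; the k maximising it
#' is chosen, ties broken toward smaller k. Values of k with too few
#' observations are skipped.
#'
#' @param x numeric observation x feature matrix with finite entries.
#' @param kRange integer vector of candidate cluster numbers (>= 2).
#' @param noStructureFloor optional mean-silhouette floor; when the best
#'   value falls below it the result is flagged \code{noSubstructure}.
#' @return a \code{\linkS4class{ClusterResult}}.
#' @export
silhouetteSelectK <- function(x, kRange = 2:10, noStructureFloor = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2)) stop("kRange must be >= 2")
  kRange <- kRange[kRange < nrow(x)]
  if (!length(kRange))
    stop("no feasible k: need more observations than clusters")
  d <- dist(x)
  hc <- hclust(d, method = "ward.D2")
  sil <- vapply(kRange, function(k) {
    labels <- cutree(hc, k = k)
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- kRange
  kBest <- kRange[which.max(sil)]
  labels <- cutree(hc, k = kBest)
  if (!is.null(rownames(x))) names(labels) <- rownames(x)
  flag <- !is.null(noStructureFloor) && max(sil) < noStructureFloor
  new("ClusterResult", labels = as.integer(labels) |>
        setNames(names(labels)), k = as.integer(kBest),
      silhouetteByK = sil, noSubstructure = flag)
}

#' Shapiro-Wilk normality check
#'
#' Wraps \code{stats::shapiro.test} (3 <= n <= 5000). A constant vector
#' has an undefined W; it is reported as non-normal (p = 0) with a
#' warning. Recorded as a gate for reporting; downstream comparisons
#' always proceed nonparametrically.
#'
#' @param x numeric vector.
#' @return list with \code{statistic} (W), \code{p.value}, \code{method}.
#' @export
shapiroWilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (length(unique(x)) == 1) {
    warning("constant vector: W undefined, reported as non-normal")
    return(list(statistic = NA_real_, p.value = 0,
                method = "Shapiro-Wilk (degenerate)"))
  }
  st <- shapiro.test(x)
  list(statistic = unname(st$statistic), p.value = st$p.value,
       method = "Shapiro-Wilk")
}
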