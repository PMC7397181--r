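#' Statistical tests used across the pipeline
#'
#' Thin, uniformly-shaped wrappers around the classical tests the analysis
#' relies on. Every function returns a one-row \code{data.frame} with columns
#' \code{test}, \code{statistic}, \code{p_value}, \code{n1}, \code{n2},
#' \code{estimate1}, \code{estimate2} and \code{direction}.
#'
#' @name splice-stats
NULL

.testResult <- function(test, statistic, p_value, n1, n2 = NA_integer_,
                        estimate1 = NA_real_, estimate2 = NA_real_,
                        direction = NA_character_) {
  data.frame(test = test, statistic = as.numeric(statistic),
             p_value = as.numeric(p_value), n1 = n1, n2 = n2,
             estimate1 = estimate1, estimate2 = estimate2,
             direction = direction, stringsAsFactors = FALSE)
}

#' Mood's median test
#'
#' Counts of values above vs at-or-below the grand median form a 2x2 table;
#' ties at the median are assigned to the "at or below" cell. The table is
#' tested by chi-square with continuity correction when all expected counts
#' are at least 5, otherwise by Fisher's exact test.
#'
#' @param x,y numeric samples (combined length >= 4).
#' @return A test-result \code{data.frame} (see \link{splice-stats});
#'   \code{estimate1}/\code{estimate2} are the group medians.
#' @export
moodsMedianTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) + length(y) < 4)
    stop("Mood's median test needs a combined sample size of at least 4")
  gm <- stats::median(c(x, y))
  tab <- rbind(x = c(above = sum(x > gm), below = sum(x <= gm)),
               y = c(above = sum(y > gm), below = sum(y <= gm)))
  if (sum(tab[, "above"]) == 0) {
    warning("all values tie at the grand median; p = 1")
    return(.testResult("moods_median", 0, 1, length(x), length(y),
                       stats::median(x), stats::median(y), "none"))
  }
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(exp_counts >= 5)) {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    stat <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(tab)
    stat <- unname(ht$estimate)
  }
  mx <- stats::median(x); my <- stats::median(y)
  .testResult("moods_median", stat, min(1, ht$p.value), length(x), length(y),
              mx, my,
              if (mx > my) "x_greater" else if (mx < my) "y_greater" else "none")
}

#' Welch two-sample t-test
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param two_tailed logical; two-sided by default.
#' @return A test-result \code{data.frame}; estimates are the group means.
#' @export
welchTTest <- function(x, y, two_tailed = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  alt <- if (two_tailed) "two.sided" else "greater"
  ht <- stats::t.test(x, y, alternative = alt, var.equal = FALSE)
  mx <- mean(x); my <- mean(y)
  .testResult("welch_t", unname(ht$statistic), ht$p.value,
              length(x), length(y), mx, my,
              if (mx > my) "x_greater" else if (mx < my) "y_greater" else "none")
}

#' Exact two-sided binomial test
#'
#' Two-sided p-value by summing point probabilities not exceeding the
#' observed one (the classical exact construction).
#'
#' @param k number of successes, \code{0 <= k <= n}.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return A test-result \code{data.frame}; \code{estimate1} is k/n.
#' @export
binomialTest <- function(k, n, p0 = 0.5) {
  if (n < 1 || k < 0 || k > n) stop("invalid counts for binomial test")
  ht <- stats::binom.test(k, n, p = p0, alternative = "two.sided")
  .testResult("binomial", k, ht$p.value, n, NA_integer_, k / n, p0,
              if (k / n > p0) "above_null" else if (k / n < p0) "below_null"
              else "none")
}

#' Hypergeometric enrichment (upper tail)
#'
#' Probability of drawing at least \code{hits} members of a category of size
#' \code{category_size} when sampling \code{draw_size} items without
#' replacement from a universe of \code{universe_size}.
#'
#' @param hits,draw_size,category_size,universe_size integer counts.
#' @return A test-result \code{data.frame}; \code{estimate1} is the observed
#'   hit fraction, \code{estimate2} the expected fraction.
#' @export
hypergeomEnrichment <- function(hits, draw_size, category_size,
                                universe_size) {
  if (any(c(hits, draw_size, category_size, universe_size) < 0) ||
      hits > draw_size || hits > category_size ||
      draw_size > universe_size || category_size > universe_size)
    stop("inconsistent counts for hypergeometric test")
  p <- stats::phyper(hits - 1, category_size, universe_size - category_size,
                     draw_size, lower.tail = FALSE)
  .testResult("hypergeometric", hits, p, draw_size, category_size,
              hits / max(draw_size, 1), category_size / universe_size,
              "enrichment")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bhFDR <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Gene-set enrichment over user-supplied sets
#'
#' Hypergeometric upper-tail enrichment of a query gene list against each
#' gene set, BH-corrected. The universe defaults to the union of all sets.
#'
#' @param genes character vector of query gene ids.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of background gene ids.
#' @param fdr report sets with q below this threshold flagged as significant.
#' @return data.frame with one row per gene set: hits, sizes, p, q,
#'   significant.
#' @export
geneSetEnrichment <- function(genes, gene_sets, universe = NULL,
                              fdr = 0.001) {
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  genes <- intersect(unique(genes), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    hits <- length(intersect(genes, set))
    tr <- hypergeomEnrichment(hits, length(genes), length(set),
                              length(universe))
    data.frame(set = nm, hits = hits, set_size = length(set),
               query_size = length(genes), universe_size = length(universe),
               p_value = tr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhFDR(out$p_value)
  out$significant <- out$q_value < fdr
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids,
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
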