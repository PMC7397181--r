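# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force or by a structurally different rule set, so
# agreement is informative.

# ---- Boltzmann enumeration over nested structures (structure oracle) ----
enumPairProbs <- function(seq, w = exp(2), minh = 3) {
  v <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(v)
  canp <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- new.env()
  enum <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    for (s in enum(i + 1, j)) out[[length(out) + 1]] <- s
    if (i + minh + 1 <= j) {
      for (k in (i + minh + 1):j) {
        if (!canp(v[i], v[k])) next
        inner <- enum(i + 1, k - 1)
        outer <- enum(k + 1, j)
        for (a in inner) for (b in outer)
          out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  ss <- enum(1, n)
  P <- matrix(0, n, n)
  Z <- 0
  for (s in ss) {
    wt <- w^length(s)
    Z <- Z + wt
    for (p in s) P[p[1], p[2]] <- P[p[1], p[2]] + wt
  }
  P <- P / Z
  P + t(P)
}

# ---- junction-set event-kind oracle for two-isoform genes ----
# Works in transcript orientation (coordinates negated and flipped for
# minus-strand genes), then classifies by direct pattern matching on the
# exon lists -- a rule set independent of the package's pairwise scanner.
oracleEventKind <- function(em1, em2, strand) {
  tf <- function(m) {
    if (strand == "-") {
      m <- cbind(-m[, 2], -m[, 1])
    }
    m[order(m[, 1]), , drop = FALSE]
  }
  A <- tf(em1); B <- tf(em2)
  n1 <- nrow(A); n2 <- nrow(B)
  rowsEqual <- function(X, Y)
    nrow(X) == nrow(Y) && all(X == Y)
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  if (n1 == n2) {
    diffs <- which(A[, 1] != B[, 1] | A[, 2] != B[, 2])
    if (length(diffs) != 1) return(NA_character_)
    k <- diffs
    a <- A[k, ]; b <- B[k, ]
    if (k > 1 && k < n1) {
      if (a[1] != b[1] && a[2] == b[2]) return("A3")
      if (a[1] == b[1] && a[2] != b[2]) return("A5")
      if (!overlap(a, b)) return("MX")
      return(NA_character_)
    }
    if (k == 1) {
      if (a[2] != b[2]) return(if (overlap(a, b)) "A5" else "AF")
      return(NA_character_)
    }
    # k == n1
    if (a[1] != b[1]) return(if (overlap(a, b)) "A3" else "AL")
    return(NA_character_)
  }
  if (abs(n1 - n2) == 1) {
    L <- if (n1 > n2) A else B
    S <- if (n1 > n2) B else A
    nL <- nrow(L)
    for (k in 2:(nL - 1)) {
      if (rowsEqual(L[-k, , drop = FALSE], S)) return("SE")
    }
    for (k in seq_len(nL - 1)) {
      fused <- L
      fused[k, 2] <- L[k + 1, 2]
      fused <- fused[-(k + 1), , drop = FALSE]
      if (rowsEqual(fused, S)) return("RI")
    }
  }
  NA_character_
}

# ---- exact small-sample oracle for Mood's median test ----
# enumerate the hypergeometric support of the dichotomized table and sum
# probabilities of tables at least as extreme (by table probability).
oracleMoodsP <- function(x, y) {
  gm <- median(c(x, y))
  a <- sum(x > gm)
  m <- sum(c(x, y) > gm)
  n_tot <- length(x) + length(y)
  probs <- dhyper(0:m, m, n_tot - m, length(x))
  sum(probs[probs <= probs[a + 1] + 1e-12])
}

# ---- PWM score distribution by full k-mer enumeration ----
oraclePwmThreshold <- function(pwm, quantile) {
  lo <- log2(pwm / 0.25)
  k <- ncol(lo)
  grid <- expand.grid(rep(list(1:4), k))
  scores <- apply(grid, 1, function(idx) sum(lo[cbind(idx, seq_len(k))]))
  scores <- sort(scores)
  n <- length(scores)
  # smallest support value with P(score >= t) <= 1 - quantile
  tail_p <- (n - seq_len(n) + 1) / n
  uniq <- !duplicated(scores)
  cand <- scores[uniq & tail_p <= 1 - quantile + 1e-12]
  # recompute exactly on unique support
  us <- unique(scores)
  pv <- vapply(us, function(t) mean(scores >= t - 1e-12), numeric(1))
  ok <- us[pv <= 1 - quantile]
  if (length(ok)) min(ok) else Inf
}

# random small TranscriptSet + expression for property tests
randomUsageTable <- function(seed) {
  cfg <- simulationConfig(n_genes = 15, frac_switching_genes = 0.3,
                          ri_nuclear_frac = 0.3, noise_cv = 0.2,
                          seed = seed)
  ann <- simulateAnnotation(cfg)
  fe <- simulateExpression(ann$ts, ann$truth, cfg)
  list(ts = ann$ts, fe = fe, truth = ann$truth)
}
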