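# Independent oracles used by the property tests.  These are deliberately
# naive implementations (full dynamic programs, exhaustive enumeration,
# closed forms) kept separate from the package's own code paths.

# full Gotoh DP, score only, conversion-aware; gap of length k costs
# open + k * ext
oracle_gotoh_score <- function(ref, read, strand, match = 2, mismatch = -3,
                               open = -6, ext = -1, conv = 2) {
  r <- strsplit(ref, "")[[1]]; q <- strsplit(read, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -1e18
  score <- function(a, b) {
    if (strand == "OT" && a == "C" && (b == "C" || b == "T")) return(conv)
    if (strand == "OB" && a == "G" && (b == "G" || b == "A")) return(conv)
    if (a == b) match else mismatch
  }
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- open + (j - 1) * ext
  for (i in 2:(n + 1)) X[i, 1] <- open + (i - 1) * ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] + open + ext, X[i - 1, j] + ext,
                   Y[i - 1, j] + open + ext)
    Y[i, j] <- max(M[i, j - 1] + open + ext, Y[i, j - 1] + ext,
                   X[i, j - 1] + open + ext)
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      score(r[i - 1], q[j - 1])
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive minimum-total-|coverage difference| matching within genotype
# strata (all permutations; feasible for <= 6x6 toys)
oracle_match_pairs <- function(cases, controls) {
  geno <- function(d) paste(pmin(d$hap1, d$hap2), pmax(d$hap1, d$hap2))
  cg <- geno(cases); kg <- geno(controls)
  best <- NULL
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  n <- nrow(cases)
  for (p in perm(seq_len(nrow(controls)))) {
    sel <- p[seq_len(min(n, length(p)))]
    if (any(kg[sel] != cg[seq_along(sel)])) next
    cost <- sum(abs(cases$mean_coverage[seq_along(sel)] -
                      controls$mean_coverage[sel]))
    if (is.null(best) || cost < best$cost)
      best <- list(cost = cost,
                   pairs = data.frame(case_id = cases$subject_id[seq_along(sel)],
                                      control_id = controls$subject_id[sel]))
  }
  best
}

# direct Benjamini-Hochberg step-up formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# maximum-likelihood logistic fit by direct optimization of the
# log-likelihood (independent of glm's IRLS)
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) {
    p <- 1 / (1 + exp(-X %*% b))
    as.numeric(t(X) %*% (p - y))
  }
  opt <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# a tiny toy catalog with letter-compatible alleles: three haplotypes over
# seven markers (two indels), the risk haplotype carrying every alt allele
toy_catalog <- function() {
  mk <- data.frame(
    marker_id = sprintf("t%d", 1:7),
    coord = c(110, 150, 200, 260, 320, 380, 440),
    ref_allele = c("A", "C",   "A", "G", "A", "G", "T"),
    alt_allele = c("T", "CGG", "G", "A", "C", "A", "TAG"),
    creates_cpg = FALSE)
  haplotype_catalog(mk, list(
    hapRR = c("A", "C",   "A", "G", "A", "G", "T"),
    hapRI = c("A", "C",   "A", "G", "A", "G", "TAG"),
    hapAA = c("T", "CGG", "G", "A", "C", "A", "TAG")),
    risk_haplotype = "hapAA")
}
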