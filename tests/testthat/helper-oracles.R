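# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Upper-tail phasing probability by exhaustive subset enumeration:
# positions 1..N, the first K are "phased"; draw n distinct positions and
# count draws with >= k phased. Feasible for N <= 15.
enumerate_phasing_tail <- function(n, k, N, K) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins, summing point probabilities <= the observed one (with the
# customary 1 + 1e-7 tolerance for ties).
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sample K-S D statistic and exact p by enumeration of all label
# assignments of the pooled sample (valid with ties).
ks_D_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

enumerate_ks_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  d_obs <- ks_D_stat(a, b)
  idx <- utils::combn(length(pooled), n1)
  ds <- apply(idx, 2, function(i) ks_D_stat(pooled[i], pooled[-i]))
  mean(ds >= d_obs - 1e-12)
}

# Naive duplex penalty: direct per-position comparison of the sRNA with
# the reverse of the target site, written independently of the package's
# lookup-table scanner.
naive_duplex_score <- function(srna, site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(srna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])
  total <- 0
  for (i in seq_along(s)) {
    pen <- if (comp[[s[i]]] == t[i]) {
      0
    } else if ((s[i] == "G" && t[i] == "T") || (s[i] == "T" && t[i] == "G")) {
      0.5
    } else {
      1
    }
    if (i >= 2 && i <= 13) pen <- 2 * pen
    total <- total + pen
  }
  total
}

# All windows of a transcript scoring at most `cutoff` against the sRNA.
naive_site_scan <- function(srna, transcript, cutoff) {
  len <- nchar(srna)
  starts0 <- 0:(nchar(transcript) - len)
  scores <- vapply(starts0, function(w) {
    naive_duplex_score(srna, substr(transcript, w + 1, w + len))
  }, numeric(1))
  data.frame(start = starts0, score = scores)[scores <= cutoff, ]
}

# Independent degradome category (a restatement of the rank rules).
naive_category <- function(profile, pos) {
  c0 <- profile[pos]
  nz <- profile[profile > 0]
  if (c0 == 0) return(NA_integer_)
  if (c0 == 1) return(4L)
  if (c0 == max(nz)) return(if (sum(nz == max(nz)) == 1) 0L else 1L)
  if (c0 > median(nz)) 2L else 3L
}

dinucleotide_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 2) return(table(character(0)))
  table(paste0(chars[-length(chars)], chars[-1]))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Feature-wise time x replicate matrix from a libraries-in-columns matrix.
feature_tp_matrix <- function(counts, feature) {
  tps <- deetiolR::TIME_POINTS
  reps <- sort(unique(as.integer(sub("^W[0-9]+_", "", colnames(counts)))))
  m <- matrix(0, length(tps), length(reps), dimnames = list(tps, reps))
  for (lib in colnames(counts)) {
    tp <- sub("_[0-9]+$", "", lib)
    r <- sub("^W[0-9]+_", "", lib)
    m[tp, r] <- counts[feature, lib]
  }
  m
}
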