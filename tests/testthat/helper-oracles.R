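# Independent reference implementations used as oracles. They share no code
# with the package internals beyond base R.

rand_dna <- function(n, p = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# positionwise match count via vector comparison
oracle_match_count <- function(a, b) {
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# exhaustive maximization over all k-mer pairs of two windows
oracle_edge_weight <- function(kmers_u, kmers_v) {
  if (length(kmers_u) == 0 || length(kmers_v) == 0) return(NA_integer_)
  max(outer(kmers_u, kmers_v, Vectorize(oracle_match_count)))
}

# all k-mers of a window text
oracle_kmers <- function(text, k) {
  n <- nchar(text)
  if (n < k) return(character(0))
  vapply(1:(n - k + 1), function(i) substr(text, i, i + k - 1), "")
}

# symmetric random weighted graph; weights uniform on 1..wmax
random_weight_graph <- function(nv, p, wmax = 8) {
  W <- matrix(0, nv, nv)
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      if (runif(1) < p) W[i, j] <- W[j, i] <- sample.int(wmax, 1)
    }
  }
  W
}

oracle_is_clique <- function(W, members) {
  if (length(members) < 2) return(TRUE)
  all(W[members, members][upper.tri(diag(length(members)))] > 0)
}

oracle_is_maximal_clique <- function(W, members) {
  if (!oracle_is_clique(W, members)) return(FALSE)
  outside <- setdiff(seq_len(nrow(W)), members)
  !any(vapply(outside, function(u) all(W[u, members] > 0), logical(1)))
}

# direct textbook formulas, coded separately from accuracy_metrics()
oracle_metrics <- function(tp, fp, fn) {
  safe <- function(x, y) ifelse(y == 0, 0, x / y)
  sn <- safe(tp, tp + fn)
  sp <- safe(tp, tp + fp)
  c(sn = sn, sp = sp, pc = safe(tp, tp + fp + fn),
    f = safe(2 * sn * sp, sn + sp))
}

# interval overlap of two 0-based half-open site rows
oracle_overlap <- function(s1, l1, s2, l2) {
  max(0, min(s1 + l1, s2 + l2) - max(s1, s2))
}

# clique stand-in for merge tests
fake_clique <- function(members, weight_sum = length(members), seed = members[1]) {
  structure(list(members = sort(members), weight_sum = weight_sum,
                 size = length(members), seed = seed),
            class = "clique")
}
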