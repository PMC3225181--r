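#' Sum of squared distance between two base compositions
#'
#' SSD is \eqn{\sum_b (p(b) - q(b))^2} over the four bases. A binding site
#' whose composition is close to the background has a small SSD; the k-mer
#' filters exclude candidates whose SSD against the background exceeds a
#' cutoff (default 0.3) because almost all curated binding sites fall below
#' it, while higher-SSD words are typically low-complexity background.
#'
#' @param p,q Named base-frequency vectors as from [base_frequencies()].
#' @return A number in \[0, 2\]; symmetric in its arguments.
#' @examples
#' ssd(base_frequencies("AAAAAAAA"), c(A = .25, C = .25, G = .25, T = .25))
#' @export
ssd <- function(p, q) {
  stopifnot(all(DNA_BASES %in% names(p)), all(DNA_BASES %in% names(q)))
  sum((p[DNA_BASES] - q[DNA_BASES])^2)
}

#' k-mer filter configuration
#'
#' A k-mer is admitted as a candidate site only if (1) its SSD against the
#' background composition is at most `ssd_cutoff`, (2) its longest
#' single-nucleotide run does not exceed `max_run_fraction` of its length,
#' and (3) it contains at least `min_base_types` distinct bases. The
#' defaults (0.3, 0.6, 3) retain the overwhelming majority of curated
#' binding sites while discarding low-complexity words.
#'
#' @param ssd_cutoff SSD threshold in (0, 1.5]; lower it (e.g. to 0.06) to
#'   focus on motifs whose composition closely matches the background.
#' @param max_run_fraction Maximum allowed single-base run, as a fraction of
#'   k, in (0, 1].
#' @param min_base_types Minimum number of distinct bases, 1..4.
#' @param background Named base-frequency vector \eqn{\{q(b)\}} of the
#'   background (uniform by default; [build_graph()] substitutes the pooled
#'   input composition when no configuration is supplied).
#' @return An object of class `"filter_config"`.
#' @export
filter_config <- function(ssd_cutoff = 0.3, max_run_fraction = 0.6,
                          min_base_types = 3L,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)) {
  stopifnot(ssd_cutoff > 0, ssd_cutoff <= 1.5,
            max_run_fraction > 0, max_run_fraction <= 1,
            min_base_types %in% 1:4,
            all(DNA_BASES %in% names(background)),
            abs(sum(background) - 1) < 1e-9)
  structure(list(ssd_cutoff = ssd_cutoff,
                 max_run_fraction = max_run_fraction,
                 min_base_types = as.integer(min_base_types),
                 background = background[DNA_BASES]),
            class = "filter_config")
}

#' Test k-mers for admissibility as candidate sites
#'
#' Applies the three composition filters of [filter_config()]. k-mers
#' containing ambiguity codes are inadmissible (match counting is defined
#' only over concrete bases), not an error.
#'
#' @param kmers Character vector of equal-length k-mers.
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per k-mer.
#' @export
kmer_admissible <- function(kmers, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  k <- nchar(kmers[1L])
  vapply(kmers, function(km) {
    chars <- strsplit(km, "")[[1]]
    idx <- match(chars, DNA_BASES)
    if (anyNA(idx)) return(FALSE)
    counts <- tabulate(idx, nbins = 4L)
    if (sum(counts > 0L) < cfg$min_base_types) return(FALSE)
    if (max(rle(chars)$lengths) > cfg$max_run_fraction * k) return(FALSE)
    p <- setNames(counts / k, DNA_BASES)
    ssd(p, cfg$background) <= cfg$ssd_cutoff
  }, logical(1), USE.NAMES = FALSE)
}

#' Number of matching positions between two k-mers
#'
#' @param a,b DNA strings of equal length.
#' @return Integer in \[0, k\].
#' @export
kmer_match_count <- function(a, b) match_count_cpp(a, b)

#' Decompose a sequence into 2(k-1)-mer windows
#'
#' Windows start every k-1 bases, so adjacent windows overlap by k-1 bases
#' and every k-mer of the sequence lies in exactly one window. The last
#' window may be shorter than 2(k-1) but is only emitted when it still
#' contains a k-mer (length >= k); a shorter tail holds no k-mer that is not
#' already covered.
#'
#' @param seq A DNA string.
#' @param k Motif length (>= 4).
#' @return Data frame with columns `start` (0-based window offset) and
#'   `text`; zero rows (with a warning) when the sequence is shorter than k.
#' @examples
#' decompose_windows(strrep("ACGT", 5), k = 8)  # length 20: windows 0, 7
#' @export
decompose_windows <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 4L)
  L <- nchar(seq)
  if (L < k) {
    warning("sequence shorter than k (", L, " < ", k, "); no windows")
    return(data.frame(start = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(0L, L - k, by = k - 1L)
  data.frame(start = starts,
             text = substring(seq, starts + 1L,
                              pmin(starts + 2L * (k - 1L), L)),
             stringsAsFactors = FALSE)
}

# All k-mers of a window text with their 0-based offsets inside the window.
window_kmer_offsets <- function(text, k) 0:(nchar(text) - k)

#' Edge weight between two windows
#'
#' The weight is the maximum match count over all pairs of admissible
#' k-mers, one from each window; `NA` when either list is empty.
#'
#' @param kmers_u,kmers_v Character vectors of admissible k-mers.
#' @return Integer weight, or `NA_integer_`.
#' @export
edge_weight <- function(kmers_u, kmers_v) {
  if (length(kmers_u) == 0L || length(kmers_v) == 0L) return(NA_integer_)
  e <- window_pair_weights_cpp(c(kmers_u, kmers_v),
                               c(0L, length(kmers_u),
                                 length(kmers_u) + length(kmers_v)),
                               1L)
  if (nrow(e) == 0L) 0L else e$w[1L]
}

#' Estimate the edge-weight cutoff alpha by background sampling
#'
#' Draws N = max(10, ceiling(n/4)) k-mers uniformly from all k-mer positions
#' of the input set; each sampled k-mer is scanned against the n-1 other
#' sequences, recording the maximum match count per sequence. The smallest
#' 5\% of the (n-1)N values are trimmed and the rest averaged into
#' \eqn{\bar\mu}, the expected best background match. The default cutoff is
#' \eqn{\lfloor\bar\mu\rfloor + 1} (one match above background); the
#' `"degenerate"` stringency uses \eqn{\lfloor\bar\mu\rfloor} to admit more
#' degenerate sites. Both are capped at k and floored at 1.
#'
#' @param seqs Named character vector of sequences (n >= 2, all of length
#'   >= k).
#' @param k Motif length.
#' @param stringency `"default"` or `"degenerate"` (the latter corresponds
#'   to a `-s 0`-style lowered cutoff).
#' @param seed Optional integer seed making the sampling reproducible.
#' @param trim Fraction of smallest match values removed before averaging.
#' @return List of class `"alpha_estimate"` with elements `alpha`, `mu_bar`,
#'   `n_sampled` and the raw `values`.
#' @export
estimate_alpha <- function(seqs, k, stringency = c("default", "degenerate"),
                           seed = NULL, trim = 0.05) {
  stringency <- match.arg(stringency)
  n <- length(seqs)
  if (n < 2L) stop("alpha estimation needs at least 2 sequences")
  if (any(nchar(seqs) < k)) stop("all sequences must be at least k bases")
  npos <- nchar(seqs) - k + 1L
  total <- sum(npos)
  N <- max(10L, as.integer(ceiling(n / 4)))
  vals <- with_seed(seed, {
    idx <- sample.int(total, N, replace = total < N)
    ends <- cumsum(npos)
    src <- findInterval(idx - 1L, ends) + 1L   # source sequence of each draw
    pos <- idx - c(0L, ends)[src]              # 1-based k-mer start
    unlist(lapply(seq_len(N), function(i) {
      a <- substr(seqs[[src[i]]], pos[i], pos[i] + k - 1L)
      vapply(seq_len(n)[-src[i]], function(j)
        scan_max_match_cpp(a, seqs[[j]]), integer(1))
    }))
  })
  sorted <- sort(vals)
  drop <- floor(trim * length(sorted))
  mu <- mean(sorted[(drop + 1L):length(sorted)])
  alpha <- if (stringency == "default") floor(mu) + 1 else floor(mu)
  alpha <- as.integer(max(1, min(alpha, k)))
  structure(list(alpha = alpha, mu_bar = mu, n_sampled = N,
                 values = vals, stringency = stringency),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("alpha estimate: alpha = %d (mu_bar = %.3f, %d sampled k-mers, %s stringency)\n",
              x$alpha, x$mu_bar, x$n_sampled, x$stringency))
  invisible(x)
}

#' Build the window similarity graph
#'
#' Decomposes every sequence into 2(k-1)-mer windows, filters each window's
#' k-mers through `cfg`, and connects every pair of windows (including pairs
#' from the same sequence) whose maximum k-mer match count reaches `alpha`.
#' If the density |E|/|V| exceeds `max_density`, alpha is incremented and the
#' edges re-thresholded until the graph is sparse enough or alpha reaches k;
#' the final alpha is recorded on the graph and reused by the refinement
#' stage.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param k Motif length.
#' @param cfg A [filter_config()]; when `NULL`, the default filters are used
#'   with the pooled input composition as background.
#' @param alpha Integer match cutoff in \[1, k\], typically from
#'   [estimate_alpha()].
#' @param max_density Maximum mean number of edges per vertex.
#' @param revcomp Also add windows of the reverse-complement strand as extra
#'   vertices (tagged strand "-").
#' @return An object of class `"word_graph"`: window table, admissible k-mer
#'   table, edge list (`u`, `v`, `w`), the final `alpha`, and input metadata.
#' @export
build_graph <- function(seqs, k, cfg = NULL, alpha, max_density = 20,
                        revcomp = FALSE) {
  stopifnot(length(seqs) >= 1L, k >= 4L)
  if (inherits(alpha, "alpha_estimate")) alpha <- alpha$alpha
  stopifnot(alpha >= 1L, alpha <= k)
  if (is.null(cfg)) cfg <- filter_config(background = pooled_base_frequencies(seqs))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))

  strands <- if (revcomp) c("+", "-") else "+"
  win <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    do.call(rbind, lapply(strands, function(st) {
      s <- if (st == "+") seqs[[i]] else revcomp(seqs[[i]])
      if (nchar(s) < k) return(NULL)
      w <- decompose_windows(s, k)
      if (nrow(w) == 0L) return(NULL)
      cbind(data.frame(seq_index = i - 1L, seq_id = ids[i], strand = st,
                       stringsAsFactors = FALSE), w)
    }))
  }))
  if (is.null(win) || nrow(win) == 0L)
    stop("no windows: all sequences shorter than k")

  km <- do.call(rbind, lapply(seq_len(nrow(win)), function(wi) {
    off <- window_kmer_offsets(win$text[wi], k)
    data.frame(window = wi, off = win$start[wi] + off,
               text = substring(win$text[wi], off + 1L, off + k),
               stringsAsFactors = FALSE)
  }))
  km <- km[kmer_admissible(km$text, cfg), , drop = FALSE]
  keep <- sort(unique(km$window))
  if (length(keep) == 0L)
    stop("no candidate k-mers survive filters; raise the SSD cutoff")
  win <- win[keep, , drop = FALSE]
  km$window <- match(km$window, keep)
  rownames(win) <- rownames(km) <- NULL
  nv <- nrow(win)

  km <- km[order(km$window, km$off), , drop = FALSE]
  ptr <- c(0L, cumsum(tabulate(km$window, nbins = nv)))
  edges_all <- window_pair_weights_cpp(km$text, ptr, alpha)

  a <- as.integer(alpha)
  edges <- edges_all
  while (nrow(edges) / nv > max_density && a < k) {
    a <- a + 1L
    edges <- edges_all[edges_all$w >= a, , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(windows = win, kmers = km, edges = edges,
                 alpha = a, alpha_initial = as.integer(alpha), k = as.integer(k),
                 n_seq = length(seqs), seq_ids = ids, seq_len = nchar(seqs),
                 cfg = cfg),
            class = "word_graph")
}

#' @export
print.word_graph <- function(x, ...) {
  cat(sprintf("word graph: %d vertices, %d edges, k = %d, alpha = %d (initial %d), %d sequences\n",
              nrow(x$windows), nrow(x$edges), x$k, x$alpha,
              x$alpha_initial, x$n_seq))
  invisible(x)
}
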