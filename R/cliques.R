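#' Build a word graph from an explicit weight matrix
#'
#' Utility for experimenting with the clique stage on arbitrary weighted
#' graphs: wraps a symmetric weight matrix (0 = no edge) into a minimal
#' `"word_graph"` object without window or k-mer annotation.
#'
#' @param W Symmetric numeric matrix with zero diagonal.
#' @param k Nominal motif length recorded on the graph.
#' @return A `"word_graph"` whose vertices are the matrix rows.
#' @export
word_graph_from_weights <- function(W, k = 8L) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W == t(W)),
            all(diag(W) == 0), all(W >= 0))
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(u = idx[, 1L], v = idx[, 2L], w = W[idx])
  win <- data.frame(seq_index = rep(NA_integer_, n),
                    seq_id = sprintf("v%d", seq_len(n)),
                    strand = "+", start = NA_integer_,
                    text = NA_character_, stringsAsFactors = FALSE)
  structure(list(windows = win, kmers = NULL, edges = edges,
                 alpha = 1L, alpha_initial = 1L, k = as.integer(k),
                 n_seq = 0L, seq_ids = character(), seq_len = integer(),
                 cfg = NULL),
            class = "word_graph")
}

# Sparse symmetric weight matrix of a word graph.
graph_weight_matrix <- function(graph) {
  n <- nrow(graph$windows)
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e$u, e$v), j = c(e$v, e$u), x = c(e$w, e$w),
                       dims = c(n, n))
}

#' Neighborhood subgraph of a vertex
#'
#' The subgraph induced by a vertex and its neighbors; every maximal clique
#' containing the vertex lies inside it.
#'
#' @param graph A `"word_graph"`.
#' @param v Vertex id (1-based row of the window table).
#' @return List of class `"nbhd_subgraph"` with the member vertex ids
#'   (`vids`, sorted, including `v`) and the dense induced weight matrix `W`.
#' @export
neighborhood_subgraph <- function(graph, v) {
  n <- nrow(graph$windows)
  if (!(v >= 1L && v <= n)) stop("unknown vertex: ", v)
  W <- graph_weight_matrix(graph)
  nbhd_from_sparse(W, v)
}

nbhd_from_sparse <- function(W, v) {
  nb <- which(W[, v] != 0)
  vids <- sort(unique(c(v, nb)))
  structure(list(vids = vids,
                 W = as.matrix(W[vids, vids, drop = FALSE]),
                 seed = v),
            class = "nbhd_subgraph")
}

#' Greedy maximal weighted clique around a seed vertex
#'
#' Starting from the full neighborhood subgraph, repeatedly deletes the
#' minimum-degree vertex among the seed's neighbors (never the seed itself)
#' until the remainder is a clique; degree ties are broken by the smaller
#' sum of incident edge weights, then by the lower vertex id. If any outside
#' vertex of the subgraph is adjacent to every member of the remainder it is
#' re-added (in id order), so the result is always a maximal clique of the
#' parent graph containing the seed. Runs in O(d(v)^2) for seed degree d(v).
#'
#' @param nsub A `"nbhd_subgraph"` from [neighborhood_subgraph()], or a
#'   `"word_graph"` (in which case the neighborhood of `v` is taken first).
#' @param v Seed vertex id.
#' @return List of class `"clique"` with sorted `members`, the summed
#'   internal edge weight `weight_sum`, `size` and the `seed` vertex.
#' @export
greedy_max_clique <- function(nsub, v) {
  if (inherits(nsub, "word_graph")) nsub <- neighborhood_subgraph(nsub, v)
  stopifnot(inherits(nsub, "nbhd_subgraph"), v %in% nsub$vids)
  greedy_clique_core(nsub$W, nsub$vids, v)
}

greedy_clique_core <- function(W, vids, seed) {
  n <- length(vids)
  A <- W > 0
  seed_pos <- match(seed, vids)
  alive <- rep(TRUE, n)
  deg <- colSums(A)
  wsum <- colSums(W)
  n_alive <- n
  n_edges <- sum(deg) / 2

  while (n_edges < n_alive * (n_alive - 1) / 2) {
    cand <- which(alive)
    cand <- cand[cand != seed_pos]
    # min degree, then min incident weight, then lowest vertex id
    o <- order(deg[cand], wsum[cand], vids[cand])
    x <- cand[o[1L]]
    alive[x] <- FALSE
    nbx <- which(alive & A[, x])
    deg[nbx] <- deg[nbx] - 1L
    wsum[nbx] <- wsum[nbx] - W[nbx, x]
    n_edges <- n_edges - length(nbx)
    n_alive <- n_alive - 1L
  }

  members <- which(alive)
  # maximality guard: re-add outside vertices adjacent to all members
  outside <- which(!alive)
  for (u in outside[order(vids[outside])]) {
    if (all(A[u, members])) members <- c(members, u)
  }
  members <- sort(members)
  structure(list(members = vids[members],
                 weight_sum = sum(W[members, members]) / 2,
                 size = length(members), seed = seed),
            class = "clique")
}

#' @export
print.clique <- function(x, ...) {
  cat(sprintf("clique: %d vertices (seed %d), weight sum %.1f\n",
              x$size, x$seed, x$weight_sum))
  invisible(x)
}

#' One greedy maximal clique per vertex
#'
#' Applies [greedy_max_clique()] to the neighborhood subgraph of every
#' vertex, then collapses duplicate member sets (keeping the first seed).
#' Every vertex of the graph appears in at least one returned clique.
#'
#' @param graph A `"word_graph"`.
#' @return List of `"clique"` objects in seed order.
#' @export
all_vertex_cliques <- function(graph) {
  n <- nrow(graph$windows)
  W <- graph_weight_matrix(graph)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", n)
  m <- 0L
  for (v in seq_len(n)) {
    ns <- nbhd_from_sparse(W, v)
    cl <- greedy_clique_core(ns$W, ns$vids, v)
    key <- paste(cl$members, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      m <- m + 1L
      out[[m]] <- cl
    }
  }
  out[seq_len(m)]
}
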