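#' Clique merging configuration
#'
#' Two cliques are merged when either overlap rate r = |C ∩ C'|/|C'| reaches
#' `gamma` or R = |C ∩ C'|/|C| reaches `beta`, where C is the core clique
#' and C' the candidate. The defaults (3/4, 3/5) mean, intuitively, that a
#' 4-vertex clique sharing a triangle with the core, or a 5-vertex core
#' sharing a triangle with the candidate, is merged. `gamma > beta` because
#' candidates are usually no larger than the core.
#'
#' @param gamma Cutoff on r, in (0, 1].
#' @param beta Cutoff on R, strictly below `gamma`.
#' @return An object of class `"merge_config"`.
#' @export
merge_config <- function(gamma = 3 / 4, beta = 3 / 5) {
  stopifnot(beta > 0, beta < gamma, gamma <= 1)
  structure(list(gamma = gamma, beta = beta), class = "merge_config")
}

#' Select the core clique
#'
#' The core is the clique with the maximum sum of internal edge weights;
#' ties go to the larger member count, then the lowest seed vertex id.
#'
#' @param cliques Non-empty list of `"clique"` objects.
#' @return The selected `"clique"`.
#' @export
select_core_clique <- function(cliques) {
  if (length(cliques) == 0L) stop("no cliques to select a core from")
  ws <- vapply(cliques, `[[`, numeric(1), "weight_sum")
  sz <- vapply(cliques, `[[`, integer(1), "size")
  sd <- vapply(cliques, `[[`, numeric(1), "seed")
  cliques[[order(-ws, -sz, sd)[1L]]]
}

#' Overlap rates between a core clique and a candidate
#'
#' @param C Core clique.
#' @param Cp Candidate clique.
#' @return Named numeric vector `c(r = |C ∩ C'|/|C'|, R = |C ∩ C'|/|C|)`.
#' @export
overlap_rates <- function(C, Cp) {
  inter <- length(intersect(C$members, Cp$members))
  c(r = inter / Cp$size, R = inter / C$size)
}

#' Merge cliques around a core
#'
#' Selects the core clique, then traverses all other cliques once (in
#' descending weight-sum order) and absorbs each candidate whose overlap
#' with the core satisfies r >= gamma or R >= beta. Every test is against
#' the fixed core, so the traversal order does not affect membership.
#'
#' @param cliques Non-empty list of `"clique"` objects.
#' @param cfg A [merge_config()].
#' @return List of class `"merged_group"` with the `core`, the merged
#'   `members` (cliques, core first) and the `vertex_union`.
#' @export
merge_cliques <- function(cliques, cfg = merge_config()) {
  stopifnot(inherits(cfg, "merge_config"))
  core <- select_core_clique(cliques)
  core_key <- paste(core$members, collapse = ",")
  rest <- cliques[vapply(cliques, function(cl)
    !identical(paste(cl$members, collapse = ","), core_key), logical(1))]
  if (length(rest) > 0L) {
    ws <- vapply(rest, `[[`, numeric(1), "weight_sum")
    rest <- rest[order(-ws)]
  }
  members <- list(core)
  for (cl in rest) {
    rr <- overlap_rates(core, cl)
    if (rr[["r"]] >= cfg$gamma || rr[["R"]] >= cfg$beta)
      members <- c(members, list(cl))
  }
  structure(list(core = core, members = members,
                 vertex_union = sort(unique(unlist(
                   lapply(members, `[[`, "members"))))),
            class = "merged_group")
}

#' @export
print.merged_group <- function(x, ...) {
  cat(sprintf("merged group: %d cliques, %d vertices (core seed %d)\n",
              length(x$members), length(x$vertex_union), x$core$seed))
  invisible(x)
}

#' Refine a merged clique group into a motif
#'
#' Builds a multipartite k-mer graph G' over the admissible k-mers of the
#' merged group's windows: two k-mers from different windows are connected
#' when their match count reaches `alpha` (the graph cutoff). The final
#' motif is the largest closed neighborhood N* over all vertices of G';
#' size ties are broken by the larger total edge weight of the induced
#' neighborhood, then the lower vertex id. Each window contributes at most
#' one site: the member k-mer best matching the hub (ties to the leftmost).
#'
#' @param mc A `"merged_group"`.
#' @param graph The parent `"word_graph"` (provides k-mers, coordinates and
#'   the default cutoff).
#' @param alpha Match cutoff for k-mer pairs; defaults to the graph's alpha.
#' @return A `"motif"` (rank unset), or `NULL` when G' has no edges (a
#'   single-window degenerate group).
#' @export
refine_motif <- function(mc, graph, alpha = graph$alpha) {
  stopifnot(inherits(mc, "merged_group"), inherits(graph, "word_graph"))
  if (is.null(graph$kmers))
    stop("graph carries no k-mer table; build it with build_graph()")
  km <- graph$kmers[graph$kmers$window %in% mc$vertex_union, , drop = FALSE]
  if (nrow(km) < 2L) return(NULL)
  km <- km[order(km$window, km$off), , drop = FALSE]
  rownames(km) <- NULL

  M <- kmer_match_matrix_cpp(km$text)
  adj <- M >= alpha & outer(km$window, km$window, `!=`)
  nbsize <- colSums(adj) + 1L
  if (max(nbsize) < 2L) return(NULL)

  best <- which(nbsize == max(nbsize))
  if (length(best) > 1L) {
    wsum <- vapply(best, function(h) {
      nb <- c(h, which(adj[, h]))
      sum(M[nb, nb][adj[nb, nb]]) / 2
    }, numeric(1))
    best <- best[order(-wsum, best)]
  }
  hub <- best[1L]
  star <- c(hub, which(adj[, hub]))

  # one site per window: the member best matching the hub, ties leftmost
  picked <- integer(0)
  for (w in unique(km$window[star])) {
    cand <- star[km$window[star] == w]
    if (hub %in% cand) {
      picked <- c(picked, hub)
    } else {
      picked <- c(picked, cand[order(-M[cand, hub], km$off[cand])][1L])
    }
  }

  win <- graph$windows[km$window[picked], , drop = FALSE]
  start <- km$off[picked]
  neg <- win$strand == "-"
  if (any(neg)) {
    L <- graph$seq_len[win$seq_index[neg] + 1L]
    start[neg] <- L - start[neg] - graph$k
  }
  new_motif(data.frame(seq_index = win$seq_index, seq_id = win$seq_id,
                       start = start, strand = win$strand,
                       text = km$text[picked], stringsAsFactors = FALSE),
            k = graph$k)
}

#' Discover the top motifs in a sequence set
#'
#' Full pipeline: estimate the match cutoff alpha by background sampling,
#' build the window similarity graph, extract one greedy maximal clique per
#' vertex, then repeatedly (i) merge cliques around the current heaviest
#' core, (ii) refine the merged group into a motif, and (iii) drop the
#' merged cliques from the candidate list, until `top_n` motifs are found
#' or the cliques are exhausted. A window (and hence a sequence position)
#' may appear in more than one reported motif.
#'
#' @param seqs Named character vector of DNA sequences (n >= 2).
#' @param k Motif length (>= 4).
#' @param top_n Maximum number of motifs to report.
#' @param ssd_cutoff SSD filter cutoff (see [filter_config()]).
#' @param stringency `"default"` or `"degenerate"` cutoff rule for alpha
#'   (see [estimate_alpha()]).
#' @param max_density Density cap |E|/|V| of the window graph.
#' @param seed Optional integer seed; fixes the alpha sampling and makes the
#'   run fully reproducible.
#' @param revcomp Also scan the reverse-complement strand.
#' @param background Optional background sequence set used for the SSD
#'   filter composition (pooled input composition when `NULL`).
#' @param merge_cfg A [merge_config()].
#' @return List of `"motif"` objects ranked in extraction order, with
#'   attributes `alpha`, `mu_bar`, `n_vertices` and `n_edges` describing the
#'   run.
#' @examples
#' \donttest{
#' set.seed(1)
#' bg <- iid_markov3()
#' sites <- sample_site_strings("TGACTCAT", 20)
#' ds <- implant_sites(setNames(
#'   vapply(1:20, function(i) sample_background(bg, 400), ""),
#'   paste0("s", 1:20)), sites)
#' m <- find_motifs(ds$sequences, k = 8, top_n = 1, seed = 7)
#' m[[1]]
#' }
#' @export
find_motifs <- function(seqs, k, top_n = 5L, ssd_cutoff = 0.3,
                        stringency = c("default", "degenerate"),
                        max_density = 20, seed = NULL, revcomp = FALSE,
                        background = NULL, merge_cfg = merge_config()) {
  stringency <- match.arg(stringency)
  stopifnot(top_n >= 1L)
  bg_comp <- pooled_base_frequencies(if (is.null(background)) seqs else background)
  cfg <- filter_config(ssd_cutoff = ssd_cutoff, background = bg_comp)
  est <- estimate_alpha(seqs, k, stringency = stringency, seed = seed)
  graph <- build_graph(seqs, k, cfg = cfg, alpha = est$alpha,
                       max_density = max_density, revcomp = revcomp)
  cliques <- all_vertex_cliques(graph)

  motifs <- list()
  while (length(motifs) < top_n && length(cliques) > 0L) {
    mc <- merge_cliques(cliques, merge_cfg)
    motif <- refine_motif(mc, graph)
    merged_keys <- vapply(mc$members, function(cl)
      paste(cl$members, collapse = ","), character(1))
    keys <- vapply(cliques, function(cl)
      paste(cl$members, collapse = ","), character(1))
    cliques <- cliques[!keys %in% merged_keys]
    if (!is.null(motif)) {
      motif$rank <- length(motifs) + 1L
      motifs <- c(motifs, list(motif))
    }
  }
  if (length(motifs) < top_n)
    message(sprintf("only %d of %d requested motifs could be extracted",
                    length(motifs), top_n))
  structure(motifs, alpha = graph$alpha, mu_bar = est$mu_bar,
            n_vertices = nrow(graph$windows), n_edges = nrow(graph$edges))
}
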