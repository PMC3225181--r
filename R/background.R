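ALL_3MERS <- sort(do.call(paste0, expand.grid(DNA_BASES, DNA_BASES,
                                              DNA_BASES)[, 3:1]))

#' Fit a third-order Markov background model
#'
#' Estimates transition probabilities P(base | previous 3 bases) from 4-mer
#' counts pooled over a corpus (e.g. the intergenic sequences of a genome),
#' with add-`pseudocount` smoothing so every one of the 64 contexts is
#' defined. The initial distribution over starting 3-mers is estimated from
#' empirical 3-mer frequencies with the same smoothing. k-mers containing
#' ambiguity codes contribute nothing.
#'
#' @param seqs Named character vector of DNA sequences, total length >= 100
#'   bases.
#' @param pseudocount Smoothing count added per (context, base) cell
#'   (default 1). With `pseudocount = 0`, contexts never observed fall back
#'   to the uniform distribution.
#' @return Object of class `"markov3"` with a 64 x 4 `transition` matrix
#'   (rows = contexts in lexicographic order, columns A,C,G,T; rows sum to
#'   1) and a named `initial` vector over the 64 3-mers.
#' @export
fit_markov3 <- function(seqs, pseudocount = 1) {
  stopifnot(length(seqs) >= 1L, pseudocount >= 0)
  if (sum(nchar(seqs)) < 100L)
    stop("corpus too small to estimate a third-order model (< 100 bases)")
  x <- Biostrings::DNAStringSet(seqs)
  c4 <- colSums(Biostrings::oligonucleotideFrequency(x, width = 4L))
  c3 <- colSums(Biostrings::oligonucleotideFrequency(x, width = 3L))
  trans <- matrix(as.numeric(c4), nrow = 64L, ncol = 4L, byrow = TRUE,
                  dimnames = list(ALL_3MERS, DNA_BASES))
  denom <- rowSums(trans) + 4 * pseudocount
  trans <- (trans + pseudocount) / denom
  unseen <- !is.finite(rowSums(trans)) | rowSums(trans) == 0
  trans[unseen, ] <- 0.25
  initial <- (as.numeric(c3[ALL_3MERS]) + pseudocount) /
    (sum(c3) + 64 * pseudocount)
  if (sum(initial) == 0) initial <- rep(1 / 64, 64L)
  initial <- setNames(initial / sum(initial), ALL_3MERS)
  structure(list(transition = trans, initial = initial,
                 pseudocount = pseudocount),
            class = "markov3")
}

#' Stationary composition-only third-order model
#'
#' Builds a `"markov3"` whose every transition row equals a single base
#' composition `p` (i.e. an i.i.d. model expressed in third-order form).
#' The default composition (A = T = 0.31, C = G = 0.19) mimics AT-rich
#' intergenic DNA such as yeast promoters. Useful when no background corpus
#' is available.
#'
#' @param p Named base-frequency vector summing to 1.
#' @return Object of class `"markov3"`.
#' @export
iid_markov3 <- function(p = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)) {
  stopifnot(all(DNA_BASES %in% names(p)), abs(sum(p) - 1) < 1e-9)
  p <- p[DNA_BASES]
  trans <- matrix(rep(p, each = 64L), nrow = 64L,
                  dimnames = list(ALL_3MERS, DNA_BASES))
  b <- strsplit(ALL_3MERS, "")
  initial <- vapply(b, function(ch) prod(p[ch]), numeric(1))
  structure(list(transition = trans,
                 initial = setNames(initial / sum(initial), ALL_3MERS),
                 pseudocount = 0),
            class = "markov3")
}

#' @export
print.markov3 <- function(x, ...) {
  cat(sprintf("third-order Markov model (64 contexts, pseudocount %g)\n",
              x$pseudocount))
  invisible(x)
}

#' Sample a background sequence from a third-order Markov model
#'
#' The first three bases are drawn from the initial 3-mer distribution, the
#' remainder one base at a time from the transition rows.
#'
#' @param model A `"markov3"` from [fit_markov3()] or [iid_markov3()].
#' @param length Output length in bases (>= 4).
#' @param seed Optional integer seed.
#' @return A DNA string of exactly `length` bases.
#' @export
sample_background <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "markov3"), length >= 4L)
  with_seed(seed, {
    cum <- t(apply(model$transition, 1L, cumsum))
    ctx3 <- sample.int(64L, 1L, prob = model$initial)
    # decode lexicographic 3-mer index into base indices 1..4
    z <- ctx3 - 1L
    out <- integer(length)
    out[1L] <- z %/% 16L + 1L
    out[2L] <- (z %/% 4L) %% 4L + 1L
    out[3L] <- z %% 4L + 1L
    ctx <- z
    r <- runif(length)
    for (t in 4:length) {
      row <- cum[ctx + 1L, ]
      b <- findInterval(r[t], row, left.open = TRUE) + 1L
      out[t] <- b
      ctx <- (ctx %% 16L) * 4L + (b - 1L)
    }
    paste(DNA_BASES[out], collapse = "")
  })
}

#' Generate binding-site instances from a consensus
#'
#' Produces `n_sites` copies of `consensus`, each independently carrying a
#' number of point mutations drawn uniformly from 0..`max_mutations`
#' (mutated positions uniform without replacement, substituted base uniform
#' over the other three).
#'
#' @param consensus DNA string over \{A,C,G,T\}.
#' @param n_sites Number of instances (default 20, a typical curated motif
#'   size).
#' @param max_mutations Maximum point mutations per instance.
#' @param seed Optional integer seed.
#' @return Character vector of site strings.
#' @export
sample_site_strings <- function(consensus, n_sites = 20L, max_mutations = 1L,
                                seed = NULL) {
  k <- nchar(consensus)
  chars <- strsplit(consensus, "")[[1]]
  stopifnot(all(chars %in% DNA_BASES), n_sites >= 1L, max_mutations >= 0L,
            max_mutations <= k)
  with_seed(seed, {
    vapply(seq_len(n_sites), function(i) {
      s <- chars
      m <- sample.int(max_mutations + 1L, 1L) - 1L
      if (m > 0L) {
        pos <- sample.int(k, m)
        for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
  })
}

#' Implant binding sites into background sequences
#'
#' Each site string is independently assigned a uniformly random sequence
#' and a uniformly random offset, and replaces the background segment of
#' the same length in place ("any number of repetitions" mode: a sequence
#' may receive several sites or none). Offsets colliding with an already
#' implanted site in the same sequence are redrawn up to `max_tries` times.
#'
#' @param backgrounds Named character vector of background sequences.
#' @param sites Character vector of site strings, each shorter than every
#'   background.
#' @param seed Optional integer seed.
#' @param max_tries Offset redraws allowed per site before failing.
#' @param motif_id Label recorded on the dataset.
#' @return List of class `"benchmark_dataset"` with the implanted
#'   `sequences`, a `truth` site table (`seq_index`, `seq_id`, `start`
#'   0-based, `length`, `strand`, `text`), `motif_id` and the `seed`.
#' @export
implant_sites <- function(backgrounds, sites, seed = NULL, max_tries = 1000L,
                          motif_id = "motif") {
  stopifnot(length(backgrounds) >= 1L, length(sites) >= 1L)
  if (any(nchar(sites) >= min(nchar(backgrounds))))
    stop("every site must be shorter than every background sequence")
  ids <- names(backgrounds)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(backgrounds))
  with_seed(seed, {
    seqs <- unname(backgrounds)
    occupied <- vector("list", length(seqs))
    truth <- vector("list", length(sites))
    for (i in seq_along(sites)) {
      len <- nchar(sites[i])
      si <- sample.int(length(seqs), 1L)
      L <- nchar(seqs[si])
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        off <- sample.int(L - len + 1L, 1L) - 1L   # 0-based
        clash <- any(vapply(occupied[[si]], function(iv)
          off < iv[2L] && iv[1L] < off + len, logical(1)))
        if (!clash) {
          substr(seqs[si], off + 1L, off + len) <- sites[i]
          occupied[[si]] <- c(occupied[[si]], list(c(off, off + len)))
          truth[[i]] <- data.frame(seq_index = si - 1L, seq_id = ids[si],
                                   start = off, length = len, strand = "+",
                                   text = sites[i], stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place site ", i, " without overlap after ",
             max_tries, " tries; use longer background sequences")
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$seq_index, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(sequences = setNames(seqs, ids), truth = truth,
                   motif_id = motif_id, seed = seed),
              class = "benchmark_dataset")
  })
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("benchmark dataset '%s': %d sequences, %d implanted sites\n",
              x$motif_id, length(x$sequences), nrow(x$truth)))
  invisible(x)
}

#' Generate replicated planted-motif benchmark datasets
#'
#' For each replicate, samples `n_seqs` background sequences of `length`
#' bases from `model` (plus `extra_noise_seqs` site-free sequences, for
#' noise-tolerance experiments) and implants each of the `site_strings`
#' into a uniformly random core sequence at a uniformly random
#' non-overlapping offset. Replicate seeds are derived from the master
#' `seed`, so the whole collection is reproducible.
#'
#' @param site_strings Character vector of binding-site strings (typically
#'   20, e.g. from [sample_site_strings()] or a curated motif FASTA).
#' @param n_seqs Background sequences receiving sites per replicate.
#' @param length Background sequence length in bases.
#' @param model A `"markov3"` background model.
#' @param n_replicates Number of independent datasets.
#' @param seed Master integer seed.
#' @param extra_noise_seqs Additional background-only sequences appended to
#'   each replicate (e.g. 5 for 25\% noise on a 20-sequence design).
#' @param motif_id Label recorded on each dataset.
#' @return List of `"benchmark_dataset"` objects.
#' @export
generate_benchmark <- function(site_strings, n_seqs = 20L, length = 400L,
                               model = iid_markov3(), n_replicates = 100L,
                               seed = 1L, extra_noise_seqs = 0L,
                               motif_id = "motif") {
  stopifnot(n_seqs >= 1L, length >= 4L, n_replicates >= 1L,
            extra_noise_seqs >= 0L)
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_replicates))
  lapply(seq_len(n_replicates), function(r) {
    with_seed(rep_seeds[r], {
      total <- n_seqs + extra_noise_seqs
      bg <- setNames(vapply(seq_len(total), function(i)
        sample_background(model, length), character(1)),
        sprintf("%s_rep%d_seq%d", motif_id, r, seq_len(total)))
      core <- bg[seq_len(n_seqs)]
      ds <- implant_sites(core, site_strings, motif_id = motif_id)
      if (extra_noise_seqs > 0L)
        ds$sequences <- c(ds$sequences, bg[(n_seqs + 1L):total])
      ds$seed <- rep_seeds[r]
      ds
    })
  })
}
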