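#' Run motif discovery on a FASTA file
#'
#' Thin orchestration around [read_fasta()], [find_motifs()] and
#' [write_motif_report()]. Progress (estimated mu-bar, final alpha, graph
#' size) is logged via `message()` so it lands on stderr.
#'
#' @param input Path to the input FASTA file.
#' @param output Path for the tab-separated motif report.
#' @param k Motif length.
#' @param top_n Number of motifs to report.
#' @param ssd_cutoff,stringency,max_density,seed,revcomp Passed to
#'   [find_motifs()].
#' @param background Optional path to a background FASTA whose composition
#'   drives the SSD filter.
#' @return Invisibly, the list of motifs.
#' @export
run_find <- function(input, output, k, top_n = 5L, ssd_cutoff = 0.3,
                     stringency = "default", max_density = 20,
                     seed = NULL, revcomp = FALSE, background = NULL) {
  seqs <- read_fasta(input)
  bg <- if (!is.null(background)) read_fasta(background) else NULL
  motifs <- find_motifs(seqs, k = k, top_n = top_n, ssd_cutoff = ssd_cutoff,
                        stringency = stringency, max_density = max_density,
                        seed = seed, revcomp = revcomp, background = bg)
  message(sprintf(
    "graph: %d vertices, %d edges; mu_bar = %.3f, alpha = %d; %d motif(s)",
    attr(motifs, "n_vertices"), attr(motifs, "n_edges"),
    attr(motifs, "mu_bar"), attr(motifs, "alpha"), length(motifs)))
  write_motif_report(motifs, output)
  invisible(motifs)
}

#' Run a replicated planted-motif benchmark
#'
#' Generates `n_replicates` synthetic datasets (sites implanted into
#' third-order Markov backgrounds in any-number-of-repetitions mode), runs
#' the motif finder on each, and scores the pooled sites of the top
#' `top_n` motifs against the implantation truth at the 50\%-overlap rule.
#'
#' @param site_strings Binding-site strings to implant (e.g. from
#'   [sample_site_strings()]).
#' @param k Motif length used for discovery.
#' @param n_seqs,length,model,extra_noise_seqs,n_replicates,seed Passed to
#'   [generate_benchmark()].
#' @param top_n Number of motifs whose sites enter the evaluation.
#' @param ssd_cutoff,stringency,max_density Passed to [find_motifs()].
#' @param output Optional path; when given, the per-replicate metrics table
#'   (plus a `mean` row) is written as TSV.
#' @return List with `replicates` (per-replicate data frame of tp/fp/fn and
#'   Sn/Sp/PC/F) and `mean` (one-row data frame of column means over
#'   replicates).
#' @export
run_benchmark <- function(site_strings, k, n_seqs = 20L, length = 400L,
                          model = iid_markov3(), n_replicates = 10L,
                          seed = 1L, extra_noise_seqs = 0L, top_n = 1L,
                          ssd_cutoff = 0.3, stringency = "default",
                          max_density = 20, output = NULL) {
  stopifnot(n_replicates >= 1L)
  datasets <- generate_benchmark(site_strings, n_seqs = n_seqs,
                                 length = length, model = model,
                                 n_replicates = n_replicates, seed = seed,
                                 extra_noise_seqs = extra_noise_seqs)
  rows <- lapply(seq_along(datasets), function(r) {
    ds <- datasets[[r]]
    motifs <- suppressMessages(find_motifs(
      ds$sequences, k = k, top_n = top_n, ssd_cutoff = ssd_cutoff,
      stringency = stringency, max_density = max_density,
      seed = ds$seed))
    preds <- motif_sites(motifs)
    cc <- confusion_counts(ds$truth, preds)
    cbind(data.frame(replicate = r, tp = cc$tp, fp = cc$fp, fn = cc$fn),
          accuracy_metrics(cc))
  })
  reps <- do.call(rbind, rows)
  mn <- as.data.frame(as.list(colMeans(reps[, -1L, drop = FALSE])))
  if (!is.null(output)) {
    tab <- rbind(cbind(replicate = as.character(reps$replicate),
                       reps[, -1L, drop = FALSE]),
                 cbind(replicate = "mean", mn))
    write.table(tab, output, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(replicates = reps, mean = mn)
}
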