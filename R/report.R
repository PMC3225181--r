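#' Construct a motif object
#'
#' A motif is a set of similar length-k sites together with its per-column
#' base count matrix and majority consensus. Site coordinates are 0-based
#' half-open internally; the report writer prints 1-based inclusive
#' coordinates.
#'
#' @param sites Data frame with columns `seq_index` (0-based sequence index,
#'   may be `NA` for motifs read back from a report), `seq_id`, `start`
#'   (0-based), `strand` ("+" or "-") and `text` (the k-mer).
#' @param k Motif length; every site text must have `k` characters.
#' @param rank 1-based output rank (NA until assigned).
#' @return An object of class `"motif"`.
#' @export
new_motif <- function(sites, k, rank = NA_integer_) {
  stopifnot(is.data.frame(sites),
            all(c("seq_index", "seq_id", "start", "strand", "text")
                %in% names(sites)))
  if (nrow(sites) == 0L) stop("a motif needs at least one site")
  if (any(nchar(sites$text) != k))
    stop("all site texts must have length k = ", k)
  sites <- sites[order(sites$seq_index, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  counts <- site_count_matrix(sites$text, k)
  structure(list(sites = sites, k = k,
                 consensus = consensus_from_counts(counts),
                 counts = counts, rank = rank),
            class = "motif")
}

# 4 x k base count matrix (rows A,C,G,T) of a set of k-mers.
site_count_matrix <- function(texts, k) {
  mat <- matrix(0L, nrow = 4L, ncol = k, dimnames = list(DNA_BASES, NULL))
  for (txt in texts) {
    idx <- match(strsplit(txt, "")[[1]], DNA_BASES)
    for (j in seq_len(k)) {
      if (!is.na(idx[j])) mat[idx[j], j] <- mat[idx[j], j] + 1L
    }
  }
  mat
}

# Majority consensus; ties resolved in A < C < G < T order (which.max).
consensus_from_counts <- function(counts) {
  paste(DNA_BASES[apply(counts, 2L, which.max)], collapse = "")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif (k = %d, rank = %s): %s with %d sites\n",
              x$k, ifelse(is.na(x$rank), "?", x$rank),
              x$consensus, nrow(x$sites)))
  invisible(x)
}

#' Flatten a list of motifs into one site table
#'
#' @param motifs List of `motif` objects.
#' @return Data frame with columns `motif_rank`, `seq_index`, `seq_id`,
#'   `start` (0-based), `length`, `strand`, `text`, ordered by rank then
#'   coordinate.
#' @export
motif_sites <- function(motifs) {
  if (length(motifs) == 0L)
    return(data.frame(motif_rank = integer(), seq_index = integer(),
                      seq_id = character(), start = integer(),
                      length = integer(), strand = character(),
                      text = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(motifs, function(m) {
    data.frame(motif_rank = m$rank, seq_index = m$sites$seq_index,
               seq_id = m$sites$seq_id, start = m$sites$start,
               length = m$k, strand = m$sites$strand, text = m$sites$text,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$motif_rank, out$seq_index, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

REPORT_COLUMNS <- c("motif_rank", "seq_id", "start", "end", "strand", "site")

#' Write a motif site report
#'
#' Writes a tab-separated site table (one row per site, 1-based inclusive
#' coordinates) followed by one comment block per motif carrying the
#' consensus and the 4 x k position count matrix. The paired reader
#' [read_motif_report()] recovers the identical site list.
#'
#' @param motifs List of `motif` objects (may be empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_motif_report <- function(motifs, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write report: ", path))
  on.exit(close(con))
  writeLines(c("# motif site report",
               "# coordinates are 1-based inclusive"), con)
  writeLines(paste(REPORT_COLUMNS, collapse = "\t"), con)
  for (m in motifs) {
    s <- m$sites
    writeLines(sprintf("%d\t%s\t%d\t%d\t%s\t%s",
                       m$rank, s$seq_id, s$start + 1L, s$start + m$k,
                       s$strand, s$text), con)
  }
  for (m in motifs) {
    writeLines(sprintf("## motif %d consensus=%s sites=%d k=%d",
                       m$rank, m$consensus, nrow(m$sites), m$k), con)
    for (b in DNA_BASES)
      writeLines(paste(c(paste0("## ", b), m$counts[b, ]), collapse = "\t"),
                 con)
  }
  invisible(path)
}

#' Read a motif site report
#'
#' Inverse of [write_motif_report()]. The `seq_index` of the recovered sites
#' is `NA` because the report stores sequence ids, not positions in the
#' original input set.
#'
#' @param path Report file path.
#' @return List of `motif` objects ordered by rank.
#' @export
read_motif_report <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) stop("malformed report (no site table): ", path)
  header <- strsplit(body[1L], "\t")[[1]]
  if (!identical(header, REPORT_COLUMNS))
    stop("malformed report header in ", path)
  if (length(body) == 1L) return(list())
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
  tab$seq_id <- as.character(tab$seq_id)
  motifs <- lapply(sort(unique(tab$motif_rank)), function(r) {
    s <- tab[tab$motif_rank == r, , drop = FALSE]
    k <- unique(s$end - s$start + 1L)
    stopifnot(length(k) == 1L)
    new_motif(data.frame(seq_index = NA_integer_, seq_id = s$seq_id,
                         start = s$start - 1L, strand = s$strand,
                         text = s$site, stringsAsFactors = FALSE),
              k = k, rank = r)
  })
  motifs
}
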