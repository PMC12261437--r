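# Synthetic long-read alignment generator: toy transcript catalogs, reads
# sampled proportionally to copy number (no length weighting), 3'-anchored
# truncation, and controlled prefix ambiguity, emitted as name-collated SAM.

#' Simulate truncated long-read transcriptome alignments
#'
#' Generates a toy transcript catalog and a set of long reads drawn i.i.d.
#' with `Pr(transcript = j) = theta_j` — deliberately with no length
#' weighting, reflecting protocols without a fragmentation step. Each read is
#' full-length with probability `p_full`, otherwise 3'-anchored truncated (the
#' end stays at the transcript 3' end; the aligned length is drawn from a
#' truncated lognormal), mimicking degradation and pore-exit artifacts. When
#' transcripts are configured as exact prefixes of others, reads whose span
#' falls inside the shared prefix are emitted as alignments to both partners
#' with (up to integer score noise) matching alignment scores. Output is a
#' valid name-collated SAM file plus a transcript FASTA and a ground-truth
#' TSV.
#'
#' @param out_dir Directory for output files (created if needed).
#' @param n_transcripts Number of transcripts.
#' @param length_range Transcript length range in nucleotides
#'   (default 500-3000).
#' @param theta True abundance: either a simplex vector of length
#'   `n_transcripts`, or a single Dirichlet concentration parameter from which
#'   one abundance vector is drawn (default 0.5).
#' @param n_reads Number of reads.
#' @param p_full Probability a read is full length (default 0.25).
#' @param trunc_meanlog,trunc_sdlog Lognormal parameters of the truncated read
#'   length, clamped to `[min_read_len, transcript length]`
#'   (defaults `log(1000)`, 0.6).
#' @param min_read_len Minimum aligned read length (default 50).
#' @param prefix_pairs Prefix ambiguity: either `NULL` (none), an integer
#'   number of pairs to auto-configure (transcript 2k is replaced by an exact
#'   prefix of transcript 2k-1), or a tibble with columns `long`, `short`
#'   (transcript indices) and `frac` (prefix length fraction).
#' @param score_per_base Alignment score per aligned base (default 2).
#' @param score_noise Uniform integer score jitter half-width per alignment
#'   (default 2), so exact score ties and near-ties both occur.
#' @param shared_noise Use one jitter per read (all its alignments tie
#'   exactly) instead of independent per-alignment jitter. Default FALSE.
#' @param seed Integer seed; the same seed reproduces identical output bytes.
#' @return A list: `sam`, `fasta`, `truth_tsv` (paths); `catalog`, `truth`,
#'   `alignments` (tibbles; `alignments` holds the emitted records in file
#'   order); `theta` (the true abundance vector).
#' @export
simulate_reads <- function(out_dir = tempfile("lrquant_sim"),
                           n_transcripts = 50,
                           length_range = c(500, 3000),
                           theta = 0.5,
                           n_reads = 50000,
                           p_full = 0.25,
                           trunc_meanlog = log(1000),
                           trunc_sdlog = 0.6,
                           min_read_len = 50,
                           prefix_pairs = NULL,
                           score_per_base = 2,
                           score_noise = 2,
                           shared_noise = FALSE,
                           seed = 1) {
  stopifnot(n_transcripts >= 1, n_reads >= 1, p_full >= 0, p_full <= 1)
  withr::with_seed(seed, {
    lengths <- as.integer(round(stats::runif(n_transcripts,
                                             length_range[1],
                                             length_range[2])))
    catalog <- tibble::tibble(
      tname = sprintf("T%d", seq_len(n_transcripts)),
      length = lengths
    )

    # prefix configuration: short is an exact prefix of long
    pairs <- .resolve_prefix_pairs(prefix_pairs, n_transcripts)
    if (nrow(pairs) > 0) {
      catalog$length[pairs$short] <- as.integer(
        pmax(min_read_len,
             round(pairs$frac * catalog$length[pairs$long]))
      )
    }

    if (length(theta) == 1L) {
      g <- stats::rgamma(n_transcripts, shape = theta)
      theta <- g / sum(g)
    }
    if (length(theta) != n_transcripts || any(theta < 0) ||
        abs(sum(theta) - 1) > 1e-8) {
      rlang::abort("theta must be a simplex vector over the transcripts")
    }

    sim <- .sample_reads(catalog, theta, n_reads, p_full, trunc_meanlog,
                         trunc_sdlog, min_read_len, pairs, score_per_base,
                         score_noise, shared_noise)

    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seqs <- .prefix_consistent_sequences(catalog, pairs)
    fasta <- file.path(out_dir, "transcripts.fasta")
    Biostrings::writeXStringSet(seqs, fasta)
    sam <- file.path(out_dir, "reads.sam")
    .write_sam(sim$alignments, catalog, sam)
    truth <- tibble::tibble(
      tname = catalog$tname,
      true_count = tabulate(sim$origin, nbins = n_transcripts),
      true_frac = theta
    )
    truth_tsv <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, truth_tsv)

    list(sam = sam, fasta = fasta, truth_tsv = truth_tsv,
         catalog = catalog, truth = truth, alignments = sim$alignments,
         theta = theta)
  })
}

# Normalise the prefix_pairs argument to a tibble(long, short, frac).
.resolve_prefix_pairs <- function(prefix_pairs, n_transcripts) {
  if (is.null(prefix_pairs)) {
    return(tibble::tibble(long = integer(), short = integer(),
                          frac = numeric()))
  }
  if (is.numeric(prefix_pairs) && length(prefix_pairs) == 1L) {
    n_pairs <- as.integer(prefix_pairs)
    if (2L * n_pairs > n_transcripts) {
      rlang::abort("too many prefix pairs for the catalog size")
    }
    return(tibble::tibble(
      long = 2L * seq_len(n_pairs) - 1L,
      short = 2L * seq_len(n_pairs),
      frac = stats::runif(n_pairs, 0.4, 0.7)
    ))
  }
  pairs <- tibble::as_tibble(prefix_pairs)
  stopifnot(all(c("long", "short", "frac") %in% names(pairs)))
  if (anyDuplicated(c(pairs$long, pairs$short))) {
    rlang::abort("a transcript may appear in at most one prefix pair")
  }
  pairs
}

# Draw reads and their (possibly multimapped) alignment records.
.sample_reads <- function(catalog, theta, n_reads, p_full, trunc_meanlog,
                          trunc_sdlog, min_read_len, pairs, score_per_base,
                          score_noise, shared_noise) {
  m <- nrow(catalog)
  origin <- sample.int(m, n_reads, replace = TRUE, prob = theta)
  len <- catalog$length[origin]
  full <- stats::runif(n_reads) < p_full
  rl <- round(stats::rlnorm(n_reads, trunc_meanlog, trunc_sdlog))
  rl <- pmin(pmax(rl, min_read_len), len)
  rl[full] <- len[full]
  start <- len - rl   # 3'-anchored: end fixed at the transcript end
  end <- len

  # secondary targets: the prefix partner whose sequence contains the span.
  # A read from the short member always lies inside the shared prefix (its
  # 3' end is the prefix end); a read from the long member multimaps only if
  # its whole span falls inside the prefix.
  partner <- integer(n_reads)  # 0 = none
  if (nrow(pairs) > 0) {
    short_of <- integer(m); short_of[pairs$long] <- pairs$short
    long_of <- integer(m); long_of[pairs$short] <- pairs$long
    from_short <- long_of[origin] > 0L
    partner[from_short] <- long_of[origin[from_short]]
    prefix_len <- ifelse(short_of[origin] > 0L,
                         catalog$length[pmax(short_of[origin], 1L)], -1L)
    from_long_inside <- short_of[origin] > 0L & end <= prefix_len
    partner[from_long_inside] <- short_of[origin[from_long_inside]]
  }

  read_id <- sprintf("read%06d", seq_len(n_reads))
  has2 <- partner > 0L
  ridx <- c(seq_len(n_reads), which(has2))
  aln <- tibble::tibble(
    ridx = ridx,
    tx = c(origin, partner[has2]),
    primary = rep(c(TRUE, FALSE), c(n_reads, sum(has2)))
  )
  aln <- dplyr::arrange(aln, .data$ridx, dplyr::desc(.data$primary))
  aln$read_id <- read_id[aln$ridx]
  aln$start <- start[aln$ridx]
  aln$end <- end[aln$ridx]
  base_score <- score_per_base * (aln$end - aln$start)
  if (score_noise > 0) {
    if (shared_noise) {
      per_read <- sample.int(2L * score_noise + 1L, n_reads,
                             replace = TRUE) - score_noise - 1L
      noise <- per_read[aln$ridx]
    } else {
      noise <- sample.int(2L * score_noise + 1L, nrow(aln),
                          replace = TRUE) - score_noise - 1L
    }
  } else {
    noise <- 0L
  }
  aln$score <- as.integer(base_score + noise)
  aln$tname <- catalog$tname[aln$tx]
  aln$is_reverse <- FALSE
  aln <- aln[, c("read_id", "tname", "tx", "score", "start", "end",
                 "is_reverse", "primary")]
  attr(aln, "catalog") <- catalog
  list(alignments = aln, origin = origin)
}

# Random transcript sequences; prefix partners share their prefix bases.
.prefix_consistent_sequences <- function(catalog, pairs) {
  seqs <- vapply(catalog$length, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  if (nrow(pairs) > 0) {
    seqs[pairs$short] <- substr(seqs[pairs$long], 1L,
                                catalog$length[pairs$short])
  }
  Biostrings::DNAStringSet(stats::setNames(seqs, catalog$tname))
}

# Emit records as name-collated SAM (primary first within each read).
.write_sam <- function(alignments, catalog, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown\tGO:query",
    sprintf("@SQ\tSN:%s\tLN:%d", catalog$tname, catalog$length),
    "@PG\tID:lrquant-sim\tPN:lrquant-sim"
  )
  flag <- ifelse(alignments$primary, 0L, 256L) +
    ifelse(alignments$is_reverse, 16L, 0L)
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tAS:i:%d",
    alignments$read_id, flag, alignments$tname, alignments$start + 1L,
    ifelse(alignments$primary, 60L, 0L), alignments$end - alignments$start,
    alignments$score
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Prefix-transcript disambiguation fixture
#'
#' Builds the canonical two-transcript ambiguity scenario: `T2` is an exact
#' prefix of `T1` (60% of its length), every read originates from `T2`, and
#' each read aligns to both transcripts with identical coordinates and equal
#' alignment scores. Without coverage information the two explanations are
#' indistinguishable read-by-read; the totality of coverage (nothing beyond
#' the prefix on `T1`) favours `T2`.
#'
#' @param n_reads Number of reads (>= 1).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return As [simulate_reads()].
#' @export
make_prefix_fixture <- function(n_reads = 1000, seed = 1,
                              out_dir = tempfile("lrquant_prefix")) {
  stopifnot(n_reads >= 1)
  simulate_reads(
    out_dir = out_dir,
    n_transcripts = 2,
    length_range = c(1000, 1000),
    theta = c(0, 1),
    n_reads = n_reads,
    p_full = 0.25,
    trunc_meanlog = log(350),
    trunc_sdlog = 0.5,
    min_read_len = 50,
    prefix_pairs = tibble::tibble(long = 1L, short = 2L, frac = 0.6),
    score_per_base = 2,
    score_noise = 0,
    seed = seed
  )
}
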