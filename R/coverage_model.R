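# Binned transcript coverage profiles and the logistic segment-probability
# model that converts coverage non-uniformity into assignment probabilities.

#' Tile a transcript into fixed-width segments
#'
#' @param length Transcript length in nucleotides (>= 1).
#' @param bin_width Segment width in nucleotides (>= 1, default 100). The last
#'   segment is truncated at the transcript end, so `K = ceiling(length /
#'   bin_width)`.
#' @return A tibble with columns `segment` (1-based index), `start`, `end`
#'   (0-based half-open coordinates).
#' @examples
#' segment_transcript(250, 100)
#' @export
segment_transcript <- function(length, bin_width = 100) {
  stopifnot(is.numeric(length), is.numeric(bin_width))
  if (length < 1 || bin_width < 1) {
    rlang::abort("length and bin_width must be positive")
  }
  k <- ceiling(length / bin_width)
  start <- (seq_len(k) - 1) * bin_width
  tibble::tibble(
    segment = seq_len(k),
    start = as.integer(start),
    end = as.integer(pmin(start + bin_width, length))
  )
}

#' Add the stabilising pseudocount to segment counts
#'
#' Each segment count is incremented by 1% of the number of reads aligned to
#' the transcript, preventing numerically unstable probabilities for sparsely
#' covered segments.
#'
#' @param counts Numeric vector of fractional segment counts.
#' @param n_aligned Number of alignments accumulated on the transcript.
#' @return The adjusted counts.
#' @export
apply_pseudocount <- function(counts, n_aligned) {
  stopifnot(n_aligned >= 0)
  counts + 0.01 * n_aligned
}

#' Logistic segment assignment probabilities
#'
#' Converts segment coverage counts into probabilities that penalise
#' above-average coverage: with mean segment count `E(c)` and relative
#' deviation `delta_i = (E(c) - c_i) / E(c)`, the probability of segment `i`
#' is `1 / (1 + exp(-a * delta_i))`. Segments covered above the mean receive
#' probability below 0.5 and sparsely covered segments above 0.5. A transcript
#' with no coverage (`E(c) = 0`) gets a flat 0.5 everywhere.
#'
#' @param counts Numeric vector of (pseudocount-adjusted) segment counts.
#' @param growth_rate Logistic growth rate `a >= 0` (default 2); `a = 0` makes
#'   the model uninformative (all probabilities 0.5).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
segment_probabilities <- function(counts, growth_rate = 2) {
  stopifnot(length(counts) >= 1, growth_rate >= 0, is.finite(growth_rate))
  ec <- mean(counts)
  if (ec == 0) {
    return(rep(0.5, length(counts)))
  }
  delta <- (ec - counts) / ec
  stats::plogis(growth_rate * delta)
}

#' Build per-transcript coverage profiles
#'
#' Accumulates fractional segment counts from all retained alignments (the
#' contribution of an alignment to a segment is the covered fraction of the
#' segment), applies the 1% pseudocount, and converts counts to logistic
#' segment probabilities. Profiles are computed once from the input alignments
#' and held fixed during inference.
#'
#' @param alignments Alignment tibble from [read_alignments()] (or the
#'   simulator's in-memory records).
#' @param catalog Transcript catalog; defaults to the one attached to
#'   `alignments`.
#' @param bin_width Segment width in nucleotides (default 100).
#' @param growth_rate Logistic growth rate (default 2).
#' @return A `coverage_profiles` tibble with one row per (transcript, segment):
#'   columns `tname`, `tx`, `segment`, `start`, `end`, `count_raw`
#'   (before pseudocount), `count`, `prob`. Attributes carry the catalog,
#'   `bin_width`, `growth_rate`, and the per-transcript alignment counts
#'   `n_aligned`.
#' @export
coverage_profiles <- function(alignments, catalog = attr(alignments, "catalog"),
                              bin_width = 100, growth_rate = 2) {
  if (is.null(catalog)) {
    rlang::abort("a transcript catalog is required")
  }
  stopifnot(bin_width >= 1)
  m <- nrow(catalog)
  len <- catalog$length
  k <- ceiling(len / bin_width)
  offset <- c(0L, cumsum(k))  # flat index: offset[tx] + segment

  tx_of_seg <- rep.int(seq_len(m), k)
  seg_idx <- sequence(k)
  seg_start <- (seg_idx - 1) * bin_width
  seg_end <- pmin(seg_idx * bin_width, len[tx_of_seg])

  counts_raw <- numeric(sum(k))
  if (nrow(alignments) > 0) {
    if (any(alignments$start < 0 | alignments$end > len[alignments$tx] |
            alignments$start >= alignments$end)) {
      rlang::abort("alignment span outside [0, transcript length)")
    }
    ov <- .segment_overlaps(alignments$tx, alignments$start, alignments$end,
                            bin_width, len)
    contrib <- ov$overlap / ov$seg_len
    flat <- offset[ov$tx] + ov$segment
    acc <- rowsum(contrib, flat)
    counts_raw[as.integer(rownames(acc))] <- acc[, 1]
  }

  n_aligned <- tabulate(alignments$tx, nbins = m)
  counts <- counts_raw + 0.01 * n_aligned[tx_of_seg]
  probs <- unlist(lapply(seq_len(m), function(j) {
    segment_probabilities(counts[(offset[j] + 1):offset[j + 1]], growth_rate)
  }), use.names = FALSE)

  prof <- tibble::tibble(
    tname = catalog$tname[tx_of_seg],
    tx = tx_of_seg,
    segment = seg_idx,
    start = as.integer(seg_start),
    end = as.integer(seg_end),
    count_raw = counts_raw,
    count = counts,
    prob = probs
  )
  class(prof) <- c("coverage_profiles", class(prof))
  attr(prof, "catalog") <- catalog
  attr(prof, "bin_width") <- bin_width
  attr(prof, "growth_rate") <- growth_rate
  attr(prof, "n_aligned") <- n_aligned
  attr(prof, "offset") <- offset
  prof
}

# Expand alignments to (alignment, segment) overlap rows. Returns the
# alignment index, transcript, 1-based segment index, overlap width and true
# segment length for every overlapped segment.
.segment_overlaps <- function(tx, start, end, bin_width, len) {
  i0 <- start %/% bin_width          # 0-based first segment
  i1 <- (end - 1) %/% bin_width      # 0-based last segment
  nseg <- i1 - i0 + 1
  aln <- rep.int(seq_along(tx), nseg)
  seg <- sequence(nseg, from = i0 + 1)   # 1-based segment index
  seg_start <- (seg - 1) * bin_width
  seg_len_full <- pmin(seg * bin_width, len[tx[aln]]) - seg_start
  overlap <- pmin(end[aln], seg_start + seg_len_full) -
    pmax(start[aln], seg_start)
  list(aln = aln, tx = tx[aln], segment = seg, overlap = overlap,
       seg_len = seg_len_full)
}

# Vectorised start-end probability on internal (tx, start, end) triples.
.se_prob <- function(profiles, tx, start, end) {
  bin_width <- attr(profiles, "bin_width")
  offset <- attr(profiles, "offset")
  len <- attr(profiles, "catalog")$length
  probs <- profiles$prob
  ov <- .segment_overlaps(tx, start, end, bin_width, len)
  w <- ov$overlap / ov$seg_len
  wp <- w * probs[offset[ov$tx] + ov$segment]
  num <- rowsum(wp, ov$aln, reorder = FALSE)[, 1]
  den <- rowsum(w, ov$aln, reorder = FALSE)[, 1]
  unname(num / den)
}

#' Start-end probability of an alignment span under a coverage profile
#'
#' The probability of observing an alignment spanning `[start, end)` on a
#' transcript is the weighted mean of its segment probabilities, each segment
#' weighted by the fraction of the segment the span covers (weights normalised
#' to sum to one, so the result is a convex combination in (0, 1)).
#'
#' @param profiles A `coverage_profiles` object.
#' @param tname Transcript name(s).
#' @param start,end 0-based half-open span coordinates (vectorised).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
start_end_probability <- function(profiles, tname, start, end) {
  stopifnot(inherits(profiles, "coverage_profiles"))
  catalog <- attr(profiles, "catalog")
  tx <- match(tname, catalog$tname)
  if (anyNA(tx)) {
    rlang::abort("unknown transcript name")
  }
  n <- max(length(tx), length(start), length(end))
  tx <- rep_len(tx, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(start >= end) || any(start < 0) || any(end > catalog$length[tx])) {
    rlang::abort("span must satisfy 0 <= start < end <= transcript length")
  }
  .se_prob(profiles, tx, start, end)
}

#' Plot coverage profiles
#'
#' Segment counts (bars) and logistic segment probabilities (line) along each
#' transcript, one facet per transcript.
#'
#' @param object A `coverage_profiles` object.
#' @param tnames Optional subset of transcript names to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_profiles
#' @export
autoplot.coverage_profiles <- function(object, tnames = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(tnames)) {
    df <- dplyr::filter(df, .data$tname %in% tnames)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count),
                      width = attr(object, "bin_width") * 0.9,
                      fill = "grey70") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$prob * max(df$count), colour = "probability")
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tname), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(probability = "firebrick"),
                                 name = NULL) +
    ggplot2::labs(x = "transcript position (nt)",
                  y = "segment count (prob rescaled)") +
    ggplot2::theme_minimal()
}
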