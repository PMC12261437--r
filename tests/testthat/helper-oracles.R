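# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Per-base depth oracle for fractional segment counts: sum the per-position
# depth inside each segment and divide by the true segment length.
per_base_counts_oracle <- function(starts, ends, length, bin_width) {
  depth <- numeric(length)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):ends[i]   # 1-based positions covering [s, e)
    depth[idx] <- depth[idx] + 1
  }
  segs <- segment_transcript(length, bin_width)
  vapply(seq_len(nrow(segs)), function(k) {
    pos <- (segs$start[k] + 1):segs$end[k]
    sum(depth[pos]) / (segs$end[k] - segs$start[k])
  }, numeric(1))
}

# Exhaustive simplex grid search of the marginal log-likelihood
# sum_n log sum_j theta_j q_nj at a fixed grid resolution.
# `cond` is a tibble with read_id, tx, q; M the number of transcripts.
grid_loglik_oracle <- function(cond, m, resolution = 1e-3) {
  steps <- round(1 / resolution)
  if (m == 1) return(sum(log(cond$q)))
  if (m == 2) {
    a <- 0:steps
    grid <- cbind(a, steps - a) / steps
  } else if (m == 3) {
    a <- unlist(lapply(0:steps, function(i) rep(i, steps - i + 1)))
    b <- unlist(lapply(0:steps, function(i) 0:(steps - i)))
    grid <- cbind(a, b, steps - a - b) / steps
  } else {
    stop("oracle supports at most 3 transcripts")
  }
  # dense per-read conditional matrix (reads are few by construction)
  rid <- match(cond$read_id, unique(cond$read_id))
  n <- max(rid)
  qmat <- matrix(0, nrow = m, ncol = n)
  qmat[cbind(cond$tx, rid)] <- cond$q
  per_read <- grid %*% qmat           # G x N marginal likelihoods
  ll <- rowSums(log(per_read))
  max(ll[is.finite(ll)])
}

# Brute-force average precision: sweep every distinct score as a threshold
# (predict positive when score >= threshold), accumulating (R_k - R_{k-1}) P_k.
average_precision_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  n_pos <- sum(labels)
  for (t in thr) {
    pred <- scores >= t
    precision <- sum(pred & labels) / sum(pred)
    recall <- sum(pred & labels) / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Small random sparse conditional-probability instance: every read gets 1-3
# targets among m transcripts with conditionals in (0, 1].
random_conditionals <- function(n_reads, m, seed) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_reads), function(i) {
      k <- sample.int(min(3, m), 1)
      tibble::tibble(
        read_id = sprintf("r%03d", i),
        tx = sort(sample.int(m, k)),
        q = stats::runif(k, 0.05, 1)
      )
    })
    cond <- dplyr::bind_rows(rows)
    attr(cond, "catalog") <- tibble::tibble(
      tname = sprintf("T%d", seq_len(m)),
      length = rep(1000L, m)
    )
    attr(cond, "model") <- "nocov"
    cond
  })
}

# Hand-rolled alignment tibble on a given catalog (for coverage fixtures).
manual_alignments <- function(catalog, tx, start, end,
                              read_id = sprintf("r%03d", seq_along(tx)),
                              score = 100L) {
  aln <- tibble::tibble(
    read_id = read_id,
    tname = catalog$tname[tx],
    tx = as.integer(tx),
    score = as.integer(rep_len(score, length(tx))),
    start = as.integer(start),
    end = as.integer(end),
    is_reverse = FALSE
  )
  attr(aln, "catalog") <- catalog
  aln
}
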