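# EM maximisation of the fragment-level likelihood over transcript
# abundances theta.

#' E-step: posterior read-to-transcript responsibilities
#'
#' Given abundances `theta` and fixed conditionals `q`, the responsibility of
#' transcript `j` for read `n` is `theta_j * q_nj` normalised over the read's
#' alignment set. Reads whose denominator is zero (all their transcripts at
#' zero abundance) are assigned uniformly over their entries.
#'
#' @param conditionals Conditional probability tibble from
#'   [alignment_conditionals()].
#' @param theta Abundance vector over the catalog (non-negative, sums to 1).
#' @return The tibble with an added responsibility column `r`; each read's
#'   responsibilities sum to 1.
#' @export
e_step <- function(conditionals, theta) {
  rid <- match(conditionals$read_id, unique(conditionals$read_id))
  r <- .e_step_resp(theta, conditionals$q, rid, conditionals$tx)
  dplyr::mutate(conditionals, r = r)
}

# Core E-step on integer-coded vectors.
.e_step_resp <- function(theta, q, rid, tx) {
  num <- theta[tx] * q
  den <- rowsum(num, rid, reorder = FALSE)[, 1]
  r <- num / den[rid]
  if (any(den == 0)) {
    n_entries <- rowsum(rep(1, length(rid)), rid, reorder = FALSE)[, 1]
    zero <- den[rid] == 0
    r[zero] <- 1 / n_entries[rid][zero]
  }
  unname(r)
}

#' M-step: abundance update from responsibilities
#'
#' `theta_j` is the mean responsibility mass assigned to transcript `j`:
#' the summed responsibilities divided by the number of reads.
#'
#' @param responsibilities Tibble from [e_step()] (columns `read_id`, `tx`,
#'   `r`).
#' @param n_transcripts Number of transcripts `M` in the catalog.
#' @return Updated abundance vector of length `n_transcripts`.
#' @export
m_step <- function(responsibilities, n_transcripts) {
  n <- length(unique(responsibilities$read_id))
  counts <- .tx_counts(responsibilities$r, responsibilities$tx, n_transcripts)
  counts / n
}

# Sum responsibilities per transcript into a dense length-M vector.
.tx_counts <- function(r, tx, m) {
  counts <- numeric(m)
  acc <- rowsum(r, tx)
  counts[as.integer(rownames(acc))] <- acc[, 1]
  counts
}

#' Quantify transcript abundances by EM
#'
#' Iterates E and M steps from a uniform start until the expected read counts
#' stabilise (maximum absolute per-transcript change below `tol`) or
#' `max_iters` is reached. Inference is fully deterministic. The log-likelihood
#' `sum_n log sum_j theta_j q_nj` is recorded each iteration and is
#' non-decreasing.
#'
#' @param conditionals Conditional probability tibble from
#'   [alignment_conditionals()].
#' @param catalog Transcript catalog; defaults to the one attached to
#'   `conditionals`.
#' @param max_iters Maximum EM iterations (default 1000).
#' @param tol Convergence threshold on the maximum absolute change in expected
#'   counts, in reads (default 1e-3).
#' @return An `em_fit` object: list with `abundance` (tibble `tname`, `tx`,
#'   `num_reads`, `frac`), `theta`, `counts`, `n_assigned`, `n_iters`,
#'   `final_delta`, `loglik_trace`, `converged`, `model`.
#' @export
em_quantify <- function(conditionals, catalog = attr(conditionals, "catalog"),
                        max_iters = 1000, tol = 1e-3) {
  stopifnot(max_iters >= 1, tol > 0)
  if (is.null(catalog)) {
    rlang::abort("a transcript catalog is required")
  }
  if (nrow(conditionals) == 0L) {
    rlang::abort("no conditional probabilities: nothing to quantify")
  }
  m <- nrow(catalog)
  rid <- match(conditionals$read_id, unique(conditionals$read_id))
  tx <- conditionals$tx
  q <- conditionals$q
  n <- max(rid)

  theta <- rep(1 / m, m)
  counts_prev <- theta * n
  loglik <- numeric(0)
  delta <- Inf
  iters <- 0L
  for (it in seq_len(max_iters)) {
    iters <- it
    num <- theta[tx] * q
    den <- rowsum(num, rid, reorder = FALSE)[, 1]
    loglik <- c(loglik, sum(log(den[den > 0])))
    r <- num / den[rid]
    if (any(den == 0)) {
      n_entries <- rowsum(rep(1, length(rid)), rid, reorder = FALSE)[, 1]
      zero <- den[rid] == 0
      r[zero] <- 1 / n_entries[rid][zero]
    }
    counts <- .tx_counts(r, tx, m)
    theta <- counts / n
    delta <- max(abs(counts - counts_prev))
    counts_prev <- counts
    if (delta < tol) break
  }

  fit <- list(
    abundance = tibble::tibble(
      tname = catalog$tname,
      tx = seq_len(m),
      num_reads = counts_prev,
      frac = theta
    ),
    theta = theta,
    counts = counts_prev,
    n_assigned = n,
    n_iters = iters,
    final_delta = delta,
    loglik_trace = loglik,
    converged = delta < tol,
    model = attr(conditionals, "model") %||% NA_character_
  )
  class(fit) <- "em_fit"
  fit
}

#' @export
print.em_fit <- function(x, ...) {
  cat("EM transcript abundance fit (model: ", x$model, ")\n", sep = "")
  cat("  reads assigned: ", x$n_assigned, "; transcripts: ",
      length(x$theta), "\n", sep = "")
  cat("  iterations: ", x$n_iters,
      if (x$converged) " (converged)" else " (max iterations reached)",
      "; final count delta: ", format(x$final_delta, digits = 3), "\n",
      sep = "")
  cat("  log-likelihood: ", format(utils::tail(x$loglik_trace, 1),
                                   digits = 8), "\n", sep = "")
  print(x$abundance, ...)
  invisible(x)
}

#' Tidy an EM abundance fit
#'
#' @param x An `em_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per transcript: `tname`, `tx`, `num_reads`,
#'   `frac`.
#' @method tidy em_fit
#' @export
tidy.em_fit <- function(x, ...) {
  x$abundance
}

#' One-row summary of an EM abundance fit
#'
#' @param x An `em_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_assigned`, `n_transcripts`, `n_iters`,
#'   `final_delta`, `log_lik`, `converged`, `model`.
#' @method glance em_fit
#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(
    n_assigned = x$n_assigned,
    n_transcripts = length(x$theta),
    n_iters = x$n_iters,
    final_delta = x$final_delta,
    log_lik = utils::tail(x$loglik_trace, 1),
    converged = x$converged,
    model = x$model
  )
}

#' Plot the EM log-likelihood trace
#'
#' @param object An `em_fit` object.
#' @param ... Unused.
#' @return A ggplot object showing log-likelihood against iteration.
#' @method autoplot em_fit
#' @export
autoplot.em_fit <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$loglik_trace),
    loglik = object$loglik_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}
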