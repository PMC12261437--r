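# Conditional alignment probabilities: exponential alignment-score model,
# optionally combined with the coverage start-end model.

#' Exponential alignment-score probability
#'
#' The conditional probability of an alignment given its transcript decays
#' exponentially in the gap to the read's best alignment score:
#' `exp((score - max_score) / scale)`. The best-scoring alignment of a read
#' always receives probability exactly 1; highly suboptimal alignments are
#' effectively discarded by the falloff. The probability is invariant to
#' shifting all of a read's scores by a constant.
#'
#' @param score Integer alignment score(s) (AS tag; may be negative).
#' @param max_score The maximum alignment score over the read's retained
#'   alignments.
#' @param scale Positive decay scale in score units (default 10).
#' @return Probability vector in (0, 1].
#' @examples
#' alignment_score_prob(c(100, 90, 50), 100)
#' @export
alignment_score_prob <- function(score, max_score, scale = 10) {
  stopifnot(scale > 0)
  if (any(score > max_score)) {
    rlang::abort("score exceeds max_score")
  }
  exp((score - max_score) / scale)
}

#' Build per-read conditional assignment probabilities
#'
#' For each retained alignment of each read, computes the fixed conditional
#' probability used by the EM quantifier: the exponential alignment-score
#' probability, multiplied (for `model = "cov"`) by the coverage start-end
#' probability of the aligned span. Reads whose conditionals all underflow to
#' zero are dropped with a message.
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @param profiles Coverage profiles from [coverage_profiles()]; required for
#'   `model = "cov"`.
#' @param model `"cov"` (alignment score x coverage, the default) or `"nocov"`
#'   (alignment score only).
#' @param score_scale Decay scale of the score model (default 10).
#' @return A tibble with columns `read_id`, `tname`, `tx`, `q` (conditional
#'   probability in (0, 1]), rows grouped by read in input order. Attributes:
#'   `model`, `n_reads`, `catalog`.
#' @export
alignment_conditionals <- function(alignments, profiles = NULL,
                                   model = c("cov", "nocov"),
                                   score_scale = 10) {
  model <- rlang::arg_match(model)
  catalog <- attr(alignments, "catalog")
  if (nrow(alignments) == 0L) {
    rlang::abort("no alignments to build conditionals from")
  }
  cond <- alignments |>
    dplyr::mutate(
      q = alignment_score_prob(.data$score, max(.data$score), score_scale),
      .by = "read_id"
    )
  if (model == "cov") {
    if (is.null(profiles)) {
      rlang::abort("coverage profiles are required for model = \"cov\"")
    }
    if (!setequal(unique(cond$tname),
                  intersect(unique(cond$tname),
                            attr(profiles, "catalog")$tname))) {
      rlang::abort("profiles missing for some aligned transcripts")
    }
    cond$q <- cond$q * .se_prob(profiles, cond$tx, cond$start, cond$end)
  }
  # reads where every conditional underflowed carry no information
  n_before <- length(unique(cond$read_id))
  cond <- dplyr::filter(cond, any(.data$q > 0), .by = "read_id")
  cond <- dplyr::filter(cond, .data$q > 0)
  n_dropped <- n_before - length(unique(cond$read_id))
  if (n_dropped > 0) {
    rlang::inform(paste0(
      "alignment_conditionals: dropped ", n_dropped,
      " read(s) whose conditional probabilities all underflowed"
    ))
  }
  cond <- dplyr::select(cond, "read_id", "tname", "tx", "q")
  attr(cond, "model") <- model
  attr(cond, "n_reads") <- length(unique(cond$read_id))
  attr(cond, "catalog") <- catalog
  cond
}
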