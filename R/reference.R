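#' Published DILIst class counts
#'
#' Class sizes of the most recent FDA DILIst binary annotation release:
#' 768 drugs labelled DILI-positive and 511 DILI-negative. These are the
#' reference inputs for dataset-composition arithmetic (total size and
#' positive-to-negative ratio) when the public CSV is not available
#' locally.
#'
#' @return Named integer vector with elements `positive` and `negative`.
#' @export
dilist_reference_counts <- function() {
  c(positive = 768L, negative = 511L)
}

#' Dataset composition summary
#'
#' Total record count and positive-to-negative ratio from binary class
#' counts.
#'
#' @param counts Named vector with `positive` and `negative` counts, e.g.
#'   [dilist_reference_counts()].
#' @return List with `total` and `pos_neg_ratio`.
#' @export
class_balance_summary <- function(counts = dilist_reference_counts()) {
  stopifnot(all(c("positive", "negative") %in% names(counts)),
            counts["negative"] > 0)
  list(total = as.integer(counts[["positive"]] + counts[["negative"]]),
       pos_neg_ratio = counts[["positive"]] / counts[["negative"]])
}
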