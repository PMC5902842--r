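# Interval arithmetic on 0-based half-open intervals, represented as
# tibbles with integer columns `start` and `end` (start inclusive, end
# exclusive). IRanges does the set algebra; conversion happens here only.

iv <- function(start = integer(), end = integer()) {
  tibble(start = as.integer(start), end = as.integer(end))
}

iv_to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

iranges_to_iv <- function(r) {
  iv(IRanges::start(r) - 1L, IRanges::end(r))
}

iv_sort <- function(x) dplyr::arrange(x, .data$start, .data$end)

iv_len <- function(x) sum(x$end - x$start)

# exon minus CDS and friends
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(iv())
  if (nrow(b) == 0) return(iv_sort(a))
  iranges_to_iv(IRanges::setdiff(iv_to_iranges(a), iv_to_iranges(b)))
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv())
  iranges_to_iv(IRanges::intersect(iv_to_iranges(a), iv_to_iranges(b)))
}

iv_union <- function(a, b) {
  iranges_to_iv(IRanges::reduce(IRanges::union(iv_to_iranges(a), iv_to_iranges(b))))
}

# TRUE when every base of `a` lies inside the union of `b`
iv_within <- function(a, b) {
  iv_len(iv_setdiff(a, b)) == 0
}

iv_overlaps <- function(a, b) {
  iv_len(iv_intersect(a, b)) > 0
}

# gaps between consecutive intervals inside [span_start, span_end) — introns
iv_gaps <- function(x, span_start, span_end) {
  span <- iv(span_start, span_end)
  iv_setdiff(span, x)
}

stopifnot_intervals <- function(x, what = "interval") {
  if (any(x$end < x$start)) {
    abort(sprintf("malformed %s: end < start", what), class = "genesetqc_interval_error")
  }
  invisible(x)
}
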