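#' Contrast-based difference network (A-not-in-B)
#'
#' Significant edges of the index subgroup A that are absent (by unordered
#' pair identity) from comparison subgroup B's significant edge set, carrying
#' A's SCI weights. The node set is the set of endpoints of surviving edges.
#'
#' @param A,B `mm_network` objects from the same pipeline run.
#' @return list with `index`, `comparison`, `edges` (data.frame `code_i`,
#'   `code_j`, `weight`) and `nodes`.
#' @export
difference_network <- function(A, B) {
  keys_a <- pair_key(A$edges$code_i, A$edges$code_j)
  keys_b <- pair_key(B$edges$code_i, B$edges$code_j)
  keep <- !(keys_a %in% keys_b)
  edges <- A$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  list(index = A$label, comparison = B$label, edges = edges,
       nodes = sort(unique(c(edges$code_i, edges$code_j))))
}

#' Subgroup-unique significant pairs
#'
#' Over the four diabetes-type x sex networks, a pair is unique when it
#' appears in exactly one significant edge set; it is reported under that
#' subgroup with that subgroup's SCI. The result is invariant to the order
#' in which the networks are supplied.
#'
#' @param networks named list of exactly four `mm_network` objects
#'   (names/labels: the four subgroups).
#' @return data.frame `subgroup`, `code_i`, `code_j`, `sci`.
#' @export
unique_pairs <- function(networks) {
  if (length(networks) != 4L)
    stopf("unique_pairs: exactly four subgroup networks required, got %d",
          length(networks))
  labels <- vapply(networks, `[[`, character(1), "label")
  all_keys <- unlist(lapply(networks, function(nw)
    pair_key(nw$edges$code_i, nw$edges$code_j)))
  multiplicity <- table(all_keys)
  rows <- list()
  for (nw in networks) {
    if (!nrow(nw$edges)) next
    keys <- pair_key(nw$edges$code_i, nw$edges$code_j)
    keep <- multiplicity[keys] == 1L
    if (any(keep))
      rows[[nw$label]] <- data.frame(
        subgroup = nw$label,
        code_i = pmin(nw$edges$code_i, nw$edges$code_j)[keep],
        code_j = pmax(nw$edges$code_i, nw$edges$code_j)[keep],
        sci = nw$edges$weight[keep],
        stringsAsFactors = FALSE
      )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subgroup = character(0), code_i = character(0),
               code_j = character(0), sci = numeric(0))
  out <- out[order(match(out$subgroup, sort(labels)), out$code_i, out$code_j), ]
  rownames(out) <- NULL
  out
}
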