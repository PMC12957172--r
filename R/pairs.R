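#' Pairwise co-occurrence counts within a subgroup
#'
#' Exact 2x2 contingency counts for every unordered pair of retained
#' condition codes: `c_i`, `c_j` (patients with each condition), `c_ij`
#' (patients with both) and `N` (subgroup size). Pairs are reported with
#' `code_i < code_j` lexicographically.
#'
#' @param profiles long (`patient_id`, `condition_code`) comorbidity table,
#'   already restricted to the subgroup's patients and retained codes.
#' @param patient_ids ids of all patients in the subgroup (patients with no
#'   retained condition still count towards `N`).
#' @param codes retained condition codes.
#' @return data.frame `code_i`, `code_j`, `c_i`, `c_j`, `c_ij`, `N`.
#' @export
count_pairs <- function(profiles, patient_ids, codes) {
  codes <- sort(codes)
  k <- length(codes)
  n <- length(patient_ids)
  X <- matrix(0L, n, k, dimnames = list(NULL, codes))
  sel <- profiles$patient_id %in% patient_ids &
    profiles$condition_code %in% codes
  pr <- profiles[sel, ]
  X[cbind(match(pr$patient_id, patient_ids),
          match(pr$condition_code, codes))] <- 1L
  M <- crossprod(X)
  counts <- diag(M)
  if (k < 2)
    return(data.frame(code_i = character(0), code_j = character(0),
                      c_i = integer(0), c_j = integer(0),
                      c_ij = integer(0), N = integer(0)))
  idx <- which(upper.tri(M), arr.ind = TRUE)
  out <- data.frame(
    code_i = codes[idx[, 1]], code_j = codes[idx[, 2]],
    c_i = as.integer(counts[idx[, 1]]), c_j = as.integer(counts[idx[, 2]]),
    c_ij = as.integer(M[idx]), N = n,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$code_i, out$code_j), ]
  rownames(out) <- NULL
  out
}

#' Salton cosine index
#'
#' `SCI = c_ij / sqrt(c_i * c_j)`: cosine similarity of two conditions'
#' patient sets, in `[0,1]` and unaffected by the subgroup size.
#'
#' @param c_i,c_j per-condition patient counts (must be positive).
#' @param c_ij joint count.
#' @return numeric SCI (vectorised); `NA` where `c_i` or `c_j` is zero.
#' @export
sci <- function(c_i, c_j, c_ij) {
  c_i <- as.numeric(c_i); c_j <- as.numeric(c_j); c_ij <- as.numeric(c_ij)
  ifelse(c_i > 0 & c_j > 0, c_ij / sqrt(c_i * c_j), NA_real_)
}

#' Phi coefficient from 2x2 counts
#'
#' `(c_ij*N - c_i*c_j) / sqrt(c_i*c_j*(N-c_i)*(N-c_j))`: the Pearson
#' correlation of the two binary condition indicators. Undefined (`NA`) when
#' either marginal is 0 or N.
#'
#' @param c_i,c_j,c_ij,N contingency counts.
#' @return numeric phi in `[-1,1]` (vectorised).
#' @export
phi_coefficient <- function(c_i, c_j, c_ij, N) {
  c_i <- as.numeric(c_i); c_j <- as.numeric(c_j)
  c_ij <- as.numeric(c_ij); N <- as.numeric(N)
  ok <- c_i > 0 & c_i < N & c_j > 0 & c_j < N
  ifelse(ok,
         (c_ij * N - c_i * c_j) /
           sqrt(c_i * c_j * (N - c_i) * (N - c_j)),
         NA_real_)
}

#' t-value of a phi coefficient
#'
#' `t = phi * sqrt(c_ij - 2) / sqrt(1 - phi^2)`, with degrees of freedom
#' based on the joint count `c_ij` as conventionally printed for this
#' thresholding procedure (not on N; see the methods vignette). Undefined
#' (`NA`) when `c_ij < 3` (such a pair cannot pass the significance
#' criterion); `+/-Inf` when `|phi| = 1`.
#'
#' @param phi phi coefficient(s).
#' @param c_ij joint count(s).
#' @param N subgroup size(s); required only for `df_from = "N"`.
#' @param df_from degrees-of-freedom basis: `"c_ij"` (default, the printed
#'   convention for this procedure) or `"N"` (the conventional correlation
#'   test's `N - 2`).
#' @return numeric t (vectorised).
#' @export
t_value <- function(phi, c_ij, N = NULL, df_from = c("c_ij", "N")) {
  df_from <- match.arg(df_from)
  n_basis <- if (df_from == "c_ij") c_ij else {
    if (is.null(N)) stopf("t_value: N required when df_from = 'N'")
    N
  }
  len <- max(length(phi), length(c_ij), length(n_basis))
  phi <- rep_len(as.numeric(phi), len)
  c_ij <- rep_len(as.numeric(c_ij), len)
  n_basis <- rep_len(as.numeric(n_basis), len)
  out <- rep(NA_real_, len)
  ok <- !is.na(phi) & c_ij >= 3
  sat <- ok & abs(phi) >= 1
  fin <- ok & !sat
  out[sat] <- sign(phi[sat]) * Inf
  out[fin] <- phi[fin] * sqrt(n_basis[fin] - 2) / sqrt(1 - phi[fin]^2)
  out
}

#' Attach SCI, phi and t to a pair-count table
#'
#' @param pairs data.frame from [count_pairs()].
#' @return the input with columns `sci`, `phi`, `t` appended.
#' @export
pair_statistics <- function(pairs) {
  pairs$sci <- sci(pairs$c_i, pairs$c_j, pairs$c_ij)
  pairs$phi <- phi_coefficient(pairs$c_i, pairs$c_j, pairs$c_ij, pairs$N)
  pairs$t <- t_value(pairs$phi, pairs$c_ij)
  pairs
}

#' Derive the subgroup's SCI cut-off
#'
#' Implements the four-step thresholding rule that links the SCI network to
#' the phi-based significance screen:
#' (i) compute SCI and phi for every pair; (ii) count the pairs with
#' `c_ij > 0` (`q`); (iii) count the pairs (`e`) satisfying both `t > 1.96`
#' (p < 0.05) and `c_ij` above the mean joint count `sum(c_ij)/q` over the
#' `q` pairs; (iv) keep the top-`e` pairs ranked by SCI, so both measures
#' yield networks with the same number of positively associated pairs. The
#' cut-off is the SCI of the `e`-th ranked pair (`+Inf` when `e = 0`).
#' Undefined t (including `c_ij < 3`) counts as non-significant. Ties at the
#' cut-off are broken by higher `c_ij`, then lexicographic pair id.
#'
#' @param pairs data.frame from [pair_statistics()] covering every unordered
#'   pair of the subgroup's retained codes.
#' @param t_threshold significance threshold on t (default 1.96).
#' @return list with `q`, `e`, `sci_cutoff`, `n_edges`.
#' @export
derive_cutoff <- function(pairs, t_threshold = 1.96) {
  pos <- pairs[pairs$c_ij > 0, ]
  q <- nrow(pos)
  if (q == 0)
    return(list(q = 0L, e = 0L, sci_cutoff = Inf, n_edges = 0L))
  m <- sum(pos$c_ij) / q
  sig <- !is.na(pos$t) & pos$t > t_threshold & pos$c_ij > m
  e <- sum(sig)
  if (e == 0)
    return(list(q = as.integer(q), e = 0L, sci_cutoff = Inf, n_edges = 0L))
  ord <- order(-pos$sci, -pos$c_ij, pos$code_i, pos$code_j)
  list(q = as.integer(q), e = as.integer(e),
       sci_cutoff = pos$sci[ord][e], n_edges = as.integer(e))
}

#' Significant edge set under a derived cut-off
#'
#' Exactly `e` edges: the top-`e` pairs by SCI among pairs with `c_ij > 0`,
#' deterministic under ties (higher `c_ij`, then lexicographic pair).
#'
#' @param pairs data.frame from [pair_statistics()].
#' @param cutoff result of [derive_cutoff()] on the same pair set.
#' @return data.frame `code_i`, `code_j`, `weight` (the pair's SCI).
#' @export
significant_edges <- function(pairs, cutoff) {
  if (cutoff$e == 0)
    return(data.frame(code_i = character(0), code_j = character(0),
                      weight = numeric(0)))
  pos <- pairs[pairs$c_ij > 0, ]
  ord <- order(-pos$sci, -pos$c_ij, pos$code_i, pos$code_j)
  top <- pos[ord[seq_len(cutoff$e)], ]
  out <- data.frame(code_i = top$code_i, code_j = top$code_j,
                    weight = top$sci, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
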