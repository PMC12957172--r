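# Independent brute-force oracles and fixture builders. These deliberately
# use naive loops / textbook formulas so they share no code path with the
# package implementation they check.

# Random long-format comorbidity table over given codes.
random_profiles <- function(n_patients, codes, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n_patients))
    rows <- list()
    for (id in ids) {
      has <- codes[stats::runif(length(codes)) < p]
      if (length(has))
        rows[[id]] <- data.frame(patient_id = id, condition_code = has,
                                 stringsAsFactors = FALSE)
    }
    list(profiles = if (length(rows)) do.call(rbind, rows) else
           data.frame(patient_id = character(0),
                      condition_code = character(0)),
         patient_ids = ids)
  })
}

# O(N * k^2) double-loop contingency counts.
brute_pair_counts <- function(profiles, patient_ids, codes) {
  codes <- sort(codes)
  sets <- lapply(patient_ids, function(id)
    profiles$condition_code[profiles$patient_id == id])
  rows <- list()
  for (a in seq_along(codes)) for (b in seq_along(codes)) {
    if (a >= b) next
    ci <- sum(vapply(sets, function(s) codes[a] %in% s, logical(1)))
    cj <- sum(vapply(sets, function(s) codes[b] %in% s, logical(1)))
    cij <- sum(vapply(sets, function(s)
      codes[a] %in% s && codes[b] %in% s, logical(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      code_i = codes[a], code_j = codes[b],
      c_i = ci, c_j = cj, c_ij = cij, N = length(patient_ids),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$code_i, out$code_j), ]
}

# Phi via Pearson correlation of the two binary indicator vectors.
brute_phi <- function(profiles, patient_ids, code_a, code_b) {
  x <- as.numeric(vapply(patient_ids, function(id) any(
    profiles$patient_id == id & profiles$condition_code == code_a),
    logical(1)))
  y <- as.numeric(vapply(patient_ids, function(id) any(
    profiles$patient_id == id & profiles$condition_code == code_b),
    logical(1)))
  suppressWarnings(stats::cor(x, y))
}

# Full cut-off procedure by direct enumeration, written independently:
# phi from cor(), ranking by repeated max extraction.
brute_cutoff <- function(pairs, t_threshold = 1.96) {
  pos <- pairs[pairs$c_ij > 0, , drop = FALSE]
  q <- nrow(pos)
  if (q == 0) return(list(q = 0, e = 0, edges = character(0)))
  m <- mean(pos$c_ij)
  e <- 0
  for (r in seq_len(q)) {
    ph <- pos$phi[r]
    tv <- if (is.na(ph) || pos$c_ij[r] < 3) NA
          else if (abs(ph) >= 1) sign(ph) * Inf
          else ph * sqrt(pos$c_ij[r] - 2) / sqrt(1 - ph^2)
    if (!is.na(tv) && tv > t_threshold && pos$c_ij[r] > m) e <- e + 1
  }
  chosen <- character(0)
  remaining <- pos
  while (length(chosen) < e) {
    best <- which(remaining$sci == max(remaining$sci))
    if (length(best) > 1)
      best <- best[remaining$c_ij[best] == max(remaining$c_ij[best])]
    if (length(best) > 1) {
      key <- paste(remaining$code_i[best], remaining$code_j[best])
      best <- best[order(key)][1]
    } else best <- best[1]
    chosen <- c(chosen, paste(remaining$code_i[best], remaining$code_j[best],
                              sep = "|"))
    remaining <- remaining[-best, , drop = FALSE]
  }
  list(q = q, e = e, edges = sort(chosen))
}

# Deterministic simple graph with n nodes and the first m pairs in
# lexicographic order as edges.
make_simple_graph <- function(n, m, weight = 0.5) {
  nodes <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(utils::combn(nodes, 2))
  stopifnot(m <= nrow(all_pairs))
  edges <- data.frame(code_i = all_pairs[seq_len(m), 1],
                      code_j = all_pairs[seq_len(m), 2],
                      weight = weight, stringsAsFactors = FALSE)
  build_network(nodes, edges, label = sprintf("g%d_%d", n, m))
}

# Random mm_network on k nodes.
random_network <- function(k, p_edge = 0.4, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(k))
    all_pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(all_pairs)) < p_edge
    edges <- data.frame(code_i = all_pairs[keep, 1],
                        code_j = all_pairs[keep, 2],
                        weight = stats::runif(sum(keep), 0.05, 1),
                        stringsAsFactors = FALSE)
    build_network(nodes, edges, label = sprintf("rnd%d", seed))
  })
}

# Dense power iteration over the explicit Google matrix; 200 steps puts the
# oracle's own convergence error (damping^steps) far below the comparison
# tolerance.
brute_pagerank <- function(net, damping = 0.85, steps = 200) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$code_i[r]; j <- net$edges$code_j[r]
    A[i, j] <- A[i, j] + net$edges$weight[r]
    A[j, i] <- A[j, i] + net$edges$weight[r]
  }
  P <- matrix(0, n, n)
  for (col in seq_len(n)) {
    s <- sum(A[, col])
    P[, col] <- if (s == 0) rep(1 / n, n) else A[, col] / s
  }
  G <- damping * P + (1 - damping) / n
  r <- rep(1 / n, n)
  for (s in seq_len(steps)) r <- G %*% r
  stats::setNames(as.vector(r), nodes)
}

# Tiny valid synthetic config for fast tests.
tiny_config <- function(seed = 1, n = 400, planted = default_planted_pairs()) {
  synthetic_config(n_per_cohort = n, seed = seed, planted_pairs = planted)
}
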