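# Independent brute-force oracles the implementation is checked against.

# O(n^2) matching: evaluate match_calls on every pair
bf_match_pairs <- function(A, B, params = match_params()) {
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (match_calls(A[i, ], B[j, ], params))
      out[[length(out) + 1L]] <- c(i = i, j = j)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  as.data.frame(do.call(rbind, out))
}

# maximum bipartite matching size (augmenting paths) over a pair list
bf_max_matching <- function(pairs, nA, nB) {
  adj <- split(pairs$j, factor(pairs$i, levels = seq_len(nA)))
  match_b <- rep(NA_integer_, nB)
  try_kuhn <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (is.na(match_b[j]) ||
          Recall(match_b[j], seen)) {
        match_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_len(nA)) {
    seen <- rep(FALSE, nB)
    if (length(adj[[i]]) && try_kuhn(i, seen)) n <- n + 1L
  }
  n
}

# exhaustive MAR oracle: all maximal call subsets with non-empty common
# intersection and >= min_cases distinct patients; returns regions
bf_mars <- function(starts, ends, patients, min_cases = 3L) {
  n <- length(starts)
  subsets <- list()
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    s <- max(starts[idx]); e <- min(ends[idx])
    if (s < e) subsets[[length(subsets) + 1L]] <- idx
  }
  is_max <- vapply(seq_along(subsets), function(i)
    !any(vapply(seq_along(subsets), function(j)
      j != i && length(subsets[[i]]) < length(subsets[[j]]) &&
        all(subsets[[i]] %in% subsets[[j]]), logical(1))), logical(1))
  keep <- subsets[is_max]
  keep <- keep[vapply(keep, function(idx)
    length(unique(patients[idx])) >= min_cases, logical(1))]
  regs <- unique(do.call(rbind, lapply(keep, function(idx)
    c(start = max(starts[idx]), end = min(ends[idx])))))
  if (is.null(regs)) return(data.frame(start = numeric(), end = numeric()))
  regs <- as.data.frame(regs)
  regs[order(regs$start, regs$end), , drop = FALSE]
}

# exact Mann-Whitney by full enumeration of group assignments
bf_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-9))
}

# random focal-deletion callsets for property tests
random_call_set <- function(n, sample = "S1", chrom = "chr1",
                            span = c(1e6, 5e6), size = c(1e3, 5e5),
                            caller = "DN") {
  s <- floor(runif(n, span[1], span[2]))
  w <- floor(runif(n, size[1], size[2]))
  sv_calls(call_id = sprintf("%s_%s_%d", sample, caller, seq_len(n)),
           sample_id = sample, sv_type = "deletion", chrom1 = chrom,
           pos1 = s, pos2 = s + w, callers = caller)
}
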