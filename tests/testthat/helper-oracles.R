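# Independent oracles used across tests. These deliberately use naive,
# enumerate-everything formulations so they stay independent of the
# package's implementations.

# all permutations of 1..n as a matrix (n! rows); recursive, tiny n only
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force rank products: loop over preys and screens, average ranks
brute_rank_products <- function(cpm) {
  n <- nrow(cpm); k <- ncol(cpm)
  ranks <- matrix(0, n, k)
  for (s in seq_len(k)) {
    ord <- sort(cpm[, s], decreasing = TRUE)
    for (i in seq_len(n)) {
      ranks[i, s] <- mean(which(ord == cpm[i, s]))
    }
  }
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- prod(ranks[i, ])^(1 / k)
  out
}

# exact permutation p-values by exhausting all joint rank permutations of
# every screen (n!^k cases); counting rule: randomized rank product at
# position i <= observed rank product of prey i
exact_perm_pvalues <- function(cpm) {
  n <- nrow(cpm); k <- ncol(cpm)
  ranks <- apply(cpm, 2, function(x) rank(-x, ties.method = "average"))
  obs <- apply(ranks, 1, function(r) prod(r)^(1 / k))
  perms <- all_perms(n)
  grid_idx <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), k))
  count <- numeric(n)
  for (g in seq_len(nrow(grid_idx))) {
    rnd <- sapply(seq_len(k), function(s) ranks[perms[grid_idx[g, s], ], s])
    rp <- apply(rnd, 1, function(r) prod(r)^(1 / k))
    count <- count + (rp <= obs + 1e-9)
  }
  count / nrow(grid_idx)
}

# hand-rolled BH step-up, straight from the formula
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force ambiguous-kmer scan: collect every ORF's k-mer set and mark
# k-mers present in >= 2 ORFs
brute_ambiguous_kmers <- function(seqs, k) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  all_k <- unlist(sets)
  unique(all_k[duplicated(all_k)])
}

# naive substring-search read counting for references whose k-mer sets
# are pairwise disjoint
brute_substring_counts <- function(reads, orf_ids, seqs) {
  counts <- stats::setNames(integer(length(orf_ids)), orf_ids)
  for (rd in reads) {
    hit <- which(vapply(seqs, function(s) grepl(rd, s, fixed = TRUE), logical(1)))
    if (length(hit) == 1) counts[hit] <- counts[hit] + 1L
  }
  counts
}

# random DNA helper for fixtures
rand_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# pooled-variance two-sample t from the textbook formula
brute_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# one-way ANOVA F from the sum-of-squares closed form
brute_anova_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((values - mi[groups])^2)
  k <- nlevels(groups); n <- length(values)
  f_stat <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f_stat, p = pf(f_stat, k - 1, n - k, lower.tail = FALSE))
}
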