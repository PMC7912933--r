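# Independent oracles used across the suite. Each is a deliberately
# naive computation (per-diagonal run decomposition, exhaustive subset or
# path enumeration, per-site loops) kept apart from the implementation it
# checks.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# all maximal exact matches >= k between genome g and probe p (forward),
# by run-length decomposition of every diagonal of the equality matrix:
# maximal runs of >= k equal valid bases are exactly the maximal matches
mem_oracle <- function(g, p, k) {
  gc <- strsplit(g, "", fixed = TRUE)[[1L]]
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  n <- length(gc); m <- length(pc)
  acgt <- c("A", "C", "G", "T")
  out <- NULL
  for (d in (-(m - 1L)):(n - 1L)) {   # d = i - j along the diagonal
    i0 <- max(1L, 1L + d); j0 <- i0 - d
    len <- min(n - i0, m - j0) + 1L
    if (len < k) next
    ii <- i0:(i0 + len - 1L); jj <- j0:(j0 + len - 1L)
    eq <- gc[ii] == pc[jj] & gc[ii] %in% acgt
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (t in which(r$values & r$lengths >= k)) {
      out <- rbind(out, c(ref_start = ii[starts[t]], ref_end = ii[ends[t]],
                          qry_start = jj[starts[t]], qry_end = jj[ends[t]],
                          length = r$lengths[t]))
    }
  }
  df <- if (is.null(out))
    data.frame(ref_start = integer(), ref_end = integer(),
               qry_start = integer(), qry_end = integer(),
               length = integer())
  else as.data.frame(out)
  df[order(df$ref_start, df$qry_start), , drop = FALSE]
}

# exhaustive best colinear chain over all subsets of a match table
chain_oracle <- function(mm, reverse) {
  n <- nrow(mm)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) next
    sub <- mm[idx[order(mm$ref_start[idx])], , drop = FALSE]
    ok <- TRUE
    if (nrow(sub) > 1L) for (t in 2:nrow(sub)) {
      if (!(sub$ref_start[t] > sub$ref_end[t - 1L] &&
            (if (reverse) sub$qry_end[t] < sub$qry_start[t - 1L]
             else sub$qry_start[t] > sub$qry_end[t - 1L]))) {
        ok <- FALSE; break
      }
    }
    if (ok) best <- max(best, sum(sub$length))
  }
  best
}

# exhaustive global affine alignment score by path enumeration:
# match +1, mismatch 0, gap of length L costs go + ge*L
align_score_oracle <- function(a, b, go, ge) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ac); nb <- length(bc)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, score + (ac[i] == bc[j]), 0L)
    if (i <= na)
      rec(i + 1L, j, score - ge - if (state == 1L) 0 else go, 1L)
    if (j <= nb)
      rec(i, j + 1L, score - ge - if (state == 2L) 0 else go, 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# per-site p-distance loop
p_distance_oracle <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  diff <- 0L; tot <- 0L
  for (s in seq_along(ca)) {
    if (ca[s] %in% acgt && cb[s] %in% acgt) {
      tot <- tot + 1L
      if (ca[s] != cb[s]) diff <- diff + 1L
    }
  }
  if (tot == 0L) NA_real_ else diff / tot
}

# brute-force double loops for group means
group_means_oracle <- function(dm, groups) {
  species <- unique(groups)
  within <- setNames(rep(NA_real_, length(species)), species)
  between <- matrix(NA_real_, length(species), length(species),
                    dimnames = list(species, species))
  for (si in species) {
    ids <- which(groups == si)
    vals <- c()
    if (length(ids) >= 2L)
      for (x in seq_along(ids)) for (y in seq_along(ids))
        if (x < y) vals <- c(vals, dm[ids[x], ids[y]])
    if (length(vals)) within[si] <- mean(vals)
  }
  for (si in species) for (sj in species) {
    if (si == sj) next
    vals <- c()
    for (x in which(groups == si)) for (y in which(groups == sj))
      vals <- c(vals, dm[x, y])
    between[si, sj] <- mean(vals)
  }
  list(within = within, between = between)
}

# all permutations of 1..n (small n)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

random_sym_matrix <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1L) / 2)
  m + t(m)
}
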