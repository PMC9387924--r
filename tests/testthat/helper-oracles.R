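# Independent oracle implementations: deliberately written in a different
# style (plain loops, no shared helpers) from the package code they check.

# Brute-force windowed-SD / top-5 variability score for one cell.
# x: corrected values; chroms: chromosome label per value; masked: logical.
vs_oracle <- function(x, chroms, masked = rep(FALSE, length(x)),
                      n_windows = 30, n_top = 5) {
  chrom_avgs <- c()
  for (ch in unique(chroms)) {
    v <- x[chroms == ch & !masked & !is.na(x)]
    n <- length(v)
    if (n < 2) next
    if (n < n_windows) {
      starts <- 1:n
      len <- 1
    } else {
      len <- ceiling(n / n_windows)
      starts <- floor(seq(0, n - len, length.out = n_windows)) + 1
    }
    sds <- numeric(length(starts))
    for (i in seq_along(starts)) {
      lo <- starts[i]
      hi <- min(lo + len - 1, n)
      w <- v[lo:hi]
      sds[i] <- if (length(w) < 2) 0 else sd(w)
    }
    chrom_avgs <- c(chrom_avgs, mean(sds))
  }
  mean(rev(sort(chrom_avgs))[1:n_top])
}

# Exhaustive Viterbi oracle: enumerates every state path over n bins and
# returns the 0-based path with the highest joint log-likelihood
# (uniform initial distribution, stay-probability transitions, Gaussian
# emissions with an optional flat outlier mixture).
viterbi_enum_oracle <- function(x, means, sd, p_self,
                                outlier_prob = 0, outlier_density = 0.1) {
  S <- length(means)
  n <- length(x)
  emis <- matrix(0, S, n)
  for (s in 1:S) {
    for (i in 1:n) {
      emis[s, i] <- log((1 - outlier_prob) * dnorm(x[i], means[s], sd) +
                          outlier_prob * outlier_density)
    }
  }
  l_self <- log(p_self)
  l_sw <- log((1 - p_self) / (S - 1))
  # grow all paths one bin at a time, tracking loglik and last state
  ll <- emis[, 1]
  last <- 1:S
  paths <- matrix(1:S, ncol = 1)
  for (i in 2:n) {
    m <- length(ll)
    new_ll <- numeric(m * S)
    new_last <- integer(m * S)
    new_paths <- matrix(0L, m * S, i)
    row <- 0
    for (s in 1:S) {
      for (p in 1:m) {
        row <- row + 1
        trans <- if (last[p] == s) l_self else l_sw
        new_ll[row] <- ll[p] + trans + emis[s, i]
        new_last[row] <- s
        new_paths[row, ] <- c(paths[p, ], s)
      }
    }
    ll <- new_ll
    last <- new_last
    paths <- new_paths
  }
  paths[which.max(ll), ] - 1L
}

# Exhaustive TE-ICM discordance oracle: enumerate all subsets of size m of
# each lineage and all pairings, and average the fraction of unequal pairs.
# te, icm: integer karyotype class ids.
discordance_enum_oracle <- function(te, icm) {
  m <- min(length(te), length(icm))
  te_subsets <- utils::combn(seq_along(te), m, simplify = FALSE)
  icm_subsets <- utils::combn(seq_along(icm), m, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  pairings <- perms(1:m)
  total <- 0
  count <- 0
  for (ts in te_subsets) {
    for (is in icm_subsets) {
      for (pg in pairings) {
        frac <- mean(te[ts] != icm[is][pg])
        total <- total + frac
        count <- count + 1
      }
    }
  }
  total / count
}

# Writes a small SAM file of single-end alignments and returns its own
# per-bin tally (computed directly from the positions it wrote).
write_sam_fixture <- function(path, grid, positions, chroms,
                              mapq = 60L, flags = 0L) {
  n <- length(positions)
  mapq <- rep_len(mapq, n)
  flags <- rep_len(flags, n)
  chrom_lens <- tapply(grid$end, grid$chrom, max)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), as.integer(chrom_lens)))
  ord <- order(match(chroms, names(chrom_lens)), positions)
  body <- sprintf("r%03d\t%d\t%s\t%d\t%d\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                  seq_len(n), flags[ord], chroms[ord], positions[ord], mapq[ord])
  writeLines(c(header, body), path)
  # independent tally: primary, non-duplicate, mapq >= 30 reads per bin
  tally <- integer(nrow(grid))
  for (i in seq_len(n)) {
    if (bitwAnd(flags[i], 1024L) != 0L || bitwAnd(flags[i], 256L) != 0L ||
        bitwAnd(flags[i], 4L) != 0L || mapq[i] < 30L) next
    hit <- which(grid$chrom == chroms[i] & grid$start <= positions[i] - 1 &
                   grid$end > positions[i] - 1)
    if (length(hit) == 1) tally[hit] <- tally[hit] + 1L
  }
  tally
}
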