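# Independent reference implementations ("oracles") used to validate the
# package's fast paths. These deliberately use naive algorithms.

# brute-force scan for 19nt+NGG sites on both strands of a sequence string;
# returns data.frame(offset0 (0-based footprint start), strand, protospacer)
oracle_scan_sites <- function(seq) {
  n <- nchar(seq)
  rows <- list()
  rc1 <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                  collapse = ""))
  for (i in seq_len(max(0L, n - 21L))) {
    frag <- substr(seq, i, i + 21L)
    if (grepl("[^ACGT]", frag)) next
    if (substr(frag, 21L, 22L) == "GG") {
      rows[[length(rows) + 1L]] <- data.frame(
        offset0 = i - 1L, strand = "+", protospacer = substr(frag, 1L, 19L),
        stringsAsFactors = FALSE)
    }
    if (substr(frag, 1L, 2L) == "CC") {
      rows[[length(rows) + 1L]] <- data.frame(
        offset0 = i - 1L, strand = "-",
        protospacer = rc1(substr(frag, 4L, 22L)), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(offset0 = integer(), strand = character(),
                      protospacer = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# assignments of the pooled sample to the two groups (no ties assumed)
oracle_mw_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# quadratic-time ROC AUC: pairwise concordance with half-credit ties
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# quadratic-time precision-recall reference: for every distinct score
# threshold, count calls directly
oracle_pr <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    called <- scores >= th[i]
    prec[i] <- sum(labels & called) / sum(called)
    rec[i] <- sum(labels & called) / np
  }
  list(precision = prec, recall = rec)
}

# brute-force tier evaluator: walks the tier definitions directly over a
# site list, using a naive interval-overlap loop for proximality
oracle_tier <- function(sites, prox_df) {
  overlaps <- function(chrom, s0, e0) {
    for (k in seq_len(nrow(prox_df))) {
      if (prox_df$chrom[k] == chrom && s0 < prox_df$end[k] &&
          prox_df$start[k] < e0) return(TRUE)
    }
    FALSE
  }
  n_prox <- 0L; n_gen <- 0L
  for (i in seq_len(nrow(sites))) {
    if (sites$score[i] < 21) n_gen <- n_gen + 1L
    if (sites$score[i] < 31 &&
        overlaps(sites$chrom[i], sites$site_start[i], sites$site_end[i]))
      n_prox <- n_prox + 1L
  }
  if (n_prox <= 1 && n_gen <= 1) "T0"
  else if (n_prox <= 1) "T1"
  else if (n_gen <= 1) "T2"
  else if (n_prox <= 2) "T3"
  else if (n_prox <= 3) "T4"
  else "FAIL"
}

# exhaustive enumeration of every nested secondary structure (min loop 3);
# returns the minimum total energy. Only feasible for short sequences.
oracle_fold_mfe <- function(seq, pair_energy = c(GC = -3, AU = -2, GU = -1),
                            min_loop = 3L) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  pe <- function(x, y) {
    key <- paste0(sort(c(x, y)), collapse = "")
    switch(key, "CG" = pair_energy[["GC"]], "AU" = pair_energy[["AU"]],
           "GU" = pair_energy[["GU"]], NA_real_)
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      e <- pe(b[k], b[j])
      if (is.na(e)) next
      left <- if (k > i) rec(i, k - 1L) else 0
      inner <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0
      best <- min(best, e + left + inner)
    }
    best
  }
  if (length(b) < min_loop + 2L) return(0)
  rec(1L, length(b))
}

# naive per-position base frequency profile of a protospacer set
oracle_base_profile <- function(protos) {
  m <- do.call(rbind, strsplit(protos, ""))
  sapply(seq_len(ncol(m)), function(j)
    sapply(c("A", "C", "G", "T"), function(b) mean(m[, j] == b)))
}

rc_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
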