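# Independent oracles used across the suite. These deliberately re-derive
# each quantity by a different route from the package implementation.

# Literal transcription of the published filtering workflow, coded
# independently of call_hits(): a non-redundant interactor is kept if
# present in at least 2 experiments, excluded outright when seen in any
# control, screened for >= 4 unique peptides in 2 experiments
# ("Filtered_2"), and promoted when present in all three experiments
# ("Filtered_3").
tier_oracle <- function(u, control_hit) {
  if (control_hit) return("excluded_control")
  if (sum(u >= 1) < 2) return("below_threshold")
  if (sum(u >= 4) < 2) return("below_threshold")
  if (sum(u >= 1) == length(u)) "filtered3" else "filtered2"
}

# Brute-force two-sided Fisher p by direct hypergeometric enumeration
# with log-binomials (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Wilcoxon rank-sum p via the classic counting recursion
# for the number of m-subsets of 1..(m+n) with a given Mann-Whitney U
# (independent of the combn-based enumeration in the package).
wilcox_count_oracle <- local({
  memo <- new.env(parent = emptyenv())
  cw <- function(k, m, n) {
    if (k < 0 || k > m * n) return(0)
    if (m == 0 || n == 0) return(as.numeric(k == 0))
    key <- paste(k, m, n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- cw(k - n, m - 1, n) + cw(k, m, n - 1)
    memo[[key]] <- val
    val
  }
  function(x, y) {
    nx <- length(x); ny <- length(y); N <- nx + ny
    r <- rank(c(x, y))
    stopifnot(!anyDuplicated(c(x, y)))
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mid <- nx * ny / 2
    us <- 0:(nx * ny)
    cnt <- vapply(us, cw, numeric(1), m = nx, n = ny)
    sum(cnt[abs(us - mid) >= abs(U - mid) - 1e-9]) / choose(N, nx)
  }
})

# Build a hit_table directly from a peptide matrix (rows = accessions,
# cols = replicates) without going through evidence files.
hit_table_from_matrix <- function(u, control_hit = rep(FALSE, nrow(u)),
                                  mascot = NULL) {
  R <- ncol(u)
  acc <- sprintf("P%04d", seq_len(nrow(u)))
  runs <- lapply(seq_len(R), function(r) {
    keep <- u[, r] > 0
    s <- if (is.null(mascot)) 10 * u[keep, r] else mascot[keep, r]
    pulldown_run("BAIT", "bait", r, data.frame(
      accession = acc[keep], gene_symbol = rep(NA_character_, sum(keep)),
      unique_peptides = as.integer(u[keep, r]), mascot_score = s,
      stringsAsFactors = FALSE))
  })
  ctl_acc <- acc[control_hit]
  controls <- list(pulldown_run("WT", "control_untagged", 1L, data.frame(
    accession = ctl_acc, gene_symbol = rep(NA_character_, length(ctl_acc)),
    unique_peptides = rep(1L, length(ctl_acc)),
    mascot_score = rep(20, length(ctl_acc)), stringsAsFactors = FALSE)))
  es <- experiment_set(runs, controls)
  ht <- build_hit_matrix(es)
  suppressWarnings(flag_control_contaminants(ht, es))
}

# tier lookup by accession index for tables built with hit_table_from_matrix;
# proteins absent from every bait replicate have no row (implicit
# "not a candidate")
tiers_by_index <- function(ht, n) {
  out <- rep("absent", n)
  idx <- as.integer(sub("^P", "", ht$accession))
  out[idx] <- ht$tier
  out
}

# 3D rotation matrix from an axis and angle (radians)
rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  rbind(c(c_ + a[1]^2 * C, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s),
        c(a[2] * a[1] * C + a[3] * s, c_ + a[2]^2 * C, a[2] * a[3] * C - a[1] * s),
        c(a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, c_ + a[3]^2 * C))
}

# tiny voxel image with rectangular blocks set to given intensities
block_image <- function(dim = c(20L, 20L, 8L), voxel = c(0.1, 0.1, 0.3),
                        blocks = list(), base = 0) {
  arr <- array(base, dim = dim)
  for (b in blocks)
    arr[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2]] <- b$value
  arr
}
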