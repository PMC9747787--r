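# Independent oracles used to cross-check the package's estimators.

# Brute-force zero-intercept least squares: golden-section search of the SSE
# over the slope, refined from a coarse grid. Independent of the closed form.
oracle_slope <- function(copies, reads, tol = 1e-10) {
  sse <- function(b) sum((reads - b * copies)^2)
  hi <- 2 * max(reads / copies) + 1
  grid <- seq(0, hi, length.out = 200)
  lo_i <- which.min(vapply(grid, sse, 0))
  a <- grid[max(lo_i - 1, 1)]
  b <- grid[min(lo_i + 1, length(grid))]
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- sse(x1); f2 <- sse(x2)
  while (b - a > tol * (1 + b)) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- sse(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- sse(x2)
    }
  }
  (a + b) / 2
}

# Kendall tau-b by naive double loop over all pairs.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
      if (sx == 0) tx <- tx + 1
      if (sy == 0) ty <- ty + 1
      if (sx * sy > 0) conc <- conc + 1
      if (sx * sy < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  list(tau_b = (conc - disc) / sqrt((n0 - tx) * (n0 - ty)),
       S = conc - disc, conc = conc, disc = disc, tx = tx, ty = ty)
}

# All permutations via Heap's algorithm (iterative), distinct from the
# package's recursive construction. Memoized: exact tests reuse the matrix.
.oracle_perm_cache <- new.env(parent = emptyenv())
oracle_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.oracle_perm_cache[[key]])) return(.oracle_perm_cache[[key]])
  out <- oracle_perms_build(n)
  .oracle_perm_cache[[key]] <- out
  out
}

oracle_perms_build <- function(n) {
  out <- matrix(0L, factorial(n), n)
  a <- seq_len(n)
  c_vec <- integer(n)
  out[1, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c_vec[i] < i - 1) {
      if (i %% 2 == 1) {
        tmp <- a[1]; a[1] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_vec[i] + 1]; a[c_vec[i] + 1] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_vec[i] <- c_vec[i] + 1L
      i <- 1L
    } else {
      c_vec[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# Exact two-sided permutation p-value for Kendall S by full enumeration.
oracle_exact_p <- function(x, y) {
  n <- length(x)
  perms <- oracle_perms(n)
  obs <- oracle_tau_b(x, y)$S
  Y <- matrix(y[perms], nrow(perms), n)
  S <- numeric(nrow(perms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[i] - x[j])
      if (sx != 0) S <- S + sx * sign(Y[, i] - Y[, j])
    }
  }
  mean(abs(S) >= abs(obs) - 1e-9)
}

# Calinski-Harabasz via the pairwise-distance identity
# sum_i ||x_i - mean||^2 = sum_{i<j} ||x_i - x_j||^2 / n,
# so W and the total SS never touch centroids.
oracle_ch <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- length(unique(labels))
  ssq <- function(m) {
    if (nrow(m) < 2) return(0)
    sum(stats::dist(m)^2) / nrow(m)
  }
  total <- ssq(points)
  W <- sum(vapply(unique(labels), function(g)
    ssq(points[labels == g, , drop = FALSE]), 0))
  B <- total - W
  (B / (k - 1)) / (W / (n - k))
}

# Small handcrafted run: one field sample + matched blank + one PCR
# negative, with noiseless reads generated from known copies and slopes.
make_toy_run <- function(field_copies_L = c(A = 500, B = 0, C = 120),
                         blank_copies_L = c(A = 50),
                         field_slope = 200, blank_slope = 400,
                         neg_reads = c(A = 0, B = 75, C = 0)) {
  std <- data.frame(standard_id = c("std1", "std2", "std3"),
                    copies_per_reaction = c(5, 25, 50))
  taxa <- names(field_copies_L)
  # copies/reaction = copies/L * water(1L) * template(2uL) / elution(100uL)
  f_cpr <- field_copies_L / 50
  b_cpr <- rep(0, length(taxa)); names(b_cpr) <- taxa
  b_cpr[names(blank_copies_L)] <- blank_copies_L / 50
  counts <- cbind(
    field1 = c(round(field_slope * f_cpr), round(field_slope * std$copies_per_reaction)),
    blank1 = c(round(blank_slope * b_cpr), round(blank_slope * std$copies_per_reaction)),
    neg1 = c(neg_reads, rep(0, 3))
  )
  rownames(counts) <- c(taxa, std$standard_id)
  storage.mode(counts) <- "integer"
  samples <- data.frame(
    sample_id = c("field1", "blank1", "neg1"),
    site_id = c("site1", "blanksite", "none"),
    river_id = c("r1", "r1", "none"),
    role = c("field", "cooler_blank", "pcr_negative"),
    stringsAsFactors = FALSE
  )
  manifest <- run_manifest(samples, c(field1 = "blank1"), standards = std)
  list(counts = counts, manifest = manifest,
       field_copies_L = field_copies_L, blank_copies_L = blank_copies_L)
}
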