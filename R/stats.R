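#' Independent-samples t-test with Cohen's d
#'
#' Pooled-variance (Student) two-tailed t-test via
#' [stats::t.test()]`(var.equal = TRUE)`, augmented with Cohen's d
#' computed from the pooled standard deviation.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return Object of class `group_test`: `t`, `df` (`n1 + n2 - 2`), `p`
#'   (two-tailed), `d`, `mean_a`, `mean_b`, `n1`, `n2`.
#' @export
independent_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = (mean(a) - mean(b)) / sqrt(sp2),
                 mean_a = mean(a), mean_b = mean(b), n1 = n1, n2 = n2),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, d = %.3f (means %.3f vs %.3f)\n",
              x$df, x$t, x$p, x$d, x$mean_a, x$mean_b))
  invisible(x)
}

#' Convert between Cohen's d and the independent-samples t statistic
#'
#' `t = d * sqrt(n1 n2 / (n1 + n2))`; `d_from_t` is the algebraic inverse.
#' Useful for checking the internal consistency of reported statistics.
#'
#' @param d,t Effect size / t statistic.
#' @param n1,n2 Group sizes (>= 2).
#' @return The corresponding t (or d).
#' @export
t_from_d <- function(d, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  d * sqrt(n1 * n2 / (n1 + n2))
}

#' @rdname t_from_d
#' @export
d_from_t <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  t / sqrt(n1 * n2 / (n1 + n2))
}

# Stack a list of comodulograms (or matrices) into subjects x bins.
comod_stack <- function(xs) {
  mats <- lapply(xs, function(x) if (inherits(x, "comodulogram")) x$values else x)
  d <- dim(mats[[1]])
  for (m in mats) if (!identical(dim(m), d)) stop("comodulogram grid mismatch")
  list(X = t(vapply(mats, as.numeric, numeric(prod(d)))), dim = d,
       phase_freqs = if (inherits(xs[[1]], "comodulogram")) xs[[1]]$phase_freqs
                     else seq_len(d[1]),
       amp_freqs = if (inherits(xs[[1]], "comodulogram")) xs[[1]]$amp_freqs
                   else seq_len(d[2]))
}

# Vectorised pooled t for many label permutations.
# X: n x bins; A: perms x n 0/1 indicator of group-A membership.
perm_tmat <- function(X, A, n1, n2) {
  Tq <- colSums(X^2); Ts <- colSums(X)
  S1 <- A %*% X; Q1 <- A %*% X^2
  S2 <- matrix(Ts, nrow(A), ncol(X), byrow = TRUE) - S1
  Q2 <- matrix(Tq, nrow(A), ncol(X), byrow = TRUE) - Q1
  v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
  v2 <- (Q2 - S2^2 / n2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (S1 / n1 - S2 / n2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Connected components of a logical matrix under 4- or 8-connectivity.
# Returns integer label matrix (0 = background).
label_clusters <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3); dc <- rep(c(-1L, 0L, 1L), each = 3)
    keep <- !(dr == 0 & dc == 0); dr <- dr[keep]; dc <- dc[keep]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        r <- p[1] + dr[k]; s <- p[2] + dc[k]
        if (r >= 1 && r <= nr && s >= 1 && s <= nc &&
            mask[r, s] && lab[r, s] == 0L) {
          lab[r, s] <- cur
          stack[[length(stack) + 1L]] <- c(r, s)
        }
      }
    }
  }
  lab
}

# Max cluster statistic per tail for one t-map.
tail_max_stats <- function(tmap, tcrit, connectivity, stat) {
  out <- c(pos = 0, neg = 0)
  for (tail in c("pos", "neg")) {
    mask <- if (tail == "pos") tmap > tcrit else tmap < -tcrit
    mask[!is.finite(tmap)] <- FALSE            # zero-variance bins
    if (!any(mask)) next
    lab <- label_clusters(mask, connectivity)
    vals <- abs(tmap[mask])
    g <- lab[mask]
    out[tail] <- if (stat == "max") max(tapply(vals, g, max))
                 else max(tapply(vals, g, sum))
  }
  out
}

#' Cluster-based permutation test on comodulograms
#'
#' Two-stage nonparametric group comparison: per-bin pooled two-tailed t
#' statistics are thresholded at the uncorrected `threshold_alpha` critical
#' value; suprathreshold bins are grouped into connected clusters
#' (separately for positive and negative signs), each summarised by its
#' maximum |t| (or, optionally, sum of |t|).  A null distribution of the
#' largest cluster statistic per tail is built by randomly relabelling
#' subjects `n_perm` times; each observed cluster's p-value is the
#' (add-one corrected) proportion of null values at least as large, and is
#' significant when below `decision_alpha` per tail (0.025, i.e. 0.05
#' corrected across both tails).
#'
#' @param group_a,group_b Lists of [comodulogram()] objects (or matrices)
#'   on identical grids.
#' @param n_perm Number of random relabelings (default 10000).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @param threshold_alpha Uncorrected bin-level threshold (default 0.05).
#' @param decision_alpha Per-tail significance level (default 0.025).
#' @param connectivity Neighbourhood on the phase x amplitude grid: 4
#'   (edges, default) or 8 (edges + diagonals).
#' @param cluster_stat `"max"` (maximum |t| in cluster, default) or
#'   `"sum"` (sum of |t|).
#' @param method `"random"` relabelings, or `"exact"` enumeration of all
#'   distinct group assignments (small samples only).
#' @return Object of class `cluster_result`: `clusters` (list with
#'   `bins` [n x 2 matrix of (phase Hz, amp Hz)], `indices`, `sign`,
#'   `cluster_stat`, `p_perm`, `significant`), `tmap`, `tcrit`, settings.
#' @export
cluster_permutation <- function(group_a, group_b, n_perm = 10000, seed = 1L,
                                threshold_alpha = 0.05,
                                decision_alpha = 0.025, connectivity = 4,
                                cluster_stat = c("max", "sum"),
                                method = c("random", "exact")) {
  cluster_stat <- match.arg(cluster_stat)
  method <- match.arg(method)
  stopifnot(connectivity %in% c(4, 8))
  sa <- comod_stack(group_a); sb <- comod_stack(group_b)
  if (!identical(sa$dim, sb$dim)) stop("comodulogram grid mismatch")
  n1 <- nrow(sa$X); n2 <- nrow(sb$X); n <- n1 + n2
  if (n < 4) stop("need at least 4 subjects in total")
  X <- rbind(sa$X, sb$X)
  df <- n - 2
  tcrit <- stats::qt(1 - threshold_alpha / 2, df)
  dm <- sa$dim

  obs_t <- matrix(perm_tmat(X, matrix(as.numeric(seq_len(n) <= n1), 1), n1, n2),
                  dm[1], dm[2])

  n_distinct <- choose(n, n1)
  if (method == "random" && n_perm > n_distinct) {
    warning("n_perm = ", n_perm, " exceeds the ", n_distinct,
            " distinct relabelings; proceeding with random relabelings")
  }
  set.seed(seed)
  A <- if (method == "exact") {
    combs <- utils::combn(n, n1)
    t(apply(combs, 2, function(ix) as.numeric(seq_len(n) %in% ix)))
  } else {
    t(replicate(n_perm, as.numeric(seq_len(n) %in% sample(n, n1))))
  }
  Tm <- perm_tmat(X, A, n1, n2)
  null_stats <- matrix(0, nrow(A), 2, dimnames = list(NULL, c("pos", "neg")))
  for (p in seq_len(nrow(A)))
    null_stats[p, ] <- tail_max_stats(matrix(Tm[p, ], dm[1], dm[2]), tcrit,
                                      connectivity, cluster_stat)

  clusters <- list()
  for (tail in c("pos", "neg")) {
    mask <- if (tail == "pos") obs_t > tcrit else obs_t < -tcrit
    mask[!is.finite(obs_t)] <- FALSE
    if (!any(mask)) next
    lab <- label_clusters(mask, connectivity)
    for (cl in seq_len(max(lab))) {
      idx <- which(lab == cl)
      vals <- abs(obs_t[idx])
      cs <- if (cluster_stat == "max") max(vals) else sum(vals)
      nullv <- null_stats[, tail]
      p_perm <- if (method == "exact") mean(nullv >= cs - 1e-12)
                else (1 + sum(nullv >= cs)) / (1 + nrow(A))
      rc <- arrayInd(idx, dm)
      clusters[[length(clusters) + 1L]] <- list(
        bins = cbind(phase_hz = sa$phase_freqs[rc[, 1]],
                     amp_hz = sa$amp_freqs[rc[, 2]]),
        indices = idx, sign = if (tail == "pos") 1 else -1,
        cluster_stat = cs, p_perm = p_perm,
        significant = p_perm < decision_alpha)
    }
  }
  structure(list(clusters = clusters, tmap = obs_t, tcrit = tcrit, df = df,
                 n_permutations = nrow(A), method = method,
                 threshold_alpha = threshold_alpha,
                 decision_alpha = decision_alpha,
                 connectivity = connectivity, cluster_stat = cluster_stat,
                 phase_freqs = sa$phase_freqs, amp_freqs = sa$amp_freqs,
                 null_stats = null_stats, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s); %d %s relabelings, |t| > %.3f (df = %d), %d-connectivity\n",
              length(x$clusters), x$n_permutations, x$method, x$tcrit, x$df,
              x$connectivity))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d: %s, %d bins (phase %g-%g Hz, amp %g-%g Hz), stat %.2f, p = %.4f%s\n",
                i, if (cl$sign > 0) "positive" else "negative",
                nrow(cl$bins), min(cl$bins[, 1]), max(cl$bins[, 1]),
                min(cl$bins[, 2]), max(cl$bins[, 2]), cl$cluster_stat,
                cl$p_perm, if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Per-bin Cohen's d between two groups of comodulograms
#'
#' @inheritParams cluster_permutation
#' @return List with `d` (phase x amp matrix), `max_d`, `max_bin`
#'   (`c(phase_hz, amp_hz)`), and the frequency grids.
#' @export
comodulogram_effect_size <- function(group_a, group_b) {
  sa <- comod_stack(group_a); sb <- comod_stack(group_b)
  if (!identical(sa$dim, sb$dim)) stop("comodulogram grid mismatch")
  n1 <- nrow(sa$X); n2 <- nrow(sb$X)
  v1 <- apply(sa$X, 2, stats::var); v2 <- apply(sb$X, 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (colMeans(sa$X) - colMeans(sb$X)) / sp
  d[sp == 0 & colMeans(sa$X) == colMeans(sb$X)] <- 0
  dmat <- matrix(d, sa$dim[1], sa$dim[2],
                 dimnames = list(sa$phase_freqs, sa$amp_freqs))
  mb <- arrayInd(which.max(abs(dmat)), sa$dim)
  list(d = dmat, max_d = dmat[mb],
       max_bin = c(phase_hz = sa$phase_freqs[mb[1]],
                   amp_hz = sa$amp_freqs[mb[2]]),
       phase_freqs = sa$phase_freqs, amp_freqs = sa$amp_freqs)
}
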