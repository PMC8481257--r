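# Correlation-versus-distance analysis of ensemble neurons and resampling
# statistics for group comparisons.

#' Pairwise activity correlation and distance of top ensemble neurons
#'
#' Takes the `top_n` neurons with the largest ensemble weight (ties broken
#' by neuron index) and returns, for every pair, the Pearson correlation of
#' their dF/F0 traces and the Euclidean distance of their centroids.
#'
#' @param weights ensemble weight per neuron (a column of the NMF P matrix)
#' @param dff matrix neurons x frames
#' @param centroids matrix neurons x 2, micrometers
#' @param top_n neurons to use (default 10)
#' @return data frame with `i`, `j`, `distance_um`, `correlation`
#' @export
pairwise_corr_distance <- function(weights, dff, centroids, top_n = 10L) {
  if (sum(weights > 0) < top_n) stop("fewer than top_n neurons with positive weight")
  sel <- order(-weights, seq_along(weights))[seq_len(top_n)]
  pairs <- utils::combn(sel, 2)
  data.frame(
    i = pairs[1, ], j = pairs[2, ],
    distance_um = sqrt(colSums((t(centroids[pairs[1, ], , drop = FALSE]) -
                                  t(centroids[pairs[2, ], , drop = FALSE]))^2)),
    correlation = vapply(seq_len(ncol(pairs)), function(p)
      stats::cor(dff[pairs[1, p], ], dff[pairs[2, p], ]), numeric(1))
  )
}

#' Bin a correlation-distance cloud
#'
#' Averages the pairwise correlations within fixed-width distance bins
#' (default 37.6 micrometers).
#'
#' @param pairs data frame from [pairwise_corr_distance()]
#' @param bin_width bin width in micrometers
#' @param max_distance upper edge of the last bin (default: covers the data)
#' @return a `binned_curve` data frame: `bin_lo`, `bin_hi`, `bin_mid`,
#'   `mean_correlation` (NA for empty bins), `n_pairs`
#' @export
bin_curve <- function(pairs, bin_width = 37.6, max_distance = NULL) {
  if (!nrow(pairs)) stop("no pairs to bin")
  if (is.null(max_distance)) max_distance <- max(pairs$distance_um)
  edges <- seq(0, max_distance + bin_width, by = bin_width)
  bin <- findInterval(pairs$distance_um, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  mc <- rep(NA_real_, nb); np <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    np[b] <- sum(sel)
    if (np[b]) mc[b] <- mean(pairs$correlation[sel])
  }
  structure(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                       mean_correlation = mc, n_pairs = np),
            class = c("binned_curve", "data.frame"))
}

#' Position-shuffled correlation-distance curve
#'
#' Null curve for the spatial-clustering analysis: `repeats` times, `n_neurons`
#' neurons are drawn at random from the same fish, their positions permuted
#' among them, and the binned correlation-distance curve computed; the curves
#' are averaged bin-wise.
#'
#' @param dff matrix neurons x frames
#' @param centroids matrix neurons x 2, micrometers
#' @param n_neurons neurons per draw (default 10)
#' @param repeats number of draws (default 10)
#' @param bin_width bin width, micrometers
#' @param max_distance common upper bin edge (default: field diagonal of the
#'   centroid cloud)
#' @param seed seed
#' @return a `binned_curve` data frame averaged over repeats
#' @export
position_shuffle_curve <- function(dff, centroids, n_neurons = 10L,
                                   repeats = 10L, bin_width = 37.6,
                                   max_distance = NULL, seed = NULL) {
  if (nrow(dff) < n_neurons) stop("need at least n_neurons neurons")
  if (is.null(max_distance)) {
    max_distance <- sqrt(sum((apply(centroids, 2, max) -
                                apply(centroids, 2, min))^2))
  }
  with_substream(seed, "position-shuffle", {
    curves <- lapply(seq_len(repeats), function(r) {
      sel <- sample.int(nrow(dff), n_neurons)
      cen <- centroids[sel[sample.int(n_neurons)], , drop = FALSE]
      w <- rep(1, n_neurons)
      pairs <- pairwise_corr_distance(w, dff[sel, , drop = FALSE], cen,
                                      top_n = n_neurons)
      bin_curve(pairs, bin_width, max_distance)
    })
    out <- curves[[1]]
    mcs <- sapply(curves, `[[`, "mean_correlation")
    out$mean_correlation <- rowMeans(mcs, na.rm = TRUE)
    out$mean_correlation[is.nan(out$mean_correlation)] <- NA_real_
    out$n_pairs <- rowSums(sapply(curves, `[[`, "n_pairs"))
    out
  })
}

#' Permutation test for a two-group difference
#'
#' The observed statistic is `mean(values[group A]) - mean(values[group B])`.
#' The values are randomly re-divided into groups of the same sizes `n_perm`
#' times to build the null distribution of the difference. The default
#' one-sided alternative `"less"` asks whether group A's mean is smaller
#' (e.g. fish with an SFPE-encoding ensemble halting less); `"greater"` and
#' `"two.sided"` are available. With `plus_one = TRUE` (default) the p-value
#' uses the finite-sample correction (#{null at least as extreme} + 1) /
#' (n_perm + 1); with `FALSE` it is the raw fraction.
#'
#' @param values numeric vector, one value per fish
#' @param group logical or two-level vector; `TRUE` / first level = group A
#' @param n_perm permutations (default 1000)
#' @param alternative `"less"`, `"greater"` or `"two.sided"`
#' @param plus_one apply the +1 correction
#' @param seed seed
#' @return a `permutation_result`: `observed`, `null` (length `n_perm`),
#'   `p_value`, `group_sizes`, `alternative`
#' @export
permutation_test <- function(values, group, n_perm = 1000L,
                             alternative = c("less", "greater", "two.sided"),
                             plus_one = TRUE, seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.logical(group)) ga <- group else {
    lv <- unique(group)
    if (length(lv) != 2L) stop("group must have exactly two levels")
    ga <- group == lv[1]
  }
  n <- length(values)
  n_a <- sum(ga)
  if (n_a == 0L || n_a == n) stop("both groups must be non-empty")
  obs <- mean(values[ga]) - mean(values[!ga])
  null <- with_substream(seed, "permutation", {
    vapply(seq_len(n_perm), function(r) {
      ia <- sample.int(n, n_a)
      mean(values[ia]) - mean(values[-ia])
    }, numeric(1))
  })
  extreme <- switch(alternative,
    less = null <= obs,
    greater = null >= obs,
    two.sided = abs(null) >= abs(obs)
  )
  p <- if (plus_one) (sum(extreme) + 1) / (n_perm + 1) else mean(extreme)
  structure(list(observed = obs, null = null, p_value = p,
                 group_sizes = c(A = n_a, B = n - n_a),
                 alternative = alternative),
            class = "permutation_result")
}

#' Two-group summary with a one-tailed t-test
#'
#' Means with standard errors, the unpaired (pooled-variance) t statistic
#' with a one-tailed p-value for the alternative that group A's mean is
#' smaller, and Cohen's d.
#'
#' @param a,b numeric vectors (at least 2 values each)
#' @param alternative passed to [stats::t.test()] (default `"less"`)
#' @return list with `mean_a`, `mean_b`, `sem_a`, `sem_b`, `t`, `df`,
#'   `p_value`, `cohens_d`
#' @export
compare_groups <- function(a, b, alternative = "less") {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = TRUE)
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  list(mean_a = mean(a), mean_b = mean(b),
       sem_a = stats::sd(a) / sqrt(length(a)),
       sem_b = stats::sd(b) / sqrt(length(b)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = d)
}
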