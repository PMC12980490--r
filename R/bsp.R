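# Bayesian sequential partitioning: recursive dyadic splits of the sample
# space scored by the multinomial-Dirichlet marginal likelihood of the leaf
# counts, explored by sequential importance sampling with resampling. The
# resulting piecewise-constant density is both evaluable and sampleable,
# which is what the reversible-jump stage needs from it.

# log multinomial-Dirichlet score difference for splitting a leaf with
# count n_j and volume V into two halves with counts (n_a, n_b)
.split_gain <- function(n_a, n_b, n_j, V, L, n, alpha) {
  lgamma((L + 1) * alpha) - lgamma(L * alpha) - lgamma(alpha) +
    lgamma(n_a + alpha) + lgamma(n_b + alpha) - lgamma(n_j + alpha) -
    (n_a + n_b) * log(V / 2) + n_j * log(V) -
    lgamma(n + (L + 1) * alpha) + lgamma(n + L * alpha)
}

#' Build a BSP partition tree from posterior samples
#'
#' Sequentially splits the root hyperrectangle at dyadic midpoints of one
#' coordinate at a time. Each split is scored by the multinomial-Dirichlet
#' marginal likelihood of the sample counts; a particle system explores
#' split sequences (leaf chosen proportional to its count, coordinate by
#' highest score gain, ties to the lowest index), with systematic
#' resampling when the weight degeneracy grows. The highest-weight
#' particle is returned as the partition; leaf density is
#' (count / total) / volume.
#'
#' @param samples Numeric matrix (rows = samples) or an `"ee_samples"`
#'   object.
#' @param max_leaves Number of leaves to grow to; default
#'   `2^ceiling(log2(sqrt(n)))`.
#' @param n_particles Number of SIS particles.
#' @param alpha Dirichlet concentration per leaf.
#' @param margin Root bounds: per-coordinate sample range expanded by this
#'   fraction on each side.
#' @param lower,upper Optional per-coordinate hard bounds clamping the
#'   padded root box (e.g. nonnegative amplitudes); recycled to the
#'   dimension.
#' @param seed Optional integer seed.
#' @return Object of class `"bsp_tree"`: `bounds` (d x 2), `leaf_lo` and
#'   `leaf_hi` (L x d), `counts`, `volumes`, `density`, `total_samples`,
#'   `log_weight`.
#' @export
build_partition <- function(samples, max_leaves = NULL, n_particles = 100,
                            alpha = 0.5, margin = 0.05, lower = NULL,
                            upper = NULL, seed = NULL) {
  if (inherits(samples, "ee_samples")) samples <- samples$samples
  x <- as.matrix(samples)
  n <- nrow(x); d <- ncol(x)
  if (n < 10 * d)
    stop(sprintf("build_partition: need >= 10 x dimension samples (have %d for d = %d)",
                 n, d))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_leaves)) max_leaves <- 2^ceiling(log2(sqrt(n)))
  lo0 <- apply(x, 2, min); hi0 <- apply(x, 2, max)
  span <- hi0 - lo0
  degenerate <- span <= 0
  if (any(degenerate))
    message(sprintf("build_partition: %d degenerate coordinate(s) will never be split",
                    sum(degenerate)))
  pad <- ifelse(degenerate, pmax(abs(lo0) * 1e-9, 1e-12), margin * span)
  lo0 <- lo0 - pad; hi0 <- hi0 + pad
  if (!is.null(lower)) lo0 <- pmax(lo0, rep_len(lower, d))
  if (!is.null(upper)) hi0 <- pmin(hi0, rep_len(upper, d))
  if (any(hi0 <= lo0))
    stop("build_partition: hard bounds leave an empty root box")
  min_width <- 1e-12 * (hi0 - lo0)

  new_particle <- function() list(lo = matrix(lo0, 1, d, byrow = TRUE),
                                  hi = matrix(hi0, 1, d, byrow = TRUE),
                                  assign = list(seq_len(n)),
                                  counts = n)
  parts <- replicate(n_particles, new_particle(), simplify = FALSE)
  logw <- numeric(n_particles)

  for (step in seq_len(max_leaves - 1L)) {
    for (p in seq_along(parts)) {
      pt <- parts[[p]]
      L <- length(pt$counts)
      # coordinate c of leaf l is cuttable if non-degenerate and still wide
      wide <- (pt$hi - pt$lo) > matrix(min_width, L, d, byrow = TRUE)
      wide[, degenerate] <- FALSE
      splittable <- pt$counts >= 1L & rowSums(wide) > 0
      if (!any(splittable)) next
      pr <- pt$counts * splittable
      j <- if (L == 1L) 1L else sample.int(L, 1L, prob = pr)
      idx <- pt$assign[[j]]
      V <- prod(pt$hi[j, ] - pt$lo[j, ])
      cand <- which(wide[j, ])
      mids <- (pt$lo[j, cand] + pt$hi[j, cand]) / 2
      n_a <- vapply(seq_along(cand),
                    function(ci) sum(x[idx, cand[ci]] < mids[ci]), 0L)
      gains <- .split_gain(n_a, pt$counts[j] - n_a, pt$counts[j], V, L, n, alpha)
      ci <- which.max(gains)                      # ties -> lowest index
      cc <- cand[ci]; mid <- mids[ci]
      in_left <- x[idx, cc] < mid
      # importance weight: score change over leaf-selection proposal prob
      logw[p] <- logw[p] + gains[ci] - log(pr[j] / sum(pr))
      # leaf j becomes the left half; the right half is appended
      lo_r <- pt$lo[j, ]; lo_r[cc] <- mid
      hi_r <- pt$hi[j, ]
      pt$lo <- rbind(pt$lo, lo_r)
      pt$hi <- rbind(pt$hi, hi_r)
      pt$hi[j, cc] <- mid
      pt$assign[[L + 1L]] <- idx[!in_left]
      pt$assign[[j]] <- idx[in_left]
      pt$counts[L + 1L] <- sum(!in_left)
      pt$counts[j] <- sum(in_left)
      parts[[p]] <- pt
    }
    w <- exp(logw - max(logw))
    ess <- sum(w)^2 / sum(w^2)
    if (ess < n_particles / 2 && step < max_leaves - 1L) {
      u <- (stats::runif(1) + seq_len(n_particles) - 1) / n_particles
      pick <- findInterval(u, cumsum(w / sum(w))) + 1L
      pick[pick > n_particles] <- n_particles
      parts <- parts[pick]
      logw[] <- 0
    }
  }
  best <- parts[[which.max(logw)]]
  counts <- best$counts
  vol <- apply(best$hi - best$lo, 1, prod)
  structure(list(bounds = cbind(lo = lo0, hi = hi0),
                 leaf_lo = best$lo, leaf_hi = best$hi,
                 counts = counts, volumes = vol,
                 density = (counts / n) / vol,
                 total_samples = n, log_weight = max(logw)),
            class = "bsp_tree")
}

#' @export
print.bsp_tree <- function(x, ...) {
  cat(sprintf("BSP partition: %d leaves over %d samples in %d dimensions\n",
              length(x$counts), x$total_samples, ncol(x$leaf_lo)))
  cat(sprintf("  nonempty leaves: %d; max leaf density %.4g\n",
              sum(x$counts > 0), max(x$density)))
  invisible(x)
}

# index of the leaf containing point `theta`, or 0L if outside the root.
# Leaves are half-open [lo, hi) except at the root's upper face (closed).
.leaf_index <- function(tree, theta) {
  b <- tree$bounds
  if (any(theta < b[, "lo"]) || any(theta > b[, "hi"])) return(0L)
  at_top <- abs(theta - b[, "hi"]) == 0
  for (l in seq_along(tree$counts)) {
    lo <- tree$leaf_lo[l, ]; hi <- tree$leaf_hi[l, ]
    if (all(theta >= lo) && all(theta < hi | (at_top & theta <= hi)))
      return(l)
  }
  0L  # numerically on an internal face; caller treats as density 0
}

#' Evaluate the BSP density at a point
#'
#' @param tree A [build_partition()] result.
#' @param theta Numeric point (or matrix of row-points).
#' @return Piecewise-constant density value(s); 0 outside the root bounds.
#' @export
density_at <- function(tree, theta) {
  if (is.matrix(theta))
    return(apply(theta, 1, function(r) density_at(tree, r)))
  l <- .leaf_index(tree, as.numeric(theta))
  if (l == 0L) 0 else tree$density[l]
}

#' Draw a point from the BSP density
#'
#' Chooses a leaf with probability count/total, then uniformly within the
#' leaf, so the draw's proposal density equals [density_at()] at the drawn
#' point.
#'
#' @param tree A [build_partition()] result.
#' @param n Number of draws.
#' @return A draw (numeric vector) for `n = 1`, else an `n` x d matrix.
#' @export
sample_from <- function(tree, n = 1) {
  nz <- which(tree$counts > 0)
  ls <- nz[sample.int(length(nz), n, replace = TRUE,
                      prob = tree$counts[nz])]
  d <- ncol(tree$leaf_lo)
  out <- tree$leaf_lo[ls, , drop = FALSE] +
    matrix(stats::runif(n * d), n, d) *
    (tree$leaf_hi[ls, , drop = FALSE] - tree$leaf_lo[ls, , drop = FALSE])
  if (n == 1L) out[1, ] else out
}

#' Serialize a BSP partition to JSON
#'
#' @param tree A [build_partition()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
partition_to_json <- function(tree, path) {
  jsonlite::write_json(list(bounds = tree$bounds,
                            leaf_lo = tree$leaf_lo, leaf_hi = tree$leaf_hi,
                            counts = tree$counts,
                            total_samples = tree$total_samples),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}
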