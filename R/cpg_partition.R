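#' Intersection threshold of a two-Gaussian mixture
#'
#' Solves `w1 * N(x; mu1, sd1^2) = w2 * N(x; mu2, sd2^2)` for the root lying
#' strictly between the two component means — the CpG-content cut point
#' separating the poor from the rich promoter class. For equal weights and
#' equal sds this is the midpoint of the means.
#'
#' @param weight,mean,sd Numeric length-2 mixture parameters (components in
#'   any order; they are sorted by mean internally).
#' @return The threshold (scalar), strictly between the two means.
#' @export
mixture_threshold <- function(weight, mean, sd) {
  stopifnot(length(weight) == 2L, length(mean) == 2L, length(sd) == 2L,
            all(sd > 0), all(weight > 0))
  o <- order(mean)
  w <- weight[o]; mu <- mean[o]; s <- sd[o]
  if (mu[1] == mu[2]) stop("component means coincide; no intersection threshold")
  f <- function(x) w[1] * dnorm(x, mu[1], s[1]) - w[2] * dnorm(x, mu[2], s[2])
  eps <- 1e-9 * (mu[2] - mu[1])
  lo <- mu[1] + eps
  hi <- mu[2] - eps
  if (f(lo) <= 0 || f(hi) >= 0) {
    stop("no density-equality root between the component means")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# one EM run for a univariate 2-component Gaussian mixture
.em_gauss2 <- function(x, w, mu, s, max_iter, tol) {
  n <- length(x)
  sd_floor <- 1e-6 * max(sd(x), 1e-12)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2 + 1e-300
    r1 <- d1 / tot
    ll <- sum(log(tot))
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 * n || n2 < 1e-8 * n) {
      return(list(ok = FALSE, reason = "vanishing component"))
    }
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s <- c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
           sqrt(sum((1 - r1) * (x - mu[2])^2) / n2))
    if (any(s < sd_floor)) {
      return(list(ok = FALSE, reason = "degenerate component variance"))
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
  }
  list(ok = TRUE, weight = w, mean = mu, sd = s, loglik = ll)
}

#' Partition promoters into CpG-rich and CpG-poor classes
#'
#' Fits a two-component univariate Gaussian mixture to the per-promoter CpG
#' counts by EM (k-means initialization plus random restarts, fixed seed; the
#' fit is on the raw per-gene totals, not a histogram) and splits the genes
#' at the intersection of the two fitted Gaussians ([mixture_threshold()]):
#' a promoter is CpG-poor iff its count lies below the threshold.
#'
#' @param counts Numeric vector of per-promoter CpG counts (at least two
#'   distinct values).
#' @param n_restarts EM restarts (the first is k-means-initialized, the rest
#'   randomized); the best log-likelihood wins.
#' @param seed Integer seed for initialization.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return Object of class `cpg_partition`: list with `counts`, `weight`,
#'   `mean`, `sd` (components ordered by mean), `threshold`, `labels`
#'   (factor `poor`/`rich`), `loglik`, `seed`. EM degeneracy (a vanishing
#'   component) and a missing density-equality root are errors.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 20, 3), rnorm(300, 60, 3))
#' p <- fit_bimodal_split(x)
#' p$threshold # close to 40
#' @export
fit_bimodal_split <- function(counts, n_restarts = 10, seed = 1,
                              max_iter = 500, tol = 1e-8) {
  x <- as.numeric(counts)
  stopifnot(all(is.finite(x)))
  if (length(unique(x)) < 2L) {
    stop("need at least two distinct count values to fit a mixture")
  }
  set.seed(seed)
  best <- NULL
  failures <- character(0)
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      km <- kmeans(x, centers = 2L, nstart = 5L)
      mu <- as.numeric(km$centers)
      s <- vapply(1:2, function(j) {
        v <- x[km$cluster == j]
        max(sd(v), 1e-3 * sd(x), 1e-6)
      }, 0)
      if (any(is.na(s))) s <- rep(sd(x) / 2, 2)
      w <- tabulate(km$cluster, 2L) / length(x)
    } else {
      mu <- sample(x, 2L) + rnorm(2L, 0, 0.1 * sd(x))
      s <- rep(sd(x) / 2, 2) * exp(rnorm(2L, 0, 0.2))
      u <- runif(1L, 0.2, 0.8)
      w <- c(u, 1 - u)
    }
    fit <- .em_gauss2(x, w, mu, s, max_iter, tol)
    if (!fit$ok) {
      failures <- c(failures, fit$reason)
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("EM failed on all restarts (", paste(unique(failures), collapse = "; "),
         "); the counts may not be bimodal")
  }
  o <- order(best$mean)
  w <- best$weight[o]; mu <- best$mean[o]; s <- best$sd[o]
  thr <- mixture_threshold(w, mu, s)
  labels <- factor(ifelse(x < thr, "poor", "rich"), levels = c("poor", "rich"))
  structure(list(counts = x, weight = w, mean = mu, sd = s, threshold = thr,
                 labels = labels, loglik = best$loglik, seed = seed),
            class = "cpg_partition")
}

#' @export
print.cpg_partition <- function(x, ...) {
  cat("CpG-content promoter partition (two-Gaussian fit)\n")
  cat(sprintf("  components: N(%.2f, %.2f^2) w=%.3f | N(%.2f, %.2f^2) w=%.3f\n",
              x$mean[1], x$sd[1], x$weight[1], x$mean[2], x$sd[2],
              x$weight[2]))
  cat(sprintf("  threshold = %.3f: %d CpG-poor, %d CpG-rich promoters\n",
              x$threshold, sum(x$labels == "poor"), sum(x$labels == "rich")))
  invisible(x)
}

#' @export
plot.cpg_partition <- function(x, breaks = 50, ...) {
  h <- graphics::hist(x$counts, breaks = breaks, freq = FALSE,
                      xlab = "CpG count in promoter window",
                      main = "CpG-content split", ...)
  xs <- seq(min(x$counts), max(x$counts), length.out = 400)
  lines(xs, x$weight[1] * dnorm(xs, x$mean[1], x$sd[1]), col = "steelblue")
  lines(xs, x$weight[2] * dnorm(xs, x$mean[2], x$sd[2]), col = "firebrick")
  abline(v = x$threshold, lty = 2, col = "red")
  invisible(x)
}
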