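# independent oracle: dense grid search over (alpha, k_eq) on the weighted
# least-squares objective
grid_search_langmuir <- function(series, alpha_range = c(1, 100),
                                 k_range = NULL, n = 400) {
  dat <- series[series$x > 0, ]
  if (is.null(k_range)) k_range <- c(min(dat$x) / 20, max(dat$x) * 20)
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n)
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n))
  best <- c(obj = Inf, alpha = NA, k = NA)
  for (k in ks) {
    s <- dat$x / (dat$x + k)
    # profile over alpha on the grid for this k
    objs <- vapply(alphas, function(a)
      sum(((dat$y - a * s) / dat$y_err)^2), numeric(1))
    i <- which.min(objs)
    if (objs[i] < best[["obj"]]) {
      best <- c(obj = objs[i], alpha = alphas[i], k = k)
    }
  }
  best
}
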