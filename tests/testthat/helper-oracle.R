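# Brute-force SDH oracle, independent of the package's tabulate-based path.
# Builds the sum/difference multisets explicitly for every window and
# evaluates each texture-feature formula by direct summation over the
# distinct histogram values.

oracle_features <- function(v, M, N, stride = 1, kernel = "abs") {
  n <- length(v)
  sums <- integer(0)
  diffs <- integer(0)
  for (l in (M + 1):n) {
    sums <- c(sums, v[l] + v[l - M])
    diffs <- c(diffs, v[l] - v[l - M])
  }
  len <- n - M
  starts <- seq(1, len - N + 1, by = stride)
  rows <- lapply(starts, function(s) {
    ws <- sums[s:(s + N - 1)]
    wd <- diffs[s:(s + N - 1)]
    js <- sort(unique(ws))
    ks <- sort(unique(wd))
    ps <- vapply(js, function(j) sum(ws == j) / N, numeric(1))
    pd <- vapply(ks, function(k) sum(wd == k) / N, numeric(1))
    mu <- 0.5 * sum(js * ps)
    S <- 0
    for (i in seq_along(js)) S <- S + (js[i] - 2 * mu)^2 * ps[i]
    D <- 0
    for (i in seq_along(ks)) D <- D + ks[i]^2 * pd[i]
    hom <- 0
    for (i in seq_along(ks)) {
      w <- if (kernel == "abs") 1 / (1 + abs(ks[i])) else 1 / (1 + ks[i]^2)
      hom <- hom + w * pd[i]
    }
    ent <- -(sum(ps * log(ps)) + sum(pd * log(pd)))
    shade <- 0
    prom <- 0
    for (i in seq_along(js)) {
      shade <- shade + (js[i] - 2 * mu)^3 * ps[i]
      prom <- prom + (js[i] - 2 * mu)^4 * ps[i]
    }
    data.frame(mean = mu, variance = 0.5 * (S + D),
               energy = sum(ps^2) * sum(pd^2), correlation = 0.5 * (S - D),
               entropy = ent, contrast = D, homogeneity = hom,
               cluster_shade = shade, cluster_prominence = prom)
  })
  do.call(rbind, rows)
}

# Build an sdh_histograms window directly from named probability maps,
# e.g. diff = c(`-2` = 1/4, `-1` = 1/4, `1` = 1/4, `2` = 1/4).
hist_pair <- function(diff, sum = c(`0` = 1), N = 1) {
  structure(list(sum_values = as.integer(names(sum)), sum_prob = unname(sum),
                 diff_values = as.integer(names(diff)), diff_prob = unname(diff),
                 window_size = N, start = 1L),
            class = "sdh_histograms")
}
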