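# Shared fixtures and independent oracles (brute force, no transforms).

# random scatter mask with a clear border so crops never clip
random_mask <- function(shape, spacing, p = 0.05, seed = 1) {
  set.seed(seed)
  g <- image_grid(shape, spacing)
  v <- array(FALSE, shape)
  inner <- lapply(shape, function(n) 3:(n - 2))
  sub <- array(runif(prod(lengths(inner))) < p,
               vapply(inner, length, integer(1)))
  v[inner[[1]], inner[[2]], inner[[3]]] <- sub
  if (!any(v)) v[ceiling(shape[1] / 2), ceiling(shape[2] / 2),
                 ceiling(shape[3] / 2)] <- TRUE
  binary_mask(v, g)
}

# all-pairs brute-force distance map (world metric), the ADT oracle;
# per-axis differences, not the expanded |a|^2+|b|^2-2ab form, so there is
# no cancellation error near zero distance
brute_force_edt <- function(mask) {
  tp <- foreground_world(mask)
  g <- mask$grid
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(g$shape[a]) - 1) * g$spacing[a])
  cen <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  d2 <- rep(Inf, nrow(cen))
  for (s in seq(1, nrow(tp), by = 128)) {
    e <- min(s + 127L, nrow(tp))
    blk <- tp[s:e, , drop = FALSE]
    m <- outer(cen[, 1], blk[, 1], "-")^2 +
      outer(cen[, 2], blk[, 2], "-")^2 +
      outer(cen[, 3], blk[, 3], "-")^2
    d2 <- pmin(d2, do.call(pmin, as.data.frame(m)))
  }
  array(sqrt(d2), g$shape)
}

# minimum world distance from each query point to a reference point set
min_point_dist <- function(query, ref, chunk = 256L) {
  out <- rep(Inf, nrow(query))
  qn <- rowSums(query^2)
  for (s in seq(1, nrow(ref), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ref))
    blk <- ref[s:e, , drop = FALSE]
    m <- outer(qn, rowSums(blk^2), "+") - 2 * (query %*% t(blk))
    out <- pmin(out, do.call(pmin, as.data.frame(m)))
  }
  sqrt(pmax(out, 0))
}

# hand-rolled product-limit estimator (events before censorings at ties)
product_limit <- function(times, events, t_eval) {
  ut <- sort(unique(times[events]))
  s <- 1
  for (tt in ut) {
    if (tt > t_eval) break
    n_risk <- sum(times >= tt)
    d <- sum(times == tt & events)
    s <- s * (1 - d / n_risk)
  }
  s
}
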