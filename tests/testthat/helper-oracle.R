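# independent grid-search oracle for tiny two-class mixtures: multi-stage
# dense grid over the clamped parameter cube, refined around the running
# argmax; deliberately shares no code with the EM path it checks

grid_oracle_2item <- function(counts, patterns, steps = c(0.05, 0.01, 0.002, 0.001)) {
  eps <- 1e-6
  pat_f <- function(p, y) if (y == 1) p else 1 - p
  centers <- rep(0.5, 5)  # p11, p12, p21, p22, pi
  win <- 0.5
  best <- -Inf
  for (st in seq_along(steps)) {
    step <- steps[st]
    grids <- lapply(1:4, function(j) {
      g <- seq(max(eps, centers[j] - win), min(1 - eps, centers[j] + win), by = step)
      unique(sort(c(g, if (st == 1) c(eps, 1 - eps))))
    })
    gpi <- seq(max(0, centers[5] - win), min(1, centers[5] + win), by = step)
    A <- B <- vector("list", nrow(patterns))
    for (k in seq_len(nrow(patterns))) {
      y <- patterns[k, ]
      A[[k]] <- as.vector(outer(pat_f(grids[[1]], y[1]), pat_f(grids[[2]], y[2])))
      B[[k]] <- as.vector(outer(pat_f(grids[[3]], y[1]), pat_f(grids[[4]], y[2])))
    }
    for (pi1 in gpi) {
      ll <- matrix(0, length(A[[1]]), length(B[[1]]))
      for (k in seq_len(nrow(patterns))) {
        if (counts[k] == 0) next
        ll <- ll + counts[k] * log(outer(pi1 * A[[k]], (1 - pi1) * B[[k]], "+"))
      }
      mx <- max(ll)
      if (mx > best) {
        best <- mx
        ij <- which(ll == mx, arr.ind = TRUE)[1, ]
        ia <- arrayInd(ij[1], c(length(grids[[1]]), length(grids[[2]])))
        ib <- arrayInd(ij[2], c(length(grids[[3]]), length(grids[[4]])))
        centers <- c(grids[[1]][ia[1]], grids[[2]][ia[2]],
                     grids[[3]][ib[1]], grids[[4]][ib[2]], pi1)
      }
    }
    win <- step
  }
  list(loglik = best, par = centers)
}

grid_oracle_1item <- function(counts, steps = c(0.02, 0.002, 0.0005)) {
  eps <- 1e-6
  centers <- rep(0.5, 3)  # p1, p2, pi
  win <- 0.5
  best <- -Inf
  for (st in seq_along(steps)) {
    step <- steps[st]
    g1 <- unique(sort(c(seq(max(eps, centers[1] - win), min(1 - eps, centers[1] + win), by = step),
                        if (st == 1) c(eps, 1 - eps))))
    g2 <- unique(sort(c(seq(max(eps, centers[2] - win), min(1 - eps, centers[2] + win), by = step),
                        if (st == 1) c(eps, 1 - eps))))
    gpi <- seq(max(0, centers[3] - win), min(1, centers[3] + win), by = step)
    for (pi1 in gpi) {
      m <- outer(pi1 * g1, (1 - pi1) * g2, "+")  # P(y = 1)
      ll <- counts[2] * log(m) + counts[1] * log(1 - m)
      mx <- max(ll)
      if (mx > best) {
        best <- mx
        ij <- which(ll == mx, arr.ind = TRUE)[1, ]
        centers <- c(g1[ij[1]], g2[ij[2]], pi1)
      }
    }
    win <- step
  }
  list(loglik = best, par = centers)
}

# canonical representative of a 4-pattern count vector under the order-8
# symmetry group (item swap, level flips); symmetric instances share their
# likelihood landscape up to relabelling
canonical_counts2 <- function(cnt) {
  variants <- list(
    cnt, cnt[c(1, 3, 2, 4)],
    cnt[c(3, 4, 1, 2)], cnt[c(2, 1, 4, 3)],
    cnt[c(4, 3, 2, 1)],
    cnt[c(2, 4, 1, 3)], cnt[c(3, 1, 4, 2)], cnt[c(4, 2, 3, 1)])
  keys <- vapply(variants, function(v) paste(v, collapse = ","), "")
  variants[[order(keys)[1]]]
}
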