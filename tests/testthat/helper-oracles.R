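# Small field presets used across tests (desk-scale geometry, same density
# and signal model as the full-size defaults).
small_params <- function(...) {
  args <- modifyList(list(width_px = 512L, height_px = 512L,
                          n_follicles = 20L, seed = 42L), list(...))
  do.call(field_params, args)
}

# Independent connected-component oracle: breadth-first flood fill,
# 4-connectivity, pure R.
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# Closed-form Welch test oracle.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exact Mann-Whitney oracle by full enumeration of rank assignments.
# Computes the two-sided p-value from the enumerated null distribution of
# the U statistic of `a`, using the same two-sided rule R applies.
mw_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  combos <- combn(na + nb, na)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  n_tot <- ncol(combos)
  p <- if (u_obs > na * nb / 2) {
    2 * sum(us >= u_obs) / n_tot
  } else {
    2 * sum(us <= u_obs) / n_tot
  }
  list(u = u_obs, p = min(p, 1))
}

# Render a pure two-spot image (no background) for suppression tests.
two_spot_image <- function(size, p1, p2, sigma = 2, peak = 1000) {
  xs <- 0:(size - 1)
  d2 <- function(p) outer((xs - p[2])^2, (xs - p[1])^2, "+")
  peak * exp(-d2(p1) / (2 * sigma^2)) + peak * exp(-d2(p2) / (2 * sigma^2))
}
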