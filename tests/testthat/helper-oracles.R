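# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: flood fill instead of V - E + F, direct series summation
# instead of psi_model's truncation logic, the separable analytic solution
# instead of the finite-difference integrator.

# Euler characteristic by flood fill: number of 8-connected foreground
# components minus number of 4-connected background components that do not
# touch the image border.
oracle_euler <- function(B) {
  B <- as.matrix(B)
  n <- nrow(B); m <- ncol(B)
  flood_count <- function(open, neigh) {
    seen <- matrix(FALSE, n, m)
    comps <- 0L
    comp_id <- matrix(NA_integer_, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      if (open[i, j] && !seen[i, j]) {
        comps <- comps + 1L
        stack <- list(c(i, j)); seen[i, j] <- TRUE
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          comp_id[p[1], p[2]] <- comps
          for (d in neigh) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= n && q[2] >= 1 && q[2] <= m &&
                open[q[1], q[2]] && !seen[q[1], q[2]]) {
              seen[q[1], q[2]] <- TRUE
              stack[[length(stack) + 1L]] <- q
            }
          }
        }
      }
    }
    list(n = comps, id = comp_id)
  }
  n8 <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
             c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  n4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  fg <- flood_count(B, n8)
  bg <- flood_count(!B, n4)
  border_ids <- unique(c(bg$id[1, ], bg$id[n, ], bg$id[, 1], bg$id[, m]))
  holes <- length(setdiff(stats::na.omit(unique(as.vector(bg$id))),
                          stats::na.omit(border_ids)))
  fg$n - holes
}

# Brute-force diagonal cube series, 200 terms, no truncation logic.
oracle_psi <- function(tau, terms = 200) {
  i <- 0:(terms - 1)
  m <- 2 * i + 1
  sum(8^3 / pi^6 * m^-6 * exp(-3 * m^2 * pi^2 * tau / 4))
}

# Mean concentration in a unit-boundary square (side 2L, C(0) = 0) from the
# separable analytic solution: the square's mean unaccomplished ratio is
# the square of the slab ratio.
oracle_mean_C_square <- function(D, t, L_half, terms = 50) {
  m <- 2 * (0:(terms - 1)) + 1
  slab <- sum(8 / (m^2 * pi^2) * exp(-m^2 * pi^2 * D * t / (4 * L_half^2)))
  1 - slab^2
}

# Trapezoid-weighted mean of a node-sampled field over the square (matches
# the integral the analytic oracle computes).
trapz_mean <- function(M) {
  n <- nrow(M)
  w <- rep(1, n); w[c(1, n)] <- 0.5
  W <- outer(w, w)
  sum(M * W) / sum(W)
}

# Small deterministic test grids.
random_grid <- function(n, m = n, p = 0.5) {
  matrix(stats::runif(n * m) < p, n, m)
}
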