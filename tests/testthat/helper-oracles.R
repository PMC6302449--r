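# Independent oracles used across the suite.

# All-pairs force evaluation, straight from the force-law definition.
brute_force_velocities <- function(pos, rad, repulsion = 10, adhesion = 0.4,
                                   factor = 1.25) {
  n <- nrow(pos)
  v <- matrix(0, n, 3)
  if (n < 2) return(v)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- pos[j, ] - pos[i, ]
      dd <- sqrt(sum(d^2))
      rsum <- rad[i] + rad[j]
      dmax <- factor * rsum
      if (dd >= dmax || dd == 0) next
      u <- d / dd
      mag <- 0
      if (dd < rsum) mag <- mag - repulsion * (1 - dd / rsum)^2
      mag <- mag + adhesion * (1 - dd / dmax)^2
      v[i, ] <- v[i, ] + mag * u
      v[j, ] <- v[j, ] - mag * u
    }
  }
  v
}

# Dense tridiagonal system for one implicit diffusion-decay axis solve.
dense_axis_solve <- function(values, n, D, lambda, dt, h, n_axes = 1) {
  r <- D * dt / h^2
  ld <- lambda * dt / n_axes
  A <- diag(1 + ld + 2 * r, n)
  A[1, 1] <- A[n, n] <- 1 + ld + r
  for (i in seq_len(n - 1)) {
    A[i, i + 1] <- -r
    A[i + 1, i] <- -r
  }
  solve(A, values)
}

# A synthetic snapshot with both cell kinds and all states, for I/O tests.
random_snapshot <- function(n = 30, seed = 42) {
  set.seed(seed)
  kind <- sample(c("tumor", "immune"), n, replace = TRUE, prob = c(0.8, 0.2))
  state <- ifelse(kind == "immune", "live",
                  sample(c("live", "apoptotic", "necrotic"), n,
                         replace = TRUE, prob = c(0.7, 0.15, 0.15)))
  vol <- runif(n, 500, 2600)
  att <- rep(NA_integer_, n)
  imm <- which(kind == "immune")
  tum <- which(kind == "tumor")
  if (length(imm) > 0 && length(tum) > 0)
    att[imm[1]] <- tum[1] - 1L
  cells <- data.frame(
    id = seq_len(n) - 1L, kind = kind,
    x = runif(n, -100, 100), y = runif(n, -100, 100), z = runif(n, -8, 8),
    volume = vol, radius = cell_radius(vol), state = state,
    oncoprotein = ifelse(kind == "tumor", runif(n, 0, 2), 0),
    attached_to = att, stringsAsFactors = FALSE)
  mesh <- create_mesh(12, 12, 1, origin = c(-120, -120, -10))
  subs <- substrate_system("oxygen", D = 1e5, lambda = 0.1,
                           boundary = "dirichlet", boundary_value = 38)
  structure(list(time = 17.5, cells = cells,
                 fields = new_field(mesh, subs), mesh = mesh,
                 substrates = subs),
            class = "tissue_snapshot")
}
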