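# Quasi-uniform direction sets on the sphere (Fibonacci lattice). Used for
# Feret caliper sampling and support-function hulls.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper hemisphere; widths are symmetric
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# directions in a cone of half-angle `ang` (radians) around unit vector u
cone_directions <- function(u, ang, n) {
  b <- orthonormal_basis(u)
  i <- seq_len(n) - 0.5
  cosa <- 1 - (1 - cos(ang)) * i / n
  sina <- sqrt(pmax(0, 1 - cosa^2))
  phi <- pi * (1 + sqrt(5)) * i
  d <- cbind(sina * cos(phi), sina * sin(phi), cosa)
  d %*% rbind(b$e1, b$e2, u)
}

# unit circle of directions orthogonal to u
orthogonal_circle <- function(u, n) {
  b <- orthonormal_basis(u)
  th <- (seq_len(n) - 1) * 2 * pi / n
  outer(cos(th), b$e1) + outer(sin(th), b$e2)
}

orthonormal_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# deterministic RNG scope: evaluate expr with a given seed, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uniform random rotation matrix (from quaternion), consumes 4 RNG draws
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
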