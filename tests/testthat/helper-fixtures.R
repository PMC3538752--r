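# Small in-code fixtures shared across the suite.

# homogeneous prolate field with e1 along `axis`
homogeneous_field <- function(dims = c(20, 9, 9), voxelSize = 2,
                              lambda = c(1.7e-3, 3e-4, 3e-4), axis = 1) {
    tens <- array(0, c(dims, 6))
    l23 <- mean(lambda[2:3])
    tens[, , , 1:3] <- l23
    tens[, , , axis] <- lambda[1]
    tensorField(tens, voxelSize = voxelSize)
}

isotropic_field <- function(dims = c(8, 8, 8), d = 7e-4, voxelSize = 2) {
    tens <- array(0, c(dims, 6))
    tens[, , , 1:3] <- d
    tensorField(tens, voxelSize = voxelSize)
}

# random symmetric positive-definite tensor with eigenvalues in [lo, hi]
random_spd_tensor <- function(lo = 1e-4, hi = 3e-3) {
    lam <- sort(runif(3, lo, hi), decreasing = TRUE)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- R %*% diag(lam) %*% t(R)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# random smooth-ish fiber as a jittered straight polyline
random_fiber <- function(n = 10, scale = 10) {
    base <- cbind(seq(0, scale, length.out = n), 0, 0)
    base + matrix(rnorm(3 * n, sd = 0.5), n, 3)
}

# tiny straight phantom (fast to build and fit)
tiny_straight <- function(snr = 30, seed = 1, length = 40)
    phantomSpec("straight", dims = c(32, 12, 12), length = length,
                tubeRadius = 4, snr = snr, seed = seed)
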