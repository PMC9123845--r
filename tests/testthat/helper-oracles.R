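# Independent brute-force oracles. These re-derive every quantity from
# first principles with naive loops and must stay independent of the
# package implementation they check.

# GLCM of the 3x3 axial patch at (cx, cy, z): enumerate every ordered
# in-patch neighbour pair over the 8 unit directions; background (0)
# pairs excluded. Returns the raw count table.
oracle_patch_glcm <- function(q, cx, cy, z, N) {
    dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
    P <- matrix(0, N, N)
    for (d in seq_len(nrow(dirs))) {
        for (px in (cx - 1):(cx + 1)) for (py in (cy - 1):(cy + 1)) {
            nx <- px + dirs[d, 1]; ny <- py + dirs[d, 2]
            if (nx < cx - 1 || nx > cx + 1 || ny < cy - 1 || ny > cy + 1)
                next
            a <- q[px, py, z]; b <- q[nx, ny, z]
            if (a > 0 && b > 0) P[a, b] <- P[a, b] + 1
        }
    }
    P
}

# Haralick features from a count table, by direct summation.
oracle_haralick <- function(P) {
    p <- P / sum(P)
    con <- 0; ene <- 0; ent <- 0; hom <- 0
    N <- nrow(p)
    for (i in seq_len(N)) for (j in seq_len(N)) {
        con <- con + p[i, j] * (i - j)^2
        ene <- ene + p[i, j]^2
        if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
        hom <- hom + p[i, j] / (1 + abs(i - j))
    }
    c(contrast = con, energy = ene, entropy = ent, homogeneity = hom)
}

# 2x2 erosion of one slice, anchor top-left, by direct looping.
oracle_erode2x2 <- function(m) {
    d <- dim(m)
    out <- matrix(FALSE, d[1], d[2])
    for (x in seq_len(d[1] - 1)) for (y in seq_len(d[2] - 1))
        out[x, y] <- m[x, y] && m[x + 1, y] && m[x, y + 1] && m[x + 1, y + 1]
    out
}

# Per-pixel min Euclidean distance (pixels) to the set pixels of a slice.
oracle_slice_distance <- function(m) {
    d <- dim(m)
    pts <- which(m, arr.ind = TRUE)
    out <- matrix(Inf, d[1], d[2])
    if (nrow(pts) == 0) return(out)
    for (x in seq_len(d[1])) for (y in seq_len(d[2]))
        out[x, y] <- sqrt(min((pts[, 1] - x)^2 + (pts[, 2] - y)^2))
    out
}

# Dilation of a slice by the discrete disk {dx^2 + dy^2 <= r^2}.
oracle_disk_dilate <- function(m, r) {
    d <- dim(m)
    out <- matrix(FALSE, d[1], d[2])
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
    pts <- which(m, arr.ind = TRUE)
    for (i in seq_len(nrow(pts))) {
        xs <- pts[i, 1] + offs$dx; ys <- pts[i, 2] + offs$dy
        ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
        out[cbind(xs[ok], ys[ok])] <- TRUE
    }
    out
}

# Benjamini-Hochberg step-up, written out longhand.
oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- (m / seq_len(m)) * p[o]
    if (m > 1)
        for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# Small phantom defaults shared by tests: a desk-scale grid that keeps
# the full tissue geometry (the acceptance suite documents this
# scale-down relative to the acquisition-size default grid).
tiny_spec <- function(noise_sd = 0, bias_amplitude = 0, seed = 1L,
                      grid = c(48L, 48L, 9L))
    phantomSpec(grid_shape = grid, noise_sd = noise_sd,
                bias_amplitude = bias_amplitude, rng_seed = seed)

# A deterministic quantized volume wrapper for texture tests.
as_quantized <- function(arr, N = 8L)
    new("QuantizedVolume", data = array(as.integer(arr), dim(arr)),
        levels = as.integer(N), spacing = c(0.43, 0.43, 4))
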