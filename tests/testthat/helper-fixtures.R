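# Shared fixtures and independent oracles. Renders are cached per test run
# so several test files can reuse the same synthetic colony.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
    if (!exists(key, envir = .fixtures)) assign(key, fn(), envir = .fixtures)
    get(key, envir = .fixtures)
}

noNoise <- function() list(poisson_on = FALSE, read_sigma = 0, background = 0)

# small quiet dome used by most unit tests (H = R = 80 um, 1 um voxels)
smallColony <- function() fixture("smallColony", function() {
    rc <- renderColony(colonySpec(H = 80, R = 80, noise = noNoise(),
                                  seed = 3L))
    rc$distmap <- surfaceDistanceMap(rc$truth@mask)
    rc
})

# same dome with the default noise model on
smallColonyNoisy <- function() fixture("smallColonyNoisy", function() {
    rc <- renderColony(colonySpec(H = 80, R = 80, seed = 3L))
    rc$distmap <- surfaceDistanceMap(rc$truth@mask)
    rc
})

# taller noiseless dome reaching above 100 um (ratio / axial checks)
tallColony <- function() fixture("tallColony", function() {
    rc <- renderColony(colonySpec(H = 120, R = 120, noise = noNoise(),
                                  seed = 5L))
    rc$distmap <- surfaceDistanceMap(rc$truth@mask)
    rc
})

# Brute-force oracle for the air-facing surface distance: explicit
# 6-neighbor surface detection and min-over-surface-voxel Euclidean
# distances in physical coordinates. Independent of the package's EDT.
bruteSurfaceDistance <- function(m, vs, includeBase = FALSE) {
    d <- dim(m)
    surf <- array(FALSE, d)
    idx <- which(m, arr.ind = TRUE)
    off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (r in seq_len(nrow(idx))) {
        v <- idx[r, ]
        for (j in 1:6) {
            nb <- v + off[j, ]
            if (nb[3] < 1) {            # substrate below the base plane
                if (includeBase) { surf[v[1], v[2], v[3]] <- TRUE; break }
                next
            }
            if (any(nb < 1) || any(nb > d) || !m[nb[1], nb[2], nb[3]]) {
                surf[v[1], v[2], v[3]] <- TRUE
                break
            }
        }
    }
    sphys <- sweep(which(surf, arr.ind = TRUE), 2, vs, "*")
    out <- array(NA_real_, d)
    mp <- sweep(idx, 2, vs, "*")
    for (r in seq_len(nrow(idx))) {
        dd <- (sphys[, 1] - mp[r, 1])^2 + (sphys[, 2] - mp[r, 2])^2 +
            (sphys[, 3] - mp[r, 3])^2
        out[idx[r, 1], idx[r, 2], idx[r, 3]] <- sqrt(min(dd))
    }
    out
}

# random smooth blob mask on a 32^3 grid
randomBlobMask <- function(seed, q = 0.7) {
    set.seed(seed)
    a <- array(rnorm(32^3), c(32, 32, 32))
    sm <- array(0, dim(a))
    for (k in 1:32) sm[, , k] <- EBImage::gblur(a[, , k], 3)
    sm > stats::quantile(sm, q)
}

# death-ramp probability of the generator
rampProb <- function(z, d0, d1, pk) pk * pmin(pmax((z - d0) / (d1 - d0), 0), 1)

# log-linear decay-length fit of an axial profile (depth below the cylinder
# top), reusing fitDecayLength on a renamed table
axialLambda <- function(axp, maxDepth = 40) {
    top <- max(axp$z_um)
    pr <- data.frame(distance_um = top - axp$z_um,
                     mean_intensity = axp$mean_intensity,
                     n_voxels = axp$n_voxels)
    pr <- pr[pr$distance_um <= maxDepth & pr$mean_intensity > 0, ]
    fitDecayLength(pr[order(pr$distance_um), ], minCount = 5, relFloor = 0)
}
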