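# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary_array <- function(x) {
  is.array(x) && (is.logical(x) || all(x %in% c(0, 1)))
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  array(x != 0, dim = dim(x))
}

# mL occupied by one voxel
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

# Integer offsets of an ellipsoidal structuring element with per-axis voxel
# radii (0 allowed: axis collapses). radii in voxels.
ball_offsets <- function(radii) {
  radii <- as.numeric(radii)
  rng <- lapply(radii, function(r) seq.int(-floor(r), floor(r)))
  g <- expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]])
  keep <- rep(TRUE, nrow(g))
  for (a in 1:3) {
    r <- radii[a]
    v <- g[[a]]
    keep <- keep & if (r == 0) v == 0 else TRUE
  }
  g <- g[keep, , drop = FALSE]
  den <- pmax(radii, 1e-12)
  inside <- (g$dx / den[1])^2 + (g$dy / den[2])^2 + (g$dz / den[3])^2 <= 1 + 1e-9
  as.matrix(g[inside, , drop = FALSE])
}

# Offsets of a physical ball of radius `r_mm` given anisotropic spacing.
physical_ball_offsets <- function(r_mm, spacing) {
  nmax <- floor(r_mm / spacing)
  rng <- lapply(nmax, function(k) seq.int(-k, k))
  g <- expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= r_mm^2 + 1e-9, , drop = FALSE])
}

dilate_with_offsets <- function(mask, offsets) {
  dm <- dim(mask)
  if (nrow(offsets) == 0) return(as_mask(mask))
  out <- cpp_dilate(as.logical(mask), as.integer(dm),
                    matrix(as.integer(offsets), ncol = 3))
  array(out, dim = dm)
}

# Squared Euclidean distance (mm^2) from each voxel to the nearest TRUE voxel.
edt_sq <- function(mask, spacing) {
  dm <- dim(mask)
  array(cpp_edt_sq(as.logical(mask), as.integer(dm), as.numeric(spacing)),
        dim = dm)
}

label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  array(cpp_label_components(as.logical(mask), as.integer(dm),
                             as.integer(connectivity)), dim = dm)
}
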