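# Shared fixture builders: all fixtures are generated in code.

# minimal phantom: aorta tube + one calcium lesion on a small grid
tiny_phantom_spec <- function(lesion_hu = 700, lumen_hu = 40, noise_sd = 0,
                              seed = 1L, lesion_center = c(26, 20, 16),
                              lesion_radius = 3) {
  phantom_spec(
    grid_shape = c(40, 40, 32), spacing = c(1, 1, 1),
    aorta = list(centerline = rbind(c(20, 20, 0), c(20, 20, 32)),
                 radius_mm = 8, hu = lumen_hu),
    calcium_lesions = list(list(center = lesion_center,
                                radius_mm = lesion_radius, hu = lesion_hu)),
    background_hu = 40, noise_sd = noise_sd, seed = seed)
}

# brute-force voxel-wise dilation oracle (independent of the Rcpp path)
brute_dilate <- function(mask, radii) {
  dm <- dim(mask)
  out <- array(FALSE, dim = dm)
  idx <- which(mask, arr.ind = TRUE)
  den <- pmax(radii, 1e-12)
  for (r in seq_len(nrow(idx))) {
    for (dx in -floor(radii[1]):floor(radii[1]))
      for (dy in -floor(radii[2]):floor(radii[2]))
        for (dz in -floor(radii[3]):floor(radii[3])) {
          if ((dx / den[1])^2 + (dy / den[2])^2 + (dz / den[3])^2 > 1 + 1e-9)
            next
          p <- idx[r, ] + c(dx, dy, dz)
          if (all(p >= 1) && all(p <= dm)) out[p[1], p[2], p[3]] <- TRUE
        }
  }
  out
}

# brute-force Cox partial log-likelihood for a single covariate, no ties
brute_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# brute-force all-pairs AUC oracle (ties count one half)
brute_auc <- function(scores, events) {
  pos <- scores[events == 1]
  neg <- scores[events == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# small survival cohort with a single binary covariate
binary_cohort <- function(n, beta, seed, prevalence = 0.5,
                          baseline = -log(1 - 0.093) / 365) {
  spec <- cohort_sim_spec(
    n = n,
    variable_specs = list(grp = list(kind = "binary",
                                     prevalence = prevalence)),
    true_beta = c(grp = beta), baseline_hazard = baseline, seed = seed)
  simulate_cohort(spec)
}
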