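# Shared fixtures, built once per test run and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# circular correlation coefficient (Fisher & Lee) for angles in radians
circular_cor <- function(a, b) {
  num <- sum(sin(outer(a, a, "-")[lower.tri(diag(length(a)))]) *
               sin(outer(b, b, "-")[lower.tri(diag(length(b)))]))
  den <- sqrt(sum(sin(outer(a, a, "-")[lower.tri(diag(length(a)))])^2) *
                sum(sin(outer(b, b, "-")[lower.tri(diag(length(b)))])^2))
  num / den
}

# small aperture movies (21-sample grid) per protocol
small_movie <- function(name, grid = 21) {
  memo(paste0("movie_", name, "_", grid),
       render_apertures(make_protocol(name), grid_samples = grid))
}

# 20 x 20 default patch + full-field-only simulation, noisy and noiseless
small_patch <- function() {
  memo("patch20", make_retinotopic_patch(patch_spec(lattice = c(20, 20),
                                                    seed = 42)))
}
small_sim <- function() {
  memo("sim20", simulate_bold(small_patch(), protocols = "fullfield"))
}
small_patch_clean <- function() {
  memo("patch20c", make_retinotopic_patch(
    patch_spec(lattice = c(20, 20), seed = 42, noise_sd = 0,
               nbr_noise_sd = 0)))
}
small_sim_clean <- function() {
  memo("sim20c", simulate_bold(small_patch_clean(),
                               protocols = "fullfield"))
}

# 30 x 30 default patch + full-field simulation (the study-scale conditions)
patch30 <- function() {
  memo("patch30", make_retinotopic_patch(patch_spec(seed = 42)))
}
sim30 <- function() {
  memo("sim30", simulate_bold(patch30(), protocols = "fullfield"))
}

ff_reference <- function() {
  memo("ff_ref", reference_waveform(make_protocol("fullfield")))
}

# construct a series with an exact correlation r against a reference
series_with_cor <- function(r, ref, mean_level = 100) {
  u <- ref - mean(ref)
  u <- u / sqrt(sum(u^2))
  v <- seq_along(ref) - mean(seq_along(ref))
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  mean_level + r * u + sqrt(1 - r^2) * v
}
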