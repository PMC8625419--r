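# Shared fixtures, built once per test run.

# sinusoidal grating whose stripe axis lies at `angle_deg`
make_stripes <- function(angle_deg, lambda = 8, H = 128, W = 128,
                         amp = 50, base = 100) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  th <- angle_deg * pi / 180
  base + amp * cos(2 * pi * (-c * sin(th) + r * cos(th)) / lambda)
}

axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

unit_vecs <- function(angles_deg) {
  t <- angles_deg * pi / 180
  cbind(cos(t), sin(t))
}

# brute-force OOP/director oracle: maximize mean cos^2(theta_i - phi) on a
# fine phi grid (independent of the eigen-decomposition path)
oop_bruteforce <- function(vectors, step = 0.01) {
  ang <- atan2(vectors[, 2], vectors[, 1])
  phi <- seq(0, 180 - step, by = step) * pi / 180
  score <- vapply(phi, function(p) mean(cos(ang - p)^2), 0)
  k <- which.max(score)
  list(oop = 2 * score[k] - 1, director_deg = phi[k] * 180 / pi)
}

# one trained texture model + training well set, cached across tests
.fixture_env <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    ws <- generate_wellset(4, 0.5, cells_per_well = 8, base_seed = 100,
                           other_fraction = 0.3)
    .fixture_env$train_ws <- ws
    .fixture_env$model <- train_texture_model(ws$scenes, fraction = 0.025,
                                              seed = 1)
  }
  .fixture_env$model
}

fixture_train_scenes <- function() {
  fixture_model()
  .fixture_env$train_ws$scenes
}
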