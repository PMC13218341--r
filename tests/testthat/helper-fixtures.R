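# Shared fixtures, built lazily and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default-range phantom population (n = 30, seed 1) and its shape model
fix_population <- function() fixture("pop30", function() {
  generate_population(30, seed = 1)
})

fix_model <- function() fixture("model30", function() {
  build_ssm(fix_population()$mesh,
            landmark_nodes = phantom_landmark_nodes(33L, 16L))
})

# landmark tibble sampled exactly from a mesh on the phantom grid
grid_landmarks <- function(mesh, nz = 33L, nc = 16L) {
  phantom_landmarks(mesh, nz, nc, noise_sd = 0)
}

# latitude-ring sphere mesh (watertight, outward wound)
sphere_mesh <- function(r, n = 24, center = c(0, 0, 0)) {
  nz <- n; nc <- 2L * n
  zt <- cos(seq(pi * (1 - 1 / (2 * nz)), pi / (2 * nz), length.out = nz))
  v <- NULL
  for (z in zt) {
    rr <- sqrt(1 - z^2)
    th <- 2 * pi * (0:(nc - 1)) / nc
    v <- rbind(v, cbind(r * rr * cos(th), r * rr * sin(th), r * z))
  }
  v <- rbind(v, c(0, 0, -r), c(0, 0, r))
  idx <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  i <- rep(seq_len(nz - 1L), each = nc); j <- rep(seq_len(nc), nz - 1L)
  f <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)),
             cbind(nz * nc + 1L, idx(1L, seq_len(nc) + 1L), idx(1L, seq_len(nc))),
             cbind(nz * nc + 2L, idx(nz, seq_len(nc)), idx(nz, seq_len(nc) + 1L)))
  m <- surface_mesh(sweep(v, 2, center, "+"), f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# tiny muscle tibble for constructed static-optimization problems
toy_muscles <- function(pcsa, arm_ankle, arm_knee = rep(0, length(pcsa))) {
  tibble::tibble(name = sprintf("m%d", seq_along(pcsa)),
                 group = "plantarflexor", pcsa_mm2 = pcsa,
                 arm_ankle_m = arm_ankle, arm_knee_m = arm_knee,
                 dir_x = 0, dir_y = 0, dir_z = -1)
}

# long condition tibble from a participants x conditions matrix
long_table <- function(m, conditions = colnames(m)) {
  tidyr::expand_grid(participant = seq_len(nrow(m)), condition = conditions) |>
    dplyr::mutate(value = as.vector(t(m)))
}
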