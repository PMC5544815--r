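# Small shared fixtures, built once per test run.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

small_geom <- function() fixture("geom", function()
  generate_phantom(40, 120, n_heart_nodes = 162, n_torso_nodes = 252,
                   n_electrodes = 64, seed = 7))

small_tm <- function() fixture("tm", function() compute_transfer_matrix(small_geom()))

fhn <- function() fixture("fhn", function() cell_model("fhn"))

small_gbar <- function() fixture("gbar", function()
  as.numeric(calibrate_gbar(small_geom()$heart, fhn(), n_steps = 400)))

# a paced beat on the small phantom heart (origin 115, LV free wall)
small_beat <- function() fixture("beat", function()
  simulate_beat(small_geom()$heart, fhn(),
                propagation_params(small_gbar(), n_steps = 450, origin = 115)))

small_windows <- function() fixture("windows", function()
  estimate_windows(small_beat()$phi_H, 1))

# tiny basis ensemble: 12 beats on the small heart
small_basis_beats <- function() fixture("basis_beats", function() {
  labels <- label_regions(small_geom()$heart)
  origins <- choose_beat_origins(labels, small_geom()$heart, "ALL", 12, seed = 42)
  lapply(origins, function(o)
    simulate_beat(small_geom()$heart, fhn(),
                  propagation_params(small_gbar(), n_steps = 450, origin = o)))
})

small_basis <- function() fixture("basis", function()
  truncate_basis(compute_svd(assemble_ensemble(small_basis_beats()), with_v = FALSE)))

# open flat triangulated grid (for gradient-operator and plane-wave tests)
flat_grid_mesh <- function(nx = 6, ny = 6, h = 1) {
  xy <- expand.grid(x = (0:(nx - 1)) * h, y = (0:(ny - 1)) * h)
  v <- cbind(xy$x, xy$y, 0)
  id <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    faces[[length(faces) + 1L]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
    faces[[length(faces) + 1L]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

# The full-scale benchmark shared by the end-to-end acceptance checks
# (25 origins per region, 5 held-out beats, SNR 30 dB, seed 1).
acceptance_benchmark <- function() fixture("acc_bench", function()
  run_benchmark(experiment_config(origins_per_region = 25, seed = 1),
                beat_count_sweep = c(6, 50), verbose = FALSE))
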