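# Shared fixtures, built once per test run and cached in this environment.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fixture_template <- function(compartment = "medial") {
  cached(paste0("template_", compartment), build_template(compartment))
}

# Predictor trained once on a fixed synthetic surrogate (expensive enough
# to share across tests).
fixture_predictor <- function() {
  cached("predictor", {
    co <- generate_cohort(500, seed = 200001, effect_size = 0)
    train_peak_predictor(make_training_table(co, seed = 100001),
                         seed = 300001)
  })
}

# A constant-output predictor: zero hidden->output weights make the
# prediction equal to the stored output centers.
stub_predictor <- function(medial, lateral, total) {
  structure(list(
    weights = list(W1 = matrix(0, 2, 6), b1 = rep(0, 2),
                   W2 = matrix(0, 3, 2), b2 = rep(0, 3)),
    hidden = 2,
    x_center = rep(0, 6), x_scale = rep(1, 6),
    y_center = c(medial, lateral, total), y_scale = rep(1, 3),
    inputs = c("height", "mass", "walking_speed", "joint_alignment",
               "age", "sex01"),
    outputs = c("peak_medial_bw", "peak_lateral_bw", "peak_total_bw")
  ), class = "peak_predictor")
}

# Minimal valid mesh of independent axis-aligned boxes with prescribed
# volumes / tissue / region labels, for degeneration-statistic tests.
toy_mesh <- function(volumes, tissue, region,
                     layer = rep(0L, length(volumes))) {
  n <- length(volumes)
  stopifnot(length(tissue) == n, length(region) == n)
  edge <- volumes^(1 / 3)
  nodes <- matrix(0, 8 * n, 3)
  hexa <- matrix(0L, n, 8)
  unit <- matrix(c(0, 0, 0,  0, 0, 1,  1, 0, 1,  1, 0, 0,
                   0, 1, 0,  0, 1, 1,  1, 1, 1,  1, 1, 0),
                 ncol = 3, byrow = TRUE) # positive orientation
  for (i in seq_len(n)) {
    idx <- (i - 1) * 8 + 1:8
    nodes[idx, ] <- unit * edge[i]
    nodes[idx, 1] <- nodes[idx, 1] + 3 * i # separate the boxes
    hexa[i, ] <- idx
  }
  structure(list(nodes = nodes, hexa = hexa, tissue = tissue,
                 layer = layer, cell = seq_len(n), region = region,
                 compartment = "medial"),
            class = "compartment_mesh")
}

# A one-row subject list for loading tests.
toy_subject <- function(mass = 73.6, height = 166.5, walking_speed = 1.37,
                        joint_alignment = 5.14, age = 58, sex = "female") {
  list(mass = mass, height = height, walking_speed = walking_speed,
       joint_alignment = joint_alignment, age = age, sex = sex)
}
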