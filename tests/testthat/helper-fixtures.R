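# Shared fixtures, built in code. The default-cohort pipeline run is
# expensive (imputation + cross-validated training + three explainability
# reports), so it is computed once per test session and reused.

.fixture_env <- new.env(parent = emptyenv())

# Full pipeline run under the default study conditions: 618 subjects, the
# 20-group / 166-variable block structure, four planted informative groups.
default_pipeline_run <- function() {
  if (is.null(.fixture_env$run)) {
    cfg <- pipeline_config(out_dir = file.path(tempdir(), "pdcognet-default"),
                           cohort = cohort_spec(seed = 20250930L),
                           seed = 20250930L)
    .fixture_env$run <- run_pipeline(cfg, verbose = FALSE)
  }
  .fixture_env$run
}

# A small, fast group specification: same latent-block generative model,
# four groups, 14 variables.
small_group_spec <- function() {
  g <- data.frame(
    name = c("COG", "MOTOR", "MOOD", "MISC"),
    n_vars = c(3L, 4L, 5L, 2L),
    block_correlation = 0.8,
    informative = c(TRUE, TRUE, FALSE, FALSE),
    effect_size = c(-1.2, 1.0, 0, 0),
    stringsAsFactors = FALSE
  )
  g
}

small_cohort <- function(seed = 1L, n = 150L, missing_rate = 0.05) {
  generate_cohort(cohort_spec(
    n_subjects = n, groups = small_group_spec(),
    target_prevalence_followup = 0.31,
    target_prevalence_baseline = 0.24,
    missing_rate = missing_rate, seed = seed
  ))
}

# Small random network for attribution tests.
toy_network <- function(n_inputs, hidden = 3L, seed = 1L) {
  init_network(n_inputs, hidden_sizes = hidden, seed = seed)
}

# Quick training config for unit tests that only exercise mechanics.
fast_tc <- function(seed = 1L, max_epochs = 8L) {
  train_config(max_epochs = max_epochs, early_stopping_patience = 3L,
               seed = seed)
}

# Finite-difference gradient of the focal loss w.r.t. every parameter.
numeric_gradient <- function(params, X, y, lc, h = 1e-5) {
  num <- list(weights = params$weights, biases = params$biases)
  for (l in seq_along(params$weights)) {
    for (slot in c("weights", "biases")) {
      arr <- params[[slot]][[l]]
      g <- arr * 0
      for (i in seq_along(arr)) {
        pp <- params; pp[[slot]][[l]][i] <- arr[i] + h
        pm <- params; pm[[slot]][[l]][i] <- arr[i] - h
        g[i] <- (focal_loss(forward(pp, X), y, lc) -
                   focal_loss(forward(pm, X), y, lc)) / (2 * h)
      }
      num[[slot]][[l]] <- g
    }
  }
  num
}

# Rank-statistic AUC oracle: exhaustive pair counting, ties count half.
auc_pair_count <- function(y_true, p) {
  lab <- cog_factor(y_true)
  pos <- p[lab == "Impaired"]
  neg <- p[lab == "Intact"]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
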