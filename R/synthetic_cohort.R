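#' Default PPMI-like variable-group specification
#'
#' Returns the default 20-group specification of baseline variable blocks:
#' socio-demographics, clinical scales (MDS-UPDRS I-III, Hoehn & Yahr,
#' medication/DBS status), cognitive tests (MoCA, JLO, HVLT-R, SDMT, LNS,
#' semantic fluency), neuropsychiatric questionnaires (GDS-15, STAI, QUIP,
#' REM sleep disorder screen), DAT-imaging uptake summaries, and a genetic
#' block. Per-group variable counts total 166. The two binary
#' treatment indicators (PD medication, deep brain stimulation) are carried
#' as a single two-variable group so that the partition has exactly 20
#' groups.
#'
#' Four groups are marked informative by default -- baseline global
#' cognition (MoCA), verbal memory (HVLT-R), motor examination
#' (MDS-UPDRS III) and anxiety (STAI) -- with log-odds effect sizes on the
#' follow-up impairment outcome attached to their unit-variance latent
#' factors. Signs follow clinical direction: higher cognition/memory
#' protective, higher motor severity/anxiety harmful.
#'
#' @param informative character vector of group names that carry signal.
#' @param effect_sizes named numeric vector of log-odds coefficients for the
#'   informative groups (names must match `informative`).
#' @param block_correlation latent-factor loading shared by all groups;
#'   real in `[0, 1)`.
#' @return data.frame with columns `name`, `n_vars`, `block_correlation`,
#'   `informative`, `effect_size`.
#' @export
default_group_spec <- function(informative = c("MOCA", "HVLT_R",
                                               "UPDRS_III", "STAI"),
                               effect_sizes = c(MOCA = -1.2, HVLT_R = -0.8,
                                                UPDRS_III = 0.9, STAI = 1.0),
                               block_correlation = 0.8) {
  groups <- data.frame(
    name = c("SEX", "ED_YEARS", "AGE_AT_VISIT", "PD_TREATMENT",
             "UPDRS_I", "UPDRS_II", "UPDRS_III", "HY",
             "MOCA", "JLO", "HVLT_R", "SDMT", "LNS", "SEM_FLUENCY",
             "GDS15", "STAI", "QUIP", "REM_SLEEP",
             "DATSCAN", "GEN_DATA"),
    n_vars = c(1L, 1L, 1L, 2L,
               6L, 13L, 33L, 1L,
               1L, 1L, 7L, 1L, 1L, 1L,
               15L, 40L, 13L, 12L,
               6L, 10L),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(groups$n_vars) == 166L)
  groups$block_correlation <- block_correlation
  groups$informative <- groups$name %in% informative
  groups$effect_size <- 0
  if (length(informative) > 0) {
    missing_es <- setdiff(informative, names(effect_sizes))
    if (length(missing_es) > 0) {
      stop("no effect size given for informative group(s): ",
           paste(missing_es, collapse = ", "))
    }
    groups$effect_size[groups$informative] <-
      unname(effect_sizes[groups$name[groups$informative]])
  }
  validate_group_spec(groups)
  groups
}

validate_group_spec <- function(groups) {
  stopifnot(
    is.data.frame(groups),
    all(c("name", "n_vars", "block_correlation", "informative",
          "effect_size") %in% names(groups)),
    !anyDuplicated(groups$name),
    all(groups$n_vars >= 1L),
    all(groups$block_correlation >= 0 & groups$block_correlation < 1)
  )
  if (any(!groups$informative & groups$effect_size != 0)) {
    stop("effect_size must be 0 for non-informative groups")
  }
  invisible(groups)
}

#' Cohort generation settings
#'
#' @param n_subjects number of subjects (default 618).
#' @param groups group specification, see [default_group_spec()].
#' @param target_prevalence_followup expected fraction impaired at 3-year
#'   follow-up (default 192/618).
#' @param target_prevalence_baseline fraction impaired at baseline
#'   (default 147/618, i.e. the stable-impaired plus reverter counts).
#' @param missing_rate MCAR missingness applied to the raw table; must be
#'   below 0.20.
#' @param noise_sd standard deviation of the idiosyncratic noise added on
#'   top of each loading-scaled latent factor.
#' @param seed master seed; all stages derive child seeds from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 618L,
                        groups = default_group_spec(),
                        target_prevalence_followup = 192 / 618,
                        target_prevalence_baseline = 147 / 618,
                        missing_rate = 0.05,
                        noise_sd = NULL,
                        seed = 1L) {
  validate_group_spec(groups)
  stopifnot(
    n_subjects >= 2,
    target_prevalence_followup > 0, target_prevalence_followup < 1,
    target_prevalence_baseline > 0, target_prevalence_baseline < 1,
    missing_rate >= 0
  )
  if (missing_rate >= 0.2) {
    stop("missing_rate must be < 0.20")
  }
  spec <- list(
    n_subjects = as.integer(n_subjects),
    groups = groups,
    target_prevalence_followup = target_prevalence_followup,
    target_prevalence_baseline = target_prevalence_baseline,
    missing_rate = missing_rate,
    noise_sd = noise_sd,   # NULL = complement loading to unit variance
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

group_column_names <- function(groups) {
  unlist(lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    if (g$n_vars == 1L) g$name
    else sprintf("%s_%02d", g$name, seq_len(g$n_vars))
  }), use.names = FALSE)
}

# Map latent continuous severity to an integer MoCA score consistent with
# the binary label: intact -> [26, 30], impaired -> [15, 25]. Only the
# binarized label feeds the pipeline; the integer mapping just has to be
# monotone within class and respect the cut-off.
severity_to_moca <- function(severity, impaired) {
  score <- integer(length(severity))
  u <- rank(severity, ties.method = "first") / (length(severity) + 1)
  if (any(!impaired)) {
    ui <- rank(u[!impaired], ties.method = "first") /
      (sum(!impaired) + 1)
    score[!impaired] <- 26L + as.integer(floor(ui * 5))
  }
  if (any(impaired)) {
    uo <- rank(u[impaired], ties.method = "first") / (sum(impaired) + 1)
    score[impaired] <- 15L + as.integer(floor(uo * 11))
  }
  stopifnot(all(score >= 0L & score <= 30L),
            all((score >= 26L) == !impaired))
  score
}

#' Generate a synthetic Parkinson's cohort
#'
#' Simulates a baseline subject-by-variable table with a latent-factor block
#' structure (one unit-variance factor per variable group; observed
#' variables are `loading * factor + noise`), plus baseline and 3-year
#' follow-up MoCA scores. Follow-up impairment is drawn from a logistic
#' model on the latent factors of the informative groups, with the
#' intercept solved numerically so that expected prevalence matches the
#' target. Baseline impairment is thresholded on a noisy replicate of the
#' cognition factor at the empirical quantile matching the baseline target.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `X_raw` (numeric
#'   matrix, possibly containing `NA` after missingness injection),
#'   `group_map`, `moca_baseline`, `moca_followup`, `latent_factors`,
#'   `truth_informative`, and the generating `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- spec$groups
  n <- spec$n_subjects
  set.seed(derive_seed(spec$seed, "latent-factors"))
  factors <- matrix(stats::rnorm(n * nrow(groups)), nrow = n,
                    dimnames = list(NULL, groups$name))

  set.seed(derive_seed(spec$seed, "observed-variables"))
  cols <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    rho <- g$block_correlation
    sd_noise <- spec$noise_sd %||% sqrt(1 - rho^2)
    eps <- matrix(stats::rnorm(n * g$n_vars, sd = sd_noise), nrow = n)
    cols[[i]] <- rho * factors[, i] + eps
  }
  X <- do.call(cbind, cols)
  colnames(X) <- group_column_names(groups)

  group_map <- new_group_map(split(
    colnames(X),
    factor(rep(groups$name, groups$n_vars), levels = groups$name)
  ))

  # Follow-up impairment: logistic on informative latent factors, intercept
  # calibrated so expected prevalence hits the target.
  lp <- drop(factors %*% groups$effect_size)
  target <- spec$target_prevalence_followup
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  if (f(-30) > 0 || f(30) < 0) {
    stop("infeasible cohort spec: cannot calibrate follow-up prevalence")
  }
  b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  if (abs(f(b0)) > 0.01) {
    stop("infeasible cohort spec: intercept search did not converge")
  }
  set.seed(derive_seed(spec$seed, "followup-outcome"))
  p_imp <- stats::plogis(b0 + lp)
  impaired_fu <- stats::runif(n) < p_imp

  # Baseline impairment: noisy replicate of the cognition factor,
  # thresholded at the empirical quantile matching the baseline target.
  set.seed(derive_seed(spec$seed, "baseline-outcome"))
  cog_idx <- if ("MOCA" %in% groups$name) "MOCA" else groups$name[1]
  sev_base <- -0.85 * factors[, cog_idx] +
    sqrt(1 - 0.85^2) * stats::rnorm(n)
  q <- stats::quantile(sev_base, 1 - spec$target_prevalence_baseline,
                       names = FALSE)
  impaired_bl <- sev_base > q
  moca_baseline <- severity_to_moca(-sev_base, impaired_bl)

  # Follow-up severity correlated with the linear predictor, mapped to an
  # integer score consistent with the sampled label.
  sev_fu <- lp + stats::rnorm(n)
  moca_followup <- severity_to_moca(-sev_fu, impaired_fu)

  # The baseline MoCA total is itself a predictor: tie the MOCA column to
  # the generated integer score.
  if ("MOCA" %in% colnames(X)) X[, "MOCA"] <- moca_baseline

  cohort <- structure(list(
    X_raw = X,
    group_map = group_map,
    moca_baseline = moca_baseline,
    moca_followup = moca_followup,
    latent_factors = factors,
    truth_informative = groups$name[groups$informative],
    spec = spec
  ), class = "synthetic_cohort")

  tc <- table(assign_transition_class(
    binarize_moca(moca_baseline), binarize_moca(moca_followup)))
  if (any(tc == 0) && n >= 200) {
    warning("a transition class is empty at n = ", n)
  }

  if (spec$missing_rate > 0) {
    cohort <- inject_missingness(cohort, spec$missing_rate,
                                 derive_seed(spec$seed, "missingness"))
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic PD cohort:", nrow(x$X_raw), "subjects x",
      ncol(x$X_raw), "variables in", length(x$group_map$entries),
      "groups\n")
  cat("  impaired at follow-up:",
      sum(x$moca_followup < 26), sprintf("(%.1f%%)\n",
      100 * mean(x$moca_followup < 26)))
  cat("  missing cells:", sum(is.na(x$X_raw)), "\n")
  cat("  informative groups:",
      paste(x$truth_informative, collapse = ", "), "\n")
  invisible(x)
}

#' Inject missing-completely-at-random cells
#'
#' Masks each cell of the raw feature table independently with the given
#' probability. Outcome columns (baseline and follow-up MoCA vectors) are
#' never masked. Rates at or above 0.20 are rejected: every variable
#' entering the pipeline is required to have less than 20% missingness.
#'
#' @param cohort a `synthetic_cohort`.
#' @param rate missingness probability in `[0, 0.2)`.
#' @param seed integer seed.
#' @return the cohort with `NA`s planted in `X_raw`.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"), rate >= 0)
  if (rate >= 0.2) stop("missingness rate must be < 0.20")
  if (rate == 0) return(cohort)
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(length(cohort$X_raw)) < rate,
                 nrow = nrow(cohort$X_raw))
  cohort$X_raw[mask] <- NA_real_
  cohort
}

#' Write / read a cohort as CSV plus JSON sidecar
#'
#' The CSV holds subjects x variables with a header row and empty cells for
#' missing values; the sidecar stores group membership, outcome scores, the
#' generating spec and the planted truth, so a cohort round-trips
#' losslessly up to float formatting.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  df <- as.data.frame(cohort$X_raw)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(
    group_map = cohort$group_map$entries,
    moca_baseline = cohort$moca_baseline,
    moca_followup = cohort$moca_followup,
    truth_informative = cohort$truth_informative,
    spec = list(
      n_subjects = cohort$spec$n_subjects,
      target_prevalence_followup = cohort$spec$target_prevalence_followup,
      target_prevalence_baseline = cohort$spec$target_prevalence_baseline,
      missing_rate = cohort$spec$missing_rate,
      seed = cohort$spec$seed,
      groups = cohort$spec$groups
    )
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path)) stop("cohort CSV not found: ", path)
  if (!file.exists(meta_path)) stop("cohort sidecar not found: ", meta_path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- gsub('^"|"$', "", header)
  if (anyDuplicated(header)) {
    stop("duplicated column name(s) in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = "", colClasses = "numeric")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  spec <- cohort_spec(
    n_subjects = meta$spec$n_subjects,
    groups = as.data.frame(meta$spec$groups),
    target_prevalence_followup = meta$spec$target_prevalence_followup,
    target_prevalence_baseline = meta$spec$target_prevalence_baseline,
    missing_rate = meta$spec$missing_rate,
    seed = meta$spec$seed
  )
  structure(list(
    X_raw = as.matrix(df),
    group_map = new_group_map(lapply(meta$group_map, unlist)),
    moca_baseline = as.integer(meta$moca_baseline),
    moca_followup = as.integer(meta$moca_followup),
    latent_factors = NULL,
    truth_informative = unlist(meta$truth_informative),
    spec = spec
  ), class = "synthetic_cohort")
}
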