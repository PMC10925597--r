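#' Default 39-protein biomarker panel
#'
#' Feature metadata for a multi-analyte plasma panel of 39 protein
#' biomarkers. Six of them (AFP, CA 19-9, CA-125, CEA, Prolactin, CA 15-3)
#' are flagged as routinely assayed in clinical practice, which the cost
#' model prices at the routine rate.
#'
#' @return A [feature_meta()] frame with 39 biomarker rows.
#' @export
default_biomarker_panel <- function() {
  nm <- c("AFP", "Angiopoietin-2", "AXL", "CA 15-3", "CA 19-9", "CA-125",
          "CD44", "CEA", "CYFRA 21-1", "DKK1", "Endoglin", "FGF2",
          "Follistatin", "Galectin-3", "G-CSF", "GDF15", "HE4", "HGF",
          "IL-6", "IL-8", "Kallikrein-6", "Leptin", "Mesothelin", "Midkine",
          "Myeloperoxidase", "NSE", "OPG", "OPN", "PAR", "Prolactin",
          "sEGFR", "sFas", "SHBG", "sHER2/sEGFR2/sErbB2", "sPECAM-1",
          "TGFa", "Thrombospondin-2", "TIMP-1", "TIMP-2")
  routine <- nm %in% c("AFP", "CA 19-9", "CA-125", "CEA", "Prolactin",
                       "CA 15-3")
  feature_meta(nm, kind = "biomarker", routine = routine, unit = "pg/ml")
}

#' Synthetic cohort configuration
#'
#' Describes the statistical structure of a generated liquid-biopsy cohort:
#' class sizes, which biomarkers are informative for which class (log-scale
#' mean shifts in SD units), correlated biomarker pairs induced through
#' shared latent factors, demographics, and the per-well cfDNA simulation
#' behind each sample's omega score.
#'
#' Defaults emulate a 1005-cancer / 812-normal cohort over seven cancer
#' types (Colorectal, Breast, Upper GI, Lung, Pancreas, Ovarian, Liver),
#' with pan-cancer inflammatory markers shared by all cancer classes,
#' type-specific markers (e.g. CA-125/HE4 for ovarian, AFP for liver),
#' and three redundant correlated pairs whose second member carries no
#' class effect.
#'
#' @param n_per_class named integer vector, label -> sample count.
#' @param biomarkers a [feature_meta()] frame of biomarker features.
#' @param informative named list, label -> named numeric vector of log-scale
#'   effect sizes in units of `noise_sd` (names are biomarker names).
#' @param correlated_pairs list of `list(a, b, rho)` entries; `|rho| < 1`.
#'   A biomarker may appear in at most one pair, and both members of a pair
#'   may be informative only with identical effects.
#' @param noise_sd log-scale standard deviation of biomarker concentrations.
#' @param baseline_log_mean log-scale baseline mean (same for all features;
#'   effects are differences, so the baseline is a nuisance location).
#' @param age_ranges named list, label -> `c(min, max, mean)` in years.
#' @param sex_probs named list, label -> probabilities for (Male, Female).
#' @param race_probs named list, label -> probabilities for
#'   (Asian, Black, Caucasian, Hispanic, Other).
#' @param n_wells wells per cfDNA sample for the omega simulation.
#' @param omega_shift named numeric, label -> well-level shift; 0 gives a
#'   null omega score, positive values push the cancer p-values down so
#'   the expected omega score is `1 - exp(shift)`.
#' @param seed integer seed; generation is deterministic given it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(
    n_per_class = c(Normal = 812, Colorectal = 388, Breast = 209,
                    `Upper GI` = 113, Lung = 104, Pancreas = 93,
                    Ovarian = 54, Liver = 44),
    biomarkers = default_biomarker_panel(),
    informative = default_informative_map(names(n_per_class)),
    correlated_pairs = list(
      list(a = "IL-6", b = "G-CSF", rho = 0.80),
      list(a = "sEGFR", b = "sHER2/sEGFR2/sErbB2", rho = 0.75),
      list(a = "OPN", b = "DKK1", rho = 0.70)),
    noise_sd = 0.5,
    baseline_log_mean = 2,
    age_ranges = default_age_ranges(names(n_per_class)),
    sex_probs = default_sex_probs(names(n_per_class)),
    race_probs = default_race_probs(names(n_per_class)),
    n_wells = 4,
    omega_shift = default_omega_shifts(names(n_per_class)),
    seed = 1L) {
  cfg <- list(n_per_class = n_per_class, biomarkers = biomarkers,
              informative = informative, correlated_pairs = correlated_pairs,
              noise_sd = noise_sd, baseline_log_mean = baseline_log_mean,
              age_ranges = age_ranges, sex_probs = sex_probs,
              race_probs = race_probs, n_wells = n_wells,
              omega_shift = omega_shift, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

default_informative_map <- function(classes) {
  cancer <- setdiff(classes, "Normal")
  shared <- c("IL-8" = 1.5, "IL-6" = 1.2, "OPN" = 1.0, "sEGFR" = 0.8,
              "TGFa" = 0.6, "Prolactin" = 0.4)
  specific <- list(
    Colorectal = c("CEA" = 1.5, "TIMP-2" = 0.8),
    Breast     = c("CA 15-3" = 1.5, "Thrombospondin-2" = 0.8),
    `Upper GI` = c("Midkine" = 1.2, "HGF" = 1.0),
    Lung       = c("CYFRA 21-1" = 1.5, "NSE" = 1.0),
    Pancreas   = c("CA 19-9" = 1.5, "Mesothelin" = 0.8),
    Ovarian    = c("CA-125" = 2.0, "HE4" = 1.5),
    Liver      = c("AFP" = 2.0, "GDF15" = 0.8))
  out <- lapply(cancer, function(cl) {
    eff <- shared
    sp <- specific[[cl]]
    if (!is.null(sp)) {
      for (nm in names(sp)) eff[nm] <- max(eff[nm], sp[nm], na.rm = TRUE)
    }
    eff
  })
  names(out) <- cancer
  out
}

default_age_ranges <- function(classes) {
  out <- lapply(classes, function(cl) {
    if (cl == "Normal") c(min = 17, max = 88, mean = 49)
    else c(min = 22, max = 93, mean = 63)
  })
  names(out) <- classes
  out
}

default_sex_probs <- function(classes) {
  out <- lapply(classes, function(cl) {
    p_male <- switch(cl, Normal = 0.534, Breast = 0.01, Ovarian = 0.01, 0.52)
    c(Male = p_male, Female = 1 - p_male)
  })
  names(out) <- classes
  out
}

default_race_probs <- function(classes) {
  lv <- c("Asian", "Black", "Caucasian", "Hispanic", "Other")
  out <- lapply(classes, function(cl) {
    p <- if (cl == "Normal") c(0.027, 0.190, 0.409, 0.094, 0.280)
         else c(0.300, 0.014, 0.671, 0.001, 0.014)
    stats::setNames(p / sum(p), lv)
  })
  names(out) <- classes
  out
}

default_omega_shifts <- function(classes) {
  stats::setNames(ifelse(classes == "Normal", 0, 1), classes)
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$n_per_class <= 0)) {
    stop("config error: class counts must be positive", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("config error: noise_sd must be positive",
                              call. = FALSE)
  panel <- cfg$biomarkers$name
  pair_members <- unlist(lapply(cfg$correlated_pairs, function(p) c(p$a, p$b)))
  if (anyDuplicated(pair_members)) {
    stop("config error: a biomarker may appear in at most one correlated pair",
         call. = FALSE)
  }
  for (p in cfg$correlated_pairs) {
    if (!all(c(p$a, p$b) %in% panel)) {
      stop("config error: correlated pair references unknown biomarker",
           call. = FALSE)
    }
    if (abs(p$rho) >= 1) stop("config error: |rho| must be < 1", call. = FALSE)
    for (cl in names(cfg$informative)) {
      ea <- cfg$informative[[cl]][p$a]
      eb <- cfg$informative[[cl]][p$b]
      ea <- if (is.na(ea)) 0 else ea
      eb <- if (is.na(eb)) 0 else eb
      if (ea != 0 && eb != 0 && ea != eb) {
        stop("config error: both members of correlated pair (", p$a, ", ",
             p$b, ") are informative with different effects for class ", cl,
             call. = FALSE)
      }
    }
  }
  for (cl in names(cfg$informative)) {
    unknown <- setdiff(names(cfg$informative[[cl]]), panel)
    if (length(unknown)) {
      stop("config error: informative feature not in panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(cfg$informative[[cl]]))) {
      stop("config error: effect sizes must be finite", call. = FALSE)
    }
  }
  cfg
}

#' Simulate per-well cfDNA mutation data
#'
#' Draws UID counts and per-well p-values for one plasma sample. Normal
#' p-values are uniform; the cancer p-value of each well is \eqn{u^{e^s}}
#' for uniform \eqn{u} and shift \eqn{s =} `cancer_shift`, so a positive
#' shift pushes the cancer p-values toward zero and the expected omega
#' score equals \eqn{1 - e^s} in closed form (0 at the null).
#'
#' @param n_wells number of wells (>= 1).
#' @param cancer_shift well-level shift `s`; 0 gives the symmetric null.
#' @param seed optional integer; if `NULL`, uses the current RNG stream.
#' @return An [omega_well_data()] object.
#' @export
generate_well_data <- function(n_wells, cancer_shift = 0, seed = NULL) {
  if (n_wells < 1) stop("n_wells must be >= 1", call. = FALSE)
  gen <- function() {
    uids <- sample(50:150, n_wells, replace = TRUE)
    p_n <- pmax(stats::runif(n_wells), .Machine$double.eps)
    u <- pmax(stats::runif(n_wells), .Machine$double.eps)
    p_c <- pmin(pmax(u ^ exp(cancer_shift), .Machine$double.xmin), 1)
    omega_well_data(uids, p_c, p_n)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a synthetic liquid-biopsy cohort
#'
#' Draws a seeded [feature_table()] with the structure the pipeline
#' assumes: log-normal biomarker concentrations with class-dependent mean
#' shifts for informative features, requested within-pair correlations
#' induced by shared Gaussian latent factors on the log scale (before
#' effects are added), an omega score computed by [compute_omega()] on
#' simulated well data, and integer-coded demographic covariates.
#'
#' @param config a [cohort_config()].
#' @return A [feature_table()] with `sum(n_per_class)` samples and
#'   `nrow(config$biomarkers) + 4` features (panel + Omega Score + Age +
#'   Sex + Race); bit-identical for a given config and seed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- validate_cohort_config(config)
  panel <- cfg$biomarkers$name
  p <- length(panel)
  classes <- names(cfg$n_per_class)
  with_seed(cfg$seed, {
    blocks <- lapply(classes, function(cl) {
      n <- cfg$n_per_class[[cl]]
      E <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, panel))
      for (pr in cfg$correlated_pairs) {
        lam <- sqrt(abs(pr$rho))
        f <- stats::rnorm(n)
        E[, pr$a] <- lam * f + sqrt(1 - lam^2) * stats::rnorm(n)
        E[, pr$b] <- sign(pr$rho) * lam * f + sqrt(1 - lam^2) * stats::rnorm(n)
      }
      logx <- cfg$baseline_log_mean + cfg$noise_sd * E
      eff <- cfg$informative[[cl]]
      if (!is.null(eff)) {
        for (nm in names(eff)) {
          logx[, nm] <- logx[, nm] + eff[[nm]] * cfg$noise_sd
        }
      }
      vals <- exp(logx)
      shift <- cfg$omega_shift[[cl]] %||% 0
      omega <- vapply(seq_len(n), function(i) {
        compute_omega(generate_well_data(cfg$n_wells, shift))
      }, numeric(1))
      ar <- cfg$age_ranges[[cl]]
      age <- round(pmin(pmax(
        stats::rnorm(n, ar[["mean"]], (ar[["max"]] - ar[["min"]]) / 5),
        ar[["min"]]), ar[["max"]]))
      sex <- sample(seq_along(cfg$sex_probs[[cl]]), n, replace = TRUE,
                    prob = cfg$sex_probs[[cl]]) - 1L
      race <- sample(seq_along(cfg$race_probs[[cl]]), n, replace = TRUE,
                     prob = cfg$race_probs[[cl]]) - 1L
      list(values = cbind(vals, `Omega Score` = omega, Age = age,
                          Sex = sex, Race = race),
           labels = rep(cl, n))
    })
  })
  values <- do.call(rbind, lapply(blocks, `[[`, "values"))
  labels <- unlist(lapply(blocks, `[[`, "labels"))
  meta <- rbind(
    cfg$biomarkers,
    feature_meta("Omega Score", kind = "omega", unit = ""),
    feature_meta(c("Age", "Sex", "Race"), kind = "clinical",
                 unit = c("years", "", "")))
  feature_table(values, labels, meta,
                codes = list(Sex = names(cfg$sex_probs[[1]]),
                             Race = names(cfg$race_probs[[1]])))
}
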