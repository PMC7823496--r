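# End-to-end synthetic experiment: 2 genotypes x 3 growth temperatures x
# 2 spin labels, measured over the protocol temperature grids, with nested
# biological/technical replicates -- the full chain from raw first-derivative
# spectra to per-temperature genotype comparisons.

#' Pipeline configuration
#'
#' Collects every setting of the synthetic-experiment pipeline with the
#' protocol defaults: measurement grids 0-40 degC in 5 degC steps for plants
#' grown at 20 or 27 degC and 0-25 degC in 2.5 degC steps for the
#' 5 degC-acclimated group; two biological replicates with two technical
#' replicates each; Student's t comparisons at `alpha = 0.05`.
#'
#' @param seed Integer seed governing every random draw of the run.
#' @param genotypes Character vector of two genotype labels (first = the
#'   reference/wild type).
#' @param growth_temperatures_C Growth/acclimation temperatures.
#' @param grids Named list (names = growth temperatures) of measurement
#'   temperature grids, degC.
#' @param spin_labels Subset of `c("5-SASL", "16-SASL")`.
#' @param n_bio,n_tech Biological replicates, and technical replicates per
#'   biological replicate.
#' @param snr Signal-to-noise ratio of simulated spectra (peak intensity over
#'   noise SD).
#' @param snr_decay_per_C For the 5 degC-acclimated group's 16-SASL spectra,
#'   exponential SNR decay rate with measurement temperature; emulates how
#'   measured spin-label spectra become unanalyzable outside a restricted
#'   temperature range for cold-acclimated samples. Set 0 to disable.
#' @param grid_points Points per simulated spectrum (12 mT window at 335 mT).
#' @param alpha Significance level for the per-temperature comparisons.
#' @param extraction An [extraction_options()] list; smoothing defaults ON
#'   here because pipeline spectra are noisy.
#' @param delta_h0_unit Unit convention handed to [correlation_times()].
#' @param output_dir Directory for result tables, or `NULL` to skip writing.
#' @param input_dir Optional directory of measured spectra (files readable by
#'   [read_spectrum()]); when given, simulation is skipped and the files are
#'   analysed instead.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            genotypes = c("Delisa", "522DK"),
                            growth_temperatures_C = c(20, 5, 27),
                            grids = list(`20` = seq(0, 40, by = 5),
                                         `5` = seq(0, 25, by = 2.5),
                                         `27` = seq(0, 40, by = 5)),
                            spin_labels = c("5-SASL", "16-SASL"),
                            n_bio = 2L, n_tech = 2L,
                            snr = 60, snr_decay_per_C = 0.12,
                            grid_points = 2048L,
                            alpha = 0.05,
                            extraction = extraction_options(smooth = TRUE),
                            delta_h0_unit = "mT",
                            output_dir = NULL, input_dir = NULL) {
  stopifnot(length(genotypes) == 2L, n_bio >= 1L, n_tech >= 1L, snr > 0,
            alpha > 0, alpha < 1)
  if (!all(as.character(growth_temperatures_C) %in% names(grids))) {
    stop("every growth temperature needs a grid entry (named by temperature)")
  }
  if (!all(spin_labels %in% c("5-SASL", "16-SASL"))) {
    stop("spin_labels must be among '5-SASL', '16-SASL'")
  }
  structure(list(seed = as.integer(seed), genotypes = genotypes,
                 growth_temperatures_C = growth_temperatures_C, grids = grids,
                 spin_labels = spin_labels, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), snr = snr,
                 snr_decay_per_C = snr_decay_per_C,
                 grid_points = as.integer(grid_points), alpha = alpha,
                 extraction = extraction, delta_h0_unit = delta_h0_unit,
                 output_dir = output_dir, input_dir = input_dir),
            class = "pipeline_config")
}

# Ground-truth membrane-dynamics trends for the synthetic experiment. The
# shapes emulate the study system: S and both correlation times fall with
# measurement temperature (membranes fluidize on warming); the mutant is more
# ordered/slower than the wild type after growth at 20 or 5 degC and
# indistinguishable after 27 degC acclimation.
truth_trends <- function(genotype, is_mutant, growth_C, meas_C) {
  s_base <- c(`20` = 0.62, `5` = 0.64, `27` = 0.60)[[as.character(growth_C)]]
  s_off <- if (is_mutant) c(`20` = 0.025, `5` = 0.030, `27` = 0)[[as.character(growth_C)]] else 0
  tau_mul <- if (is_mutant) c(`20` = 1.10, `5` = 1.25, `27` = 1)[[as.character(growth_C)]] else 1
  list(S = s_base + s_off - 0.006 * meas_C,
       a0 = 1.45,
       deltaH0 = 0.22 - 0.0015 * meas_C,
       tau2B = (7.5 - 0.14 * meas_C) * 1e-10 * tau_mul,
       tau2C = (8.5 - 0.16 * meas_C) * 1e-10 * tau_mul)
}

#' Simulate a complete spin-label EPR experiment
#'
#' Generates every spectrum of the configured design (genotype x growth
#' temperature x spin label x measurement temperature x replicate) with
#' known ground truth. Biological replicates perturb the underlying dynamics
#' parameters more strongly than technical replicates (multiplicative
#' Gaussian jitter, CV 3% vs 1.5%); spectra carry additive Gaussian noise at
#' the configured SNR.
#'
#' @param config A [pipeline_config()].
#' @return A list with `spectra` (list of [epr_spectrum()]) and `truth`
#'   (data frame of the ground-truth parameter values per spectrum).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  grid <- field_grid(329, 341, config$grid_points)
  spectra <- list()
  truth <- list()
  cv_bio <- 0.03
  cv_tech <- 0.015
  for (gt_i in seq_along(config$genotypes)) {
    gt <- config$genotypes[gt_i]
    for (gw in config$growth_temperatures_C) {
      temps <- config$grids[[as.character(gw)]]
      for (lbl in config$spin_labels) {
        for (tm in temps) {
          tr <- truth_trends(gt, gt_i == 2L, gw, tm)
          for (b in seq_len(config$n_bio)) {
            jb <- 1 + stats::rnorm(1L, sd = cv_bio)
            for (tech in seq_len(config$n_tech)) {
              jt <- jb * (1 + stats::rnorm(1L, sd = cv_tech))
              snr <- config$snr
              if (lbl == "16-SASL" && gw == 5) {
                snr <- snr * exp(-config$snr_decay_per_C * tm)
              }
              md <- list(spin_label = lbl, measurement_temperature_C = tm,
                         genotype = gt, growth_temperature_C = gw,
                         replicate_id = sprintf("b%dt%d", b, tech))
              if (lbl == "5-SASL") {
                spl <- splittings_for_order(tr$S * jt, tr$a0)
                p <- anisotropic_params(A_par = spl$A_par, A_perp = spl$A_perp)
                sp <- simulate_anisotropic(p, grid, md)
                tru <- data.frame(S_true = tr$S * jt, tau2B_true = NA,
                                  tau2C_true = NA, deltaH0_true = NA)
              } else {
                wB <- -(tr$tau2B * jt) / (6.51e-10 * 20)
                wC <- (tr$tau2C * jt) / (6.51e-10 * 20)
                p <- fast_motion_params(width_A = tr$deltaH0, width_B = wB,
                                        width_C = wC)
                sp <- simulate_fast_motion(p, grid, md)
                tru <- data.frame(S_true = NA, tau2B_true = tr$tau2B * jt,
                                  tau2C_true = tr$tau2C * jt,
                                  deltaH0_true = tr$deltaH0)
              }
              peak <- max(abs(sp$intensity))
              sp$intensity <- sp$intensity +
                stats::rnorm(length(sp$intensity), sd = peak / snr)
              k <- length(spectra) + 1L
              spectra[[k]] <- sp
              truth[[k]] <- cbind(data.frame(spin_label = lbl,
                                             genotype = gt,
                                             growth_temperature_C = gw,
                                             measurement_temperature_C = tm,
                                             bio_rep = b, tech_rep = tech),
                                  tru)
            }
          }
        }
      }
    }
  }
  list(spectra = spectra, truth = do.call(rbind, truth))
}

extract_dispatch <- function(spectrum, options) {
  lbl <- spectrum$metadata$spin_label
  if (identical(lbl, "5-SASL")) {
    extract_anisotropic_features(spectrum, options)
  } else {
    extract_fast_motion_features(spectrum, options)
  }
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the experiment's spectra, extracts spectral features
#' per spin label, computes the membrane-dynamics quantities, aggregates
#' replicates into per-temperature mean +- SE series, and compares the two
#' genotypes at every shared measurement temperature with a pooled-variance
#' Student's t-test. Deterministic given `config$seed`. When
#' `config$output_dir` is set, writes `features.csv`, `dynamics.csv`,
#' `series_summary.csv`, `comparisons.csv` and a `run_config.json` audit
#' record of every setting in effect.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with elements `features`, `dynamics`,
#'   `summaries`, `comparisons`, `truth`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input_dir)) {
    files <- list.files(config$input_dir, full.names = TRUE)
    if (length(files) == 0L) {
      stop("no input spectra found in '", config$input_dir,
           "'; expected files readable by read_spectrum()")
    }
    spectra <- lapply(files, read_spectrum)
    truth <- NULL
  } else {
    sim <- simulate_experiment(config)
    spectra <- sim$spectra
    truth <- sim$truth
  }
  feats <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    f <- tryCatch(extract_dispatch(sp, config$extraction),
                  error = function(e) {
                    warning("spectrum ", i, " failed extraction: ",
                            conditionMessage(e))
                    features_row()
                  })
    md <- sp$metadata
    cbind(data.frame(
      spin_label = md$spin_label %||% NA_character_,
      genotype = md$genotype %||% NA_character_,
      growth_temperature_C = md$growth_temperature_C %||% NA_real_,
      measurement_temperature_C = md$measurement_temperature_C %||% NA_real_,
      replicate_id = md$replicate_id %||% NA_character_), f)
  })
  features <- do.call(rbind, feats)
  dynamics <- dynamics_table(features, config$delta_h0_unit)
  # Exclude flagged S from downstream statistics.
  dynamics$S[which(dynamics$flag_S_out_of_range)] <- NA
  dynamics$bio_rep <- sub("t\\d+$", "", dynamics$replicate_id)

  metrics <- c("S", "deltaH0_mT", "tau2B_s", "tau2C_s")
  summaries <- list()
  comparisons <- list()
  for (gw in unique(dynamics$growth_temperature_C)) {
    for (lbl in unique(dynamics$spin_label)) {
      sub <- dynamics[dynamics$growth_temperature_C == gw &
                        dynamics$spin_label == lbl, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (m in metrics) {
        if (all(is.na(sub[[m]]))) next
        for (gt in config$genotypes) {
          d <- sub[sub$genotype == gt & !is.na(sub[[m]]), , drop = FALSE]
          if (nrow(d) == 0L) next
          agg <- aggregate_replicates(d, m, "measurement_temperature_C", "bio_rep")
          agg <- cbind(data.frame(genotype = gt, growth_temperature_C = gw,
                                  spin_label = lbl, metric = m), agg)
          summaries[[length(summaries) + 1L]] <- agg
        }
        a <- sub[sub$genotype == config$genotypes[1L], , drop = FALSE]
        b <- sub[sub$genotype == config$genotypes[2L], , drop = FALSE]
        # Bio-replicate means are the statistical units of the comparison.
        abio <- aggregate_bio(a, m)
        bbio <- aggregate_bio(b, m)
        cmp <- tryCatch(
          compare_genotypes(abio, bbio, value = "value",
                            temperature = "measurement_temperature_C",
                            alpha = config$alpha),
          error = function(e) NULL)
        if (!is.null(cmp)) {
          comparisons[[length(comparisons) + 1L]] <-
            cbind(data.frame(growth_temperature_C = gw, spin_label = lbl,
                             metric = m), cmp)
        }
      }
    }
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL
  result <- list(features = features, dynamics = dynamics,
                 summaries = summaries, comparisons = comparisons,
                 truth = truth, config = config)
  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-(bio, temperature) means with technical replicates averaged first.
aggregate_bio <- function(d, metric) {
  d <- d[!is.na(d[[metric]]), , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(measurement_temperature_C = numeric(0), value = numeric(0)))
  }
  key <- interaction(d$measurement_temperature_C, d$bio_rep, drop = TRUE)
  vals <- vapply(split(d[[metric]], key), mean, 0)
  temps <- vapply(split(d$measurement_temperature_C, key), `[`, 0, 1L)
  data.frame(measurement_temperature_C = unname(temps), value = unname(vals))
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(result$config$output_dir, name)
  utils::write.csv(result$features, out("features.csv"), row.names = FALSE)
  utils::write.csv(result$dynamics, out("dynamics.csv"), row.names = FALSE)
  if (!is.null(result$summaries)) {
    utils::write.csv(result$summaries, out("series_summary.csv"), row.names = FALSE)
  }
  if (!is.null(result$comparisons)) {
    utils::write.csv(result$comparisons, out("comparisons.csv"), row.names = FALSE)
  }
  audit <- result$config
  audit$extraction <- unclass(audit$extraction)
  jsonlite::write_json(unclass(audit), out("run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(NULL)
}
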