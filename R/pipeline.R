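# Pipeline orchestration: a validated run configuration, stage dispatch,
# and comparison of recovered vs predicted distance distributions. A thin
# command-line wrapper over these functions ships in inst/scripts.

.known_stages <- c("simulate", "invert_deer", "lfpr", "predict_distances",
                   "compare")

.default_config <- function() {
  list(
    stages = character(0),
    seed = 1L,
    simulate = list(kind = "deer"),
    invert_deer = list(trace = NULL, r_min = 1.5, r_max = 8, n_points = 128,
                       fit_start_fraction = 0.55, validate = FALSE,
                       n_backgrounds = 5, n_noise = 5),
    lfpr = list(spectrum = NULL, reference = NULL, smooth = FALSE),
    predict_distances = list(pdb = NULL, site_a = NULL, site_b = NULL,
                             cutoff = 0.15, label_sigma = 0.25,
                             n_draws = 200),
    compare = list()
  )
}

#' Validate and resolve a pipeline run configuration
#'
#' Merges a user configuration (list, or path to a JSON file) over the
#' package defaults and checks stage names and parameter keys against the
#' schema; unknown keys are an error.
#'
#' @param config list or JSON file path
#' @return resolved configuration list
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  def <- .default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]])) {
      badk <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(badk)) stop(sprintf("unknown keys in config$%s: %s", nm,
                                     paste(badk, collapse = ", ")))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else def[[nm]] <- config[[nm]]
  }
  unknown <- setdiff(def$stages, .known_stages)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  def
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a validated configuration.
#' `simulate` generates synthetic inputs (DEER trace, CW spectrum pair, or
#' helix ensemble); `invert_deer` recovers P(r) from the trace;
#' `lfpr` computes the mobility statistic for a spectrum/reference pair;
#' `predict_distances` predicts P(r) from a conformer ensemble; `compare`
#' computes the overlap integral between the recovered and predicted
#' distributions. With an output directory, every stage writes its results
#' as TSV/JSON and the resolved configuration is saved next to them. An
#' empty stage list just validates the configuration.
#'
#' @param config list or JSON path, see [resolve_config()]
#' @param out output directory (NULL: nothing written)
#' @return named list of stage results (invisibly the resolved config under
#'   `$config`)
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(cfg, file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res <- list(config = cfg)
  for (stage in cfg$stages) {
    res[[stage]] <- switch(stage,
      simulate = .stage_simulate(cfg, out),
      invert_deer = .stage_invert(cfg, res, out),
      lfpr = .stage_lfpr(cfg, res, out),
      predict_distances = .stage_predict(cfg, res, out),
      compare = .stage_compare(res, out))
  }
  res
}

.stage_simulate <- function(cfg, out) {
  p <- cfg$simulate
  switch(p$kind,
    deer = make_deer_dataset(deer_ground_truth(seed = cfg$seed),
                             dir = if (is.null(out)) NULL else
                               file.path(out, "simulate")),
    cw = {
      d <- if (is.null(out)) NULL else file.path(out, "simulate")
      sample <- make_cw_spectrum(cw_ground_truth(immobilized_fraction = 0.5,
                                                 noise_sigma = 0.005,
                                                 seed = cfg$seed), dir = d)
      reference <- make_cw_spectrum(cw_ground_truth(immobilized_fraction = 0,
                                                    noise_sigma = 0.005,
                                                    seed = cfg$seed + 1L))
      if (!is.null(d)) write_cw_spectrum(reference,
                                         file.path(d, "reference.dat"))
      list(sample = sample, reference = reference)
    },
    helix = {
      e <- make_helix_ensemble(seed = cfg$seed)
      if (!is.null(out)) {
        dir.create(file.path(out, "simulate"), showWarnings = FALSE,
                   recursive = TRUE)
        write_ensemble_pdb(e, file.path(out, "simulate", "ensemble.pdb"))
      }
      e
    },
    stop("unknown simulate kind: ", p$kind))
}

.stage_invert <- function(cfg, res, out) {
  p <- cfg$invert_deer
  trace <- if (!is.null(p$trace)) read_deer_trace(p$trace)
           else if (!is.null(res$simulate$trace)) res$simulate$trace
           else stop("invert_deer: no trace file configured and none simulated")
  r <- distance_grid(p$r_min, p$r_max, p$n_points)
  inv <- invert_deer(trace, r, fit_start_fraction = p$fit_start_fraction)
  if (isTRUE(p$validate))
    inv <- validate_uncertainty(inv, p$n_backgrounds, p$n_noise,
                                seed = cfg$seed)
  if (!is.null(out)) {
    d <- inv$distribution
    tab <- data.frame(r_nm = d$r, p = d$p,
                      band_low = if (is.null(inv$band_low)) NA else inv$band_low,
                      band_high = if (is.null(inv$band_high)) NA else inv$band_high)
    utils::write.table(tab, file.path(out, "distribution.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(inv$lcurve))
      utils::write.table(inv$lcurve, file.path(out, "lcurve.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(alpha = inv$alpha, lambda = inv$lambda,
                              k = inv$bg$k, d = inv$bg$d, noise = inv$noise),
                         file.path(out, "inversion.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  inv
}

.stage_lfpr <- function(cfg, res, out) {
  p <- cfg$lfpr
  sample <- if (!is.null(p$spectrum)) read_cw_spectrum(p$spectrum)
            else if (!is.null(res$simulate$sample)) res$simulate$sample
            else stop("lfpr: no spectrum configured and none simulated")
  reference <- if (!is.null(p$reference)) read_cw_spectrum(p$reference)
               else if (!is.null(res$simulate$reference)) res$simulate$reference
               else stop("lfpr: no reference spectrum available")
  ans <- lfpr_analysis(sample, reference, smooth = isTRUE(p$smooth))
  if (!is.null(out))
    jsonlite::write_json(ans, file.path(out, "lfpr.json"), auto_unbox = TRUE,
                         digits = NA)
  ans
}

.stage_predict <- function(cfg, res, out) {
  p <- cfg$predict_distances
  ens <- if (!is.null(p$pdb)) read_ensemble_pdb(p$pdb)
         else if (inherits(res$simulate, "conformer_ensemble")) res$simulate
         else stop("predict_distances: no PDB configured and no ensemble simulated")
  sites <- if (!is.null(p$site_a)) c(p$site_a, p$site_b) else {
    rs <- ens$residues; c(rs[5], rs[min(length(rs), 35)])
  }
  pred <- predict_distances(ens, sites[1], sites[2], cutoff = p$cutoff,
                            label_sigma = p$label_sigma, n_draws = p$n_draws,
                            seed = cfg$seed)
  if (!is.null(out)) {
    tab <- data.frame(r_nm = pred$distribution$r, p = pred$distribution$p,
                      band_low = pred$band_low, band_high = pred$band_high)
    utils::write.table(tab, file.path(out, "prediction.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  pred
}

.stage_compare <- function(res, out) {
  if (is.null(res$invert_deer) || is.null(res$predict_distances))
    stop("compare requires the invert_deer and predict_distances stages")
  ov <- distribution_overlap(res$invert_deer$distribution,
                             res$predict_distances$distribution)
  if (!is.null(out))
    jsonlite::write_json(list(overlap = ov), file.path(out, "compare.json"),
                         auto_unbox = TRUE, digits = NA)
  ov
}
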