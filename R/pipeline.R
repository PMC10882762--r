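# End-to-end pipeline: entropy/CHRDI -> DEA bootstrap -> quadrants ->
# Moran -> SDM + impacts, with cached per-stage CSV outputs and a manifest.

#' Assemble a pipeline configuration
#'
#' @param panel_path CSV of the long indicator panel.
#' @param coords_path CSV of unit coordinates.
#' @param out_dir output directory (created if absent).
#' @param resource_indicators indicators entering the entropy/CHRDI stage.
#' @param dea_inputs,dea_outputs indicator names for the DEA stage.
#' @param covariates extra regressor indicator names for the SDM stage
#'   (CHRDI is always the first regressor).
#' @param planar_coords logical, see [coordinate_table()].
#' @param entropy_mode `"per_year"` or `"pooled"`; `zero_shift` see
#'   [entropy_weights()].
#' @param rts,B,level DEA options; `weights_standardization` (`"row"` or
#'   `"none"`) applies to the Moran/SDM weight matrix.
#' @param moran_method,moran_nsim,alpha Moran options.
#' @param effects,impact_sims SDM options.
#' @param seed global seed; stages derive independent seeds from it by
#'   fixed offsets so each stage is reproducible in isolation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_path, coords_path, out_dir,
                            resource_indicators, dea_inputs, dea_outputs,
                            covariates = character(),
                            planar_coords = FALSE,
                            entropy_mode = "per_year", zero_shift = 0,
                            rts = "vrs", B = 2000, level = 0.95,
                            weights_standardization = "row",
                            moran_method = "randomization",
                            moran_nsim = 999, alpha = 0.05,
                            effects = "unit", impact_sims = 1000,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose fields match [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

stage_seed <- function(cfg, offset) as.integer(cfg$seed) + offset

#' Run the allocation-efficiency pipeline
#'
#' Executes entropy weighting -> CHRDI -> bootstrap DEA -> quadrant
#' classification -> global/local Moran -> SDM with impacts, writing one
#' CSV per stage plus a JSON manifest and a run log to `cfg$out_dir`.
#' Stages can be re-run individually from the cached CSVs of earlier
#' stages via `stages`.
#'
#' @param cfg a `pipeline_config`.
#' @param stages subset of `c("chrdi", "dea", "quadrant", "moran", "sdm")`
#'   to (re)run; earlier stages must have cached outputs in `out_dir`.
#' @return invisibly, a named list of the stage outputs.
#' @export
run_pipeline <- function(cfg, stages = c("chrdi", "dea", "quadrant",
                                         "moran", "sdm")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "|", ..., "\n",
        file = log_path, append = TRUE)
  }
  outfile <- function(nm) file.path(cfg$out_dir, nm)
  fail <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               outfile("FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  if (file.exists(outfile("FAILED"))) unlink(outfile("FAILED"))
  panel <- read_indicator_panel(cfg$panel_path)
  coords <- read_coordinates(cfg$coords_path, planar = cfg$planar_coords)
  W <- inverse_distance_weights(coords,
                                standardization =
                                  cfg$weights_standardization)
  res <- list()
  t0 <- proc.time()[3]

  if ("chrdi" %in% stages) {
    tryCatch({
      ch <- chrdi_series(panel, cfg$resource_indicators,
                         mode = cfg$entropy_mode,
                         zero_shift = cfg$zero_shift)
      write.csv(ch, outfile("chrdi.csv"), row.names = FALSE)
      write.csv(attr(ch, "weights"), outfile("entropy_weights.csv"),
                row.names = FALSE)
      # downstream stages consume the CSV (not the in-memory copy) so that
      # cached re-runs are bit-identical to full runs
      res$chrdi <- read.csv(outfile("chrdi.csv"))
      logline("stage=chrdi", "rows=", nrow(ch),
              "elapsed=", round(proc.time()[3] - t0, 2))
    }, error = function(e) fail("chrdi", e))
  } else res$chrdi <- read.csv(outfile("chrdi.csv"))

  if ("dea" %in% stages) {
    tryCatch({
      eff <- efficiency_panel(panel, cfg$dea_inputs, cfg$dea_outputs,
                              rts = cfg$rts, B = cfg$B, level = cfg$level,
                              seed = stage_seed(cfg, 100L))
      write.csv(eff, outfile("efficiency.csv"), row.names = FALSE)
      res$efficiency <- read.csv(outfile("efficiency.csv"))
      logline("stage=dea", "B=", cfg$B, "rts=", cfg$rts,
              "elapsed=", round(proc.time()[3] - t0, 2))
    }, error = function(e) fail("dea", e))
  } else res$efficiency <- read.csv(outfile("efficiency.csv"))

  if ("quadrant" %in% stages) {
    tryCatch({
      qd <- do.call(rbind, lapply(sort(unique(res$chrdi$year)),
                                  function(yr) {
        ch <- res$chrdi[res$chrdi$year == yr, ]
        ef <- res$efficiency[res$efficiency$year == yr, ]
        q <- quadrant_classify(setNames(ch$chrdi, ch$unit_id),
                               setNames(ef$corrected, ef$unit_id))
        data.frame(unit_id = names(q), year = yr,
                   quadrant = as.character(q))
      }))
      write.csv(qd, outfile("quadrants.csv"), row.names = FALSE)
      res$quadrants <- qd
      logline("stage=quadrant", "elapsed=",
              round(proc.time()[3] - t0, 2))
    }, error = function(e) fail("quadrant", e))
  } else if (file.exists(outfile("quadrants.csv")))
    res$quadrants <- read.csv(outfile("quadrants.csv"))

  if ("moran" %in% stages) {
    tryCatch({
      yrs <- sort(unique(res$efficiency$year))
      gl <- do.call(rbind, lapply(yrs, function(yr) {
        ef <- res$efficiency[res$efficiency$year == yr, ]
        x <- setNames(ef$corrected, ef$unit_id)[W$ids]
        mt <- moran_test(x, W, method = cfg$moran_method,
                         nsim = cfg$moran_nsim,
                         seed = stage_seed(cfg, 200L))
        data.frame(year = yr, I = mt$I, expected = mt$expected,
                   sd = mt$sd, z = mt$z, p = mt$p)
      }))
      lo <- do.call(rbind, lapply(yrs, function(yr) {
        ef <- res$efficiency[res$efficiency$year == yr, ]
        x <- setNames(ef$corrected, ef$unit_id)[W$ids]
        lm_ <- local_moran(x, W, alpha = cfg$alpha,
                           nsim = cfg$moran_nsim,
                           seed = stage_seed(cfg, 300L))
        cbind(year = yr, lm_)
      }))
      write.csv(gl, outfile("moran_global.csv"), row.names = FALSE)
      write.csv(lo, outfile("moran_local.csv"), row.names = FALSE)
      res$moran_global <- gl
      res$moran_local <- lo
      logline("stage=moran", "method=", cfg$moran_method,
              "elapsed=", round(proc.time()[3] - t0, 2))
    }, error = function(e) fail("moran", e))
  }

  if ("sdm" %in% stages) {
    tryCatch({
      key <- function(d) paste(d$unit_id, d$year)
      md <- data.frame(unit_id = res$efficiency$unit_id,
                       year = res$efficiency$year,
                       efficiency = res$efficiency$corrected,
                       chrdi = res$chrdi$chrdi[match(key(res$efficiency),
                                                     key(res$chrdi))])
      regs <- "chrdi"
      for (cv in cfg$covariates) {
        sub <- panel[panel$indicator == cv, ]
        md[[cv]] <- sub$value[match(key(md), key(sub))]
        regs <- c(regs, cv)
      }
      fit <- fit_sdm(md, "efficiency", regs, W, effects = cfg$effects)
      imp <- sdm_impacts(fit, nsim = cfg$impact_sims,
                         seed = stage_seed(cfg, 400L))
      coefs <- data.frame(term = c(names(fit$coefficients), "rho"),
                          estimate = c(fit$coefficients, fit$rho),
                          se = sqrt(diag(fit$vcov)))
      coefs$z <- coefs$estimate / coefs$se
      coefs$p <- 2 * pnorm(-abs(coefs$z))
      write.csv(coefs, outfile("sdm_coefficients.csv"), row.names = FALSE)
      write.csv(cbind(term = rownames(imp), imp), outfile("sdm_impacts.csv"),
                row.names = FALSE)
      res$sdm <- fit
      res$impacts <- imp
      logline("stage=sdm", "rho=", round(fit$rho, 4),
              "elapsed=", round(proc.time()[3] - t0, 2))
    }, error = function(e) fail("sdm", e))
  }

  manifest <- list(package_version = as.character(utils::packageVersion(
                     "phceff")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   options = cfg[setdiff(names(cfg),
                                         c("panel_path", "coords_path",
                                           "out_dir"))],
                   stages_run = stages,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(res)
}
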