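# Configuration loading (closed schema), result serialization, the
# synthetic biodistribution fixture generator and the correlation-based
# validation workflow.

config_schema <- list(
  nanoparticle = c("diameter_nm", "radius_nm", "density_g_cm3",
                   "k_deg_per_h"),
  body = c("BW_g", "CO_ml_h", "GFR_ml_h", "urine_ml_h", "bile_ml_h",
           "hematocrit", "lymph_ratio"),
  tumor = c("enabled", "radius_mm", "Q_specific_ml_g_min", "mu_cP", "f_v",
            "r_pore_nm", "phi", "l_w_um"),
  simulation = c("dose", "t_end_h", "rtol", "atol", "n_grid"),
  sensitivity = c("n", "replicates", "n_levels", "n_bins"),
  seed = NULL
)

#' Load and resolve a run configuration
#'
#' Reads a YAML or JSON configuration, validates it against the closed
#' schema (unknown keys are rejected) and applies the reference defaults
#' for everything left unset.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or a list already
#'   in config shape.
#' @return Resolved config of class `run_config`: list with `np`
#'   ([nanoparticle()]), `body` ([default_body()]), `tumor`
#'   ([default_tumor()] or `NULL`), `sim` ([sim_config()]),
#'   `sensitivity` (list), `seed`, and `raw` (the input after defaults).
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()

  bad_top <- setdiff(names(cfg), names(config_schema))
  if (length(bad_top))
    stop("unknown config keys: ", paste(bad_top, collapse = ", "),
         call. = FALSE)
  for (sect in names(config_schema)) {
    allowed <- config_schema[[sect]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sect]]), allowed)
    if (length(bad))
      stop("unknown keys in `", sect, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }

  npc <- cfg$nanoparticle
  np <- nanoparticle(
    diameter_nm = if (is.null(npc$radius_nm))
      npc$diameter_nm %||% 100 else NULL,
    radius_nm = npc$radius_nm,
    density_g_cm3 = npc$density_g_cm3 %||% 2,
    k_deg_per_h = npc$k_deg_per_h %||% 0.01
  )

  bc <- cfg$body
  body <- default_body()
  if (!is.null(bc$BW_g)) body$BW <- bc$BW_g
  if (!is.null(bc$CO_ml_h)) body$CO <- bc$CO_ml_h
  if (!is.null(bc$GFR_ml_h)) body$GFR <- bc$GFR_ml_h
  if (!is.null(bc$urine_ml_h)) body$U <- bc$urine_ml_h
  if (!is.null(bc$bile_ml_h)) body$B <- bc$bile_ml_h
  if (!is.null(bc$hematocrit)) body$H <- bc$hematocrit
  if (!is.null(bc$lymph_ratio)) body$lymph_ratio <- bc$lymph_ratio

  tc <- cfg$tumor
  tumor <- if (isFALSE(tc$enabled)) NULL else {
    args <- if (is.null(tc)) list() else tc[setdiff(names(tc), "enabled")]
    do.call(default_tumor, args)
  }

  sc <- cfg$simulation
  sim <- sim_config(dose = sc$dose %||% 100, t_end = sc$t_end_h %||% 1000,
                    rtol = sc$rtol %||% 1e-8, atol = sc$atol %||% 1e-10)

  sens <- list(n = cfg$sensitivity$n %||% 5000,
               replicates = cfg$sensitivity$replicates %||% 10,
               n_levels = cfg$sensitivity$n_levels %||% 1000,
               n_bins = cfg$sensitivity$n_bins %||% 4)

  structure(list(np = np, body = body, tumor = tumor, sim = sim,
                 sensitivity = sens, seed = cfg$seed %||% 1,
                 raw = cfg), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation results to tidy CSV plus a JSON sidecar
#'
#' The CSV holds one row per (time, compartment, sub-compartment), sorted
#' deterministically; the JSON sidecar carries the headline AUC aggregates
#' and solver diagnostics. The round trip through [read_results()] is
#' lossless to full double precision.
#'
#' @param result [pbpk_simulate()] result.
#' @param csv_path Output CSV path.
#' @param json_path Output JSON sidecar path (default: CSV path with a
#'   `.json` extension).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  st <- result$states
  nm <- colnames(st)
  comp <- sub("\\..*$", "", nm)
  sub_c <- ifelse(grepl("\\.", nm), sub("^.*\\.", "", nm), "total")
  df <- data.frame(
    time_h = rep(result$times, times = length(nm)),
    compartment = rep(comp, each = length(result$times)),
    subcompartment = rep(sub_c, each = length(result$times)),
    percent_id = as.vector(st)
  )
  df <- df[order(df$time_h, df$compartment, df$subcompartment), ]
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   csv_path, row.names = FALSE, quote = FALSE)
  agg <- aggregate_outputs(result)
  jsonlite::write_json(
    list(aggregates = agg[c("plasma", "mps", "tumor", "excreta")],
         per_compartment = as.list(agg$per_compartment),
         diagnostics = result$diagnostics),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read back a tidy results CSV
#'
#' @param csv_path Path written by [write_results()].
#' @return Data frame with `time_h`, `compartment`, `subcompartment`,
#'   `percent_id`.
#' @export
read_results <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  df$time_h <- as.numeric(df$time_h)
  df$percent_id <- as.numeric(df$percent_id)
  df
}

#' Generate a synthetic biodistribution fixture
#'
#' Simulates the tumor-free model, converts organ totals into
#' imaging-style concentrations (%ID per gram of tissue, summing all
#' sub-compartments of an organ — imaging cannot distinguish them), and
#' applies multiplicative lognormal noise with the requested coefficient
#' of variation to emulate replicate animals. This is a synthetic stand-in
#' with the *structure* of an in vivo biodistribution study; it carries no
#' real data.
#'
#' @param np [nanoparticle()] specification.
#' @param body [default_body()] specification.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param timepoints Sampling times (h).
#' @param n_reps Replicates ("animals") per time point.
#' @param seed RNG seed.
#' @return Object of class `biodistribution_obs`: data frame with
#'   `organ`, `time_h`, `mean`, `sd`, `n` (%ID g^-1), plus attribute
#'   `predicted` (the noiseless concentrations).
#' @export
generate_fixture <- function(np, body = default_body(), noise_cv = 0.2,
                             timepoints = c(0.5, 1, 2, 4, 8, 24),
                             n_reps = 4, seed = 1) {
  stopifnot(noise_cv >= 0, n_reps >= 1)
  cfg <- sim_config(t_end = max(timepoints),
                    times = sort(unique(c(0, timepoints))))
  res <- pbpk_simulate(np, body, tumor = NULL, config = cfg)
  organs <- res$params$organs$name
  mass <- res$params$organs$V_total        # unit tissue density: ml = g
  idx <- match(timepoints, res$times)
  pred <- res$totals[idx, organs, drop = FALSE] / rep(mass, each =
                                                        length(timepoints))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  for (oi in seq_along(organs)) {
    for (ti in seq_along(timepoints)) {
      mult <- if (noise_cv == 0) rep(1, n_reps)
      else stats::rlnorm(n_reps, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      reps <- pred[ti, oi] * mult
      rows[[length(rows) + 1]] <- data.frame(
        organ = organs[oi], time_h = timepoints[ti],
        mean = mean(reps), sd = stats::sd(reps), n = n_reps)
    }
  }
  obs <- do.call(rbind, rows)
  attr(obs, "predicted") <- pred
  class(obs) <- c("biodistribution_obs", "data.frame")
  obs
}

#' Correlate model predictions with observed biodistribution
#'
#' Pearson correlation between predicted and observed mean organ
#' concentrations (%ID g^-1) over all matched (organ, time) pairs, the
#' validation statistic of the correlation workflow.
#'
#' @param result [pbpk_simulate()] result (tumor-free).
#' @param obs Observations in the [generate_fixture()] schema (`organ`,
#'   `time_h`, `mean`).
#' @return Pearson correlation coefficient.
#' @export
correlate_predictions <- function(result, obs) {
  org_tab <- result$params$organs
  mass <- stats::setNames(org_tab$V_total, org_tab$name)  # unit density
  keep <- obs$organ %in% org_tab$name
  obs <- obs[keep, ]
  pred <- mapply(function(o, t) {
    y <- result$totals[, o]
    stats::approx(result$times, y, xout = t)$y / mass[[o]]
  }, obs$organ, obs$time_h)
  if (length(pred) < 3)
    stop("need at least 3 matched (organ, time) pairs", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(obs$mean) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(pred, obs$mean)
}
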