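#' Configuration for the full simulation study
#'
#' @param n_simulations Number of structural iterations of the model.
#' @param T_list Lag intervals (ms) at which functional/recruitment maps and
#'   motif censuses are built; small-world scores use `T_sw`.
#' @param T_sw Lag interval for the small-world analyses (default 25 ms).
#' @param n_null Null graphs per normalisation (default 20).
#' @param seed Master seed; per-simulation streams derive from it.
#' @param conn,params,cfg Model parameter objects.
#' @param include_double Run the paired double-strength arm (weight_scale 2 on
#'   the same topology draws).
#' @param include_inference Run the imaging-inference arm on binned model
#'   activity and its Poisson rate-matched surrogate.
#' @param include_voltage Record membrane potential in the first simulation
#'   and build the voltage-conditioned networks.
#' @param include_synaptic_sw Also score the synaptic graph against nulls (a
#'   self-normalisation control; ratios are ~1 by construction).
#' @param max_triplets,n_samples Coincidence-analysis sampling caps.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_simulations = 5, T_list = c(10, 25, 50), T_sw = 25,
                         n_null = 20, seed = 1L,
                         conn = connectivity_params(),
                         params = neuron_params(), cfg = sim_config(),
                         include_double = FALSE, include_inference = FALSE,
                         include_voltage = FALSE, include_synaptic_sw = FALSE,
                         max_triplets = 10000, n_samples = 1000) {
  structure(as.list(environment()), class = "study_config")
}

#' Run one structural iteration and its activity maps
#'
#' Builds a network, simulates a session, and derives the functional,
#' active-subnetwork and recruitment maps together with their headline
#' statistics (small-world scores at `T_sw`, motif censuses at each `T`,
#' recruitment density, coincidence comparison, dynamics summary).
#'
#' @param study A [study_config()].
#' @param sim_index Which simulation stream to run.
#' @return List with the raw objects and a `stats` list of scalars.
#' @export
run_one_simulation <- function(study, sim_index = 1L) {
  seed_i <- child_seed(study$seed, 100L, sim_index)
  sim <- run_simulation(study$conn, study$params, study$cfg, seed = seed_i,
                        record_voltage = isTRUE(study$include_voltage) &&
                          sim_index == 1L)
  net <- sim$net; raster <- sim$raster
  light <- isTRUE(study$light) # censuses only (used for the 2x contrast arm)
  func <- functional_network(raster, T = study$T_sw)
  recr <- recruitment_network(func, net)
  act <- active_subnetwork(net, raster)
  syn <- excitatory_graph(net)
  sw_func <- if (!light)
    small_world_scores(func, study$n_null, child_seed(seed_i, 1L)) else NULL
  sw_recr <- if (!light)
    small_world_scores(recr, study$n_null, child_seed(seed_i, 2L)) else NULL
  sw_act <- if (!light)
    small_world_scores(act, study$n_null, child_seed(seed_i, 3L),
                       paths = FALSE) else NULL
  sw_syn <- if (isTRUE(study$include_synaptic_sw) && !light)
    small_world_scores(syn, study$n_null, child_seed(seed_i, 4L)) else NULL
  census_syn <- directed_clustering(syn, binary = TRUE)
  census_T <- lapply(study$T_list, function(Tlag) {
    g <- if (Tlag == study$T_sw) recr else
      recruitment_network(functional_network(raster, T = Tlag), net)
    list(weighted = directed_clustering(g, binary = FALSE,
                                        perspective = "target"),
         binary = directed_clustering(g, binary = TRUE,
                                      perspective = "target"))
  })
  names(census_T) <- paste0("T", study$T_list)
  coin <- if (!light)
    coincidence_comparison(raster, net, max_triplets = study$max_triplets,
                           n_samples = study$n_samples,
                           seed = child_seed(seed_i, 5L)) else NULL
  dyn <- summarize_dynamics(raster, net = net, include_correlation = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else x
  out <- list(net = net, raster = raster, functional = func,
              recruitment = recr, active = act,
              voltage = sim$voltage,
              sw = list(functional = sw_func, recruitment = sw_recr,
                        active = sw_act, synaptic = sw_syn),
              census_synaptic = census_syn, census_recruitment = census_T,
              coincidence = coin, dynamics = dyn,
              stats = list(
                sw_functional = num_or_na(sw_func$small_world_ratio),
                sw_recruitment = num_or_na(sw_recr$small_world_ratio),
                path_recruitment = num_or_na(sw_recr$path_ratio),
                clust_recruitment = num_or_na(sw_recr$clustering_ratio),
                clust_active = num_or_na(sw_act$clustering_ratio),
                sw_synaptic = num_or_na(sw_syn$small_world_ratio),
                recruitment_density = graph_density(recr),
                rate_ratio = num_or_na(coin$rate_ratio),
                mean_abs_dt_fanin = num_or_na(coin$fan_in$mean_abs_dt),
                mean_abs_dt_conv = num_or_na(coin$convergence$mean_abs_dt),
                firing_rate = dyn$firing_rate_mean,
                participation = dyn$participation_per_epoch,
                branching = dyn$branching_coeff_median,
                presyn_spikes = dyn$presyn_spikes_mean),
              seed = seed_i)
  out
}

#' Run the complete simulation study
#'
#' Orchestrates `n_simulations` structural iterations and aggregates the
#' headline statistics; optionally adds the paired double-strength arm
#' (same topology seeds, `weight_scale = 2`, binary-census contrast), the
#' imaging-inference arm on 50 ms-binned model activity versus its Poisson
#' rate-matched surrogate, and the voltage-conditioned profile of the first
#' simulation. When `out_dir` is given, summary tables are written as CSV and
#' a JSON report alongside.
#'
#' @param study A [study_config()].
#' @param out_dir Optional output directory.
#' @return List of class `study_report` with per-simulation results and the
#'   aggregated `summary` table.
#' @export
run_full_study <- function(study = study_config(), out_dir = NULL) {
  stopifnot(inherits(study, "study_config"))
  sims <- lapply(seq_len(study$n_simulations), function(i)
    run_one_simulation(study, i))
  stats <- do.call(rbind, lapply(sims, function(s)
    as.data.frame(s$stats)))
  stats$simulation <- seq_len(nrow(stats))
  summary <- data.frame(
    statistic = setdiff(names(stats), "simulation"),
    mean = vapply(setdiff(names(stats), "simulation"),
                  function(v) mean(stats[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(setdiff(names(stats), "simulation"),
                function(v) stats::sd(stats[[v]], na.rm = TRUE), numeric(1)))
  censuses <- do.call(rbind, lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    do.call(rbind, lapply(names(s$census_recruitment), function(Tn) {
      g <- s$census_recruitment[[Tn]]$weighted$global
      b <- s$census_recruitment[[Tn]]$binary$global
      data.frame(simulation = i, T = Tn, motif = names(g),
                 coefficient = as.numeric(g), coefficient_binary = as.numeric(b))
    }))
  }))
  report <- list(sims = sims, stats = stats, summary = summary,
                 censuses = censuses, config = study)
  if (isTRUE(study$include_double)) {
    conn2 <- study$conn; conn2$weight_scale <- 2 * study$conn$weight_scale
    study2 <- study; study2$conn <- conn2
    study2$include_double <- FALSE; study2$include_voltage <- FALSE
    study2$light <- TRUE
    sims2 <- lapply(seq_len(study$n_simulations), function(i) {
      s <- run_one_simulation(study2, i) # same seed stream => same topology
      s[c("census_recruitment", "stats")]
    })
    report$double_strength <- list(
      sims = sims2,
      contrast = {
        Tn <- paste0("T", study$T_sw)
        pick <- function(ss, motif) vapply(ss, function(s)
          s$census_recruitment[[Tn]]$binary$global[[motif]], numeric(1))
        data.frame(simulation = seq_along(sims),
                   fan_in_1x = pick(sims, "fan_in"),
                   fan_in_2x = pick(sims2, "fan_in"),
                   fan_out_1x = pick(sims, "fan_out"),
                   fan_out_2x = pick(sims2, "fan_out"))
      })
  }
  if (isTRUE(study$include_inference)) {
    r1 <- sims[[1]]$raster
    ev_model <- events_from_raster(r1)
    ev_pois <- events_from_raster(
      poisson_rate_matched(r1, seed = child_seed(study$seed, 55L)))
    inf_model <- infer_functional_weights(ev_model,
                                          seed = child_seed(study$seed, 56L))
    inf_pois <- infer_functional_weights(ev_pois,
                                         seed = child_seed(study$seed, 57L))
    cl <- function(inf) {
      g <- threshold_graph(wdigraph(inf$weights, "inferred"), 0.95)
      weighted_clustering(g, binary = TRUE)$mean
    }
    report$inference <- list(model = inf_model, poisson = inf_pois,
                             clustering_model = cl(inf_model),
                             clustering_poisson = cl(inf_pois))
  }
  if (isTRUE(study$include_voltage) && !is.null(sims[[1]]$voltage)) {
    vb <- voltage_bins(sims[[1]]$voltage, sims[[1]]$raster)
    vnets <- voltage_conditioned_networks(sims[[1]]$voltage, sims[[1]]$raster,
                                          sims[[1]]$net, vb)
    report$voltage_profile <- list(
      bins = vb,
      clustering = vapply(vnets, function(g)
        weighted_clustering(g)$mean, numeric(1)))
  }
  class(report) <- "study_report"
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write study tables to disk
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$stats, file.path(out_dir, "per_simulation_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$censuses, file.path(out_dir, "motif_censuses.csv"),
                   row.names = FALSE)
  if (!is.null(report$double_strength))
    utils::write.csv(report$double_strength$contrast,
                     file.path(out_dir, "double_strength_contrast.csv"),
                     row.names = FALSE)
  json <- list(version = 1L,
               summary = stats::setNames(as.list(report$summary$mean),
                                         report$summary$statistic))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d simulations\n", length(x$sims)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
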