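#' Experiment configuration
#'
#' One validated container drives the three experiment drivers. Defaults are
#' annotated in the field docs: values carried over from the reference
#' configuration are tagged `[stated]`, values the reference leaves open are
#' tagged `[assumption]` and are logged at run start.
#'
#' @param n_tot total neuron budget. Default 135 `[assumption]` — a
#'   conventional size for kernel-quality comparisons; the image-task
#'   drivers use 200 by default (desk scale).
#' @param n_ens vector of ensemble sizes to sweep `[stated: 1,2,4,8,10]`.
#' @param seeds integer vector of weight-initialization trial seeds.
#' @param connectivity a [connectivity_spec()].
#' @param neuron a [neuron_params()].
#' @param encoder list: `r_max` (63.75 Hz `[stated]`), `T` (300 ms
#'   `[stated]`), `dt` (0.5 ms `[stated]`).
#' @param metrics list: `tau_filter` (30 ms `[stated]`), `n_samples` (20
#'   `[assumption]`, grid over (0, T]), `rel_tol` (1e-6 `[assumption]`),
#'   `tau_in` (5 ms `[stated]`), `jitter_sigma` (4 ms `[assumption]`).
#' @param sp_data list for the spike-pair suite and rank experiments:
#'   `n_pairs`, `channels`, `rate`, `distance_bins`, `m` (rank columns),
#'   `n_base` (distinct bases for generalization), `n_input_sets`.
#' @param image_data list for the clustered image task: `n_classes`,
#'   `per_cell`, `size`, `rot_deg`, `shift_px`, `noise_sd`.
#' @param readout a [readout_config()].
#' @param mlmr list: `enabled`, `x_f` (foreign percentage, 10 `[stated]`),
#'   `cd_clusters` (cluster count at which the clustered-division arm runs).
#' @param train_frac training fraction of the 60/40 split `[assumption]`.
#' @param data_seed seed of the data-generation stream (kept separate from
#'   the weight-trial seeds so all trials see the same inputs).
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(n_tot = 135,
                              n_ens = c(1, 2, 4, 8, 10),
                              seeds = 1:10,
                              connectivity = connectivity_preset("ti-alpha"),
                              neuron = neuron_params(),
                              encoder = list(),
                              metrics = list(),
                              sp_data = list(),
                              image_data = list(),
                              readout = readout_config(),
                              mlmr = list(),
                              train_frac = 0.6,
                              data_seed = 1) {
  merge_defaults <- function(given, defaults, path) {
    if (!is.list(given))
      stop_liquidens(sprintf("config error at '%s': must be a list", path),
                     "config_error")
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop_liquidens(sprintf("config error at '%s.%s': unknown field",
                             path, bad[1]), "config_error")
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    n_tot = n_tot, n_ens = n_ens, seeds = seeds,
    connectivity = connectivity, neuron = neuron,
    encoder = merge_defaults(encoder,
                             list(r_max = 63.75, T = 300, dt = 0.5),
                             "encoder"),
    metrics = merge_defaults(metrics,
                             list(tau_filter = 30, n_samples = 20,
                                  rel_tol = 1e-6, tau_in = 5,
                                  jitter_sigma = 4), "metrics"),
    sp_data = merge_defaults(sp_data,
                             list(n_pairs = 20, channels = 39, rate = 40,
                                  distance_bins = 4, m = 40, n_base = 5,
                                  n_input_sets = 5), "sp_data"),
    image_data = merge_defaults(image_data,
                                list(n_classes = 5, per_cell = 8, size = 16,
                                     rot_deg = 15, shift_px = 2,
                                     noise_sd = 20), "image_data"),
    readout = readout, mlmr = merge_defaults(mlmr,
                                             list(enabled = FALSE, x_f = 10,
                                                  cd_clusters = 4), "mlmr"),
    train_frac = train_frac, data_seed = data_seed
  )
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @export
validate_config <- function(cfg) {
  check <- function(ok, path, what) {
    if (!ok) stop_liquidens(sprintf("config error at '%s': %s", path, what),
                            "config_error")
  }
  check(is_count(cfg$n_tot, 2L), "n_tot", "integer >= 2 required")
  check(is.numeric(cfg$n_ens) && length(cfg$n_ens) >= 1 &&
          all(cfg$n_ens >= 1) && all(cfg$n_ens == round(cfg$n_ens)),
        "n_ens", "positive integers required")
  check(all(cfg$n_tot >= 2 * cfg$n_ens), "n_ens",
        "n_tot must be >= 2 * max(n_ens)")
  check(is.numeric(cfg$seeds) && length(cfg$seeds) >= 1, "seeds",
        "at least one seed required")
  check(inherits(cfg$connectivity, "connectivity_spec"), "connectivity",
        "connectivity_spec required")
  check(inherits(cfg$neuron, "neuron_params"), "neuron",
        "neuron_params required")
  check(cfg$encoder$r_max * cfg$encoder$dt / 1000 <= 1, "encoder.r_max",
        "r_max * dt must not exceed one spike per step")
  check(cfg$encoder$T > 0 && cfg$encoder$dt > 0, "encoder", "T, dt > 0")
  check(cfg$metrics$n_samples >= 1, "metrics.n_samples", ">= 1 required")
  check(cfg$train_frac > 0 && cfg$train_frac < 1, "train_frac",
        "must be in (0, 1)")
  check(inherits(cfg$readout, "readout_config"), "readout",
        "readout_config required")
  invisible(cfg)
}

#' @rdname experiment_config
#' @param cfg an `experiment_config`.
#' @export
config_hash <- function(cfg) {
  config_fingerprint(as.character(
    jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname experiment_config
#' @param path JSON file path.
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(
    n_tot = raw$n_tot, n_ens = raw$n_ens, seeds = raw$seeds,
    connectivity = do.call(connectivity_spec,
                           raw$connectivity[setdiff(names(raw$connectivity),
                                                    "p_in_i")]),
    neuron = do.call(neuron_params, raw$neuron),
    encoder = raw$encoder, metrics = raw$metrics, sp_data = raw$sp_data,
    image_data = raw$image_data,
    readout = do.call(readout_config, raw$readout),
    mlmr = raw$mlmr, train_frac = raw$train_frac, data_seed = raw$data_seed)
}

# Message every [assumption]-tagged default at run start.
log_assumptions <- function(cfg, verbose) {
  if (!verbose) return(invisible(NULL))
  message("[assumption] tau_mem_e/i = ", cfg$neuron$tau_mem_e, "/",
          cfg$neuron$tau_mem_i, " ms; e_exc/e_inh = ", cfg$neuron$e_exc, "/",
          cfg$neuron$e_inh, " mV; t_refrac_e/i = ", cfg$neuron$t_refrac_e,
          "/", cfg$neuron$t_refrac_i, " ms (borrowed formulation)")
  message("[assumption] jitter sigma = ", cfg$metrics$jitter_sigma,
          " ms; rank rel_tol = ", cfg$metrics$rel_tol,
          "; SP sample grid n = ", cfg$metrics$n_samples)
  message("[assumption] synthetic task scale: n_tot = ", cfg$n_tot,
          ", train_frac = ", cfg$train_frac)
  invisible(NULL)
}

result_table <- function(rows, cfg) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, class = c("result_table", "data.frame"),
            config_hash = config_hash(cfg),
            package_version = as.character(utils::packageVersion("liquidens")))
}

result_row <- function(experiment, n_ens, seed, metric, value) {
  data.frame(experiment = experiment, n_ens = n_ens, seed = seed,
             metric = metric, value = value)
}

#' Write / read a result table (CSV plus JSON metadata sidecar)
#'
#' @param x a result table from one of the experiment drivers.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @export
write_result_table <- function(x, path) {
  stopifnot(inherits(x, "result_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config_hash = attr(x, "config_hash"),
                            package_version = attr(x, "package_version")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Build a single- or multi-liquid topology under one interface.
build_topology <- function(n_tot, n_ens, spec, n_inputs, seed) {
  if (n_ens == 1) build_liquid(n_tot, spec, n_inputs, seed)
  else build_ensemble(n_tot, n_ens, spec, n_inputs, seed)
}

#' Pairwise-separation and rank experiment
#'
#' For every ensemble size and weight seed: builds the topology, drives it
#' with a fixed [gen_spike_pair_suite()] (the same suite for all topologies),
#' records the mean pairwise separation per distance bin, and measures
#' [separation_rank()] on `m` distinct Poisson inputs and
#' [generalization_rank()] on jittered replicas of `n_base` of them.
#'
#' @param cfg an [experiment_config()].
#' @param verbose log assumption-tagged defaults at run start.
#' @return a `result_table` with metrics `sp_pw_bin<k>`, `sep_rank`,
#'   `gen_rank`; rank rows carry one derived trial seed per
#'   (weight seed, input set).
#' @export
run_sp_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  log_assumptions(cfg, verbose)
  sp <- cfg$sp_data
  suite <- gen_spike_pair_suite(
    n_pairs = sp$n_pairs, duration = cfg$encoder$T, channels = sp$channels,
    rate = sp$rate, distance_bins = sp$distance_bins, dt = cfg$encoder$dt,
    seed = cfg$data_seed)
  T <- cfg$encoder$T
  times <- seq(T / cfg$metrics$n_samples, T,
               length.out = cfg$metrics$n_samples)
  # rank-experiment inputs: n_input_sets sets of m distinct Poisson trains
  input_sets <- lapply(seq_len(sp$n_input_sets), function(s) {
    lapply(seq_len(sp$m), function(i) {
      encode_channels(channel_stimulus(
        matrix(sp$rate * cfg$encoder$dt / 1000, sp$channels,
               round(T / cfg$encoder$dt)), dt = cfg$encoder$dt),
        seed = derive_seed(cfg$data_seed, 10000 + s * 1000 + i))
    })
  })
  rows <- list()
  for (ne in cfg$n_ens) {
    for (ws in cfg$seeds) {
      topo <- build_topology(cfg$n_tot, ne, cfg$connectivity, sp$channels,
                             derive_seed(ws, ne))
      # pairwise separation, one value per distance bin
      sp_by_bin <- tapply(
        vapply(suite$pairs, function(pr) {
          ru <- run_topo(topo, pr$u, T, cfg$encoder$dt, cfg$neuron)
          rv <- run_topo(topo, pr$v, T, cfg$encoder$dt, cfg$neuron)
          pairwise_separation(
            filtered_states(ru, times, cfg$metrics$tau_filter),
            filtered_states(rv, times, cfg$metrics$tau_filter))
        }, numeric(1)),
        factor(vapply(suite$pairs, function(pr) pr$bin, integer(1)),
               levels = seq_len(sp$distance_bins)), mean)
      for (b in seq_len(sp$distance_bins)) {
        rows[[length(rows) + 1L]] <- result_row(
          "sp", ne, ws, sprintf("sp_pw_bin%d", b), unname(sp_by_bin[b]))
      }
      for (s in seq_along(input_sets)) {
        trial_seed <- derive_seed(ws, 100 + s)
        rs <- separation_rank(topo, input_sets[[s]], t0 = T,
                              dt = cfg$encoder$dt, params = cfg$neuron,
                              tau_filter = cfg$metrics$tau_filter,
                              rel_tol = cfg$metrics$rel_tol)
        ra <- generalization_rank(topo, input_sets[[s]][seq_len(sp$n_base)],
                                  sigma = cfg$metrics$jitter_sigma, m = sp$m,
                                  t0 = T, dt = cfg$encoder$dt,
                                  params = cfg$neuron,
                                  tau_filter = cfg$metrics$tau_filter,
                                  rel_tol = cfg$metrics$rel_tol,
                                  seed = trial_seed)
        rows[[length(rows) + 1L]] <- result_row("sp", ne, trial_seed,
                                                "sep_rank", rs$rank)
        rows[[length(rows) + 1L]] <- result_row("sp", ne, trial_seed,
                                                "gen_rank", ra$rank)
      }
    }
  }
  result_table(rows, cfg)
}

run_topo <- function(topo, input, T, dt, params) {
  if (inherits(topo, "ensemble_topology"))
    run_ensemble(topo, input, T = T, dt = dt, params = params)
  else run_liquid(topo, input, T = T, dt = dt, params = params)
}

# Liquid state vectors (normalized excitatory counts) of every image of a
# clustered set through one topology; rows = images.
image_states <- function(topo, encoded, T, dt, params) {
  t(vapply(encoded, function(inp) {
    rec <- run_topo(topo, inp, T, dt, params)
    if (inherits(rec, "ensemble_spikes"))
      ensemble_state(rec, topo, T = T)
    else extract_state(rec, n_e = topo$n_e, T = T)
  }, numeric(total_n_e(topo))))
}

total_n_e <- function(topo) {
  if (inherits(topo, "ensemble_topology"))
    sum(vapply(topo$liquids, function(l) l$n_e, integer(1)))
  else topo$n_e
}

encode_image_set <- function(imgs, cfg) {
  lapply(seq_along(imgs$images), function(i) {
    encode_image_poisson(image_stimulus(imgs$images[[i]], T = cfg$encoder$T),
                         r_max = cfg$encoder$r_max, dt = cfg$encoder$dt,
                         seed = derive_seed(cfg$data_seed, 50000 + i))
  })
}

#' Discriminant-ratio sweep over ensemble sizes
#'
#' Encodes the synthetic clustered image set once, then for every ensemble
#' size and weight seed extracts liquid state vectors, computes `tr(S_w)`,
#' `tr(S_b)` and the discriminant ratio, and reports the saturation point
#' (see [dr_saturation_point()]).
#'
#' @inheritParams run_sp_experiment
#' @return a `result_table` with metrics `tr_sw`, `tr_sb`, `dr`; attribute
#'   `saturation` holds the saturation `n_ens` of the mean-DR curve.
#' @export
run_dr_sweep <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  log_assumptions(cfg, verbose)
  im <- cfg$image_data
  imgs <- gen_clustered_images(im$n_classes, im$per_cell, im$size,
                               im$rot_deg, im$shift_px, im$noise_sd,
                               seed = cfg$data_seed)
  encoded <- encode_image_set(imgs, cfg)
  rows <- list()
  for (ne in cfg$n_ens) {
    for (ws in cfg$seeds) {
      topo <- build_topology(cfg$n_tot, ne, cfg$connectivity, im$size^2,
                             derive_seed(ws, ne))
      st <- image_states(topo, encoded, cfg$encoder$T, cfg$encoder$dt,
                         cfg$neuron)
      sc <- scatter_matrices(st, imgs$labels)
      rows[[length(rows) + 1L]] <- result_row("dr", ne, ws, "tr_sw", sc$tr_sw)
      rows[[length(rows) + 1L]] <- result_row("dr", ne, ws, "tr_sb", sc$tr_sb)
      rows[[length(rows) + 1L]] <- result_row("dr", ne, ws, "dr",
                                              discriminant_ratio(sc))
    }
  }
  tab <- result_table(rows, cfg)
  dr_rows <- tab[tab$metric == "dr", ]
  mean_dr <- tapply(dr_rows$value, factor(dr_rows$n_ens, levels = cfg$n_ens),
                    mean)
  attr(tab, "saturation") <- dr_saturation_point(cfg$n_ens,
                                                 as.numeric(mean_dr))
  tab
}

#' Saturation point of a discriminant-ratio curve
#'
#' Operational definition of where the DR stops improving: the first ensemble
#' size after which the remaining gain (best later value minus the current
#' one) is below 5 percent of the total rise from the first value to the
#' maximum.
#'
#' @param n_ens ensemble sizes (ascending).
#' @param dr mean DR values aligned with `n_ens`.
#' @param gain_frac remaining-gain threshold as a fraction of total rise.
#' @return the saturation element of `n_ens`.
#' @export
dr_saturation_point <- function(n_ens, dr, gain_frac = 0.05) {
  stopifnot(length(n_ens) == length(dr), length(dr) >= 1)
  total_rise <- max(dr) - dr[1]
  if (total_rise <= 0) return(n_ens[1])
  for (k in seq_along(dr)) {
    remaining <- max(dr[k:length(dr)]) - dr[k]
    if (remaining < gain_frac * total_rise) return(n_ens[k])
  }
  n_ens[length(n_ens)]
}

# Stratified (by label) train/test split.
split_train_test <- function(labels, frac, seed) {
  with_seed(seed, {
    train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
      sample(idx, round(length(idx) * frac))
    }), use.names = FALSE)
    list(train = sort(train),
         test = setdiff(seq_along(labels), train))
  })
}

#' Accuracy sweep over ensemble sizes
#'
#' For every ensemble size and weight seed: simulates the encoded clustered
#' image set, performs a seeded stratified train/test split, trains the
#' shared readout on concatenated states (MLSR) and reports test accuracy and
#' connection counts. When `cfg$mlmr$enabled` and the ensemble size exceeds
#' 1, also runs the per-liquid readout arms: random training-space division
#' (RD) and — when the ensemble size equals the cluster count — clustered
#' division (CD) with the inhibition criterion, reporting their accuracies
#' and the realized foreign-instance fraction.
#'
#' @inheritParams run_sp_experiment
#' @return a `result_table` with metrics `mlsr_accuracy`,
#'   `connections_internal`, `connections_total`, and (MLMR arms)
#'   `mlmr_rd_accuracy`, `mlmr_cd_accuracy`, `foreign_fraction_pct`;
#'   attribute `peak_n_ens` reports the argmax of mean MLSR accuracy.
#' @export
run_accuracy_sweep <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  log_assumptions(cfg, verbose)
  im <- cfg$image_data
  imgs <- gen_clustered_images(im$n_classes, im$per_cell, im$size,
                               im$rot_deg, im$shift_px, im$noise_sd,
                               seed = cfg$data_seed)
  encoded <- encode_image_set(imgs, cfg)
  L <- im$n_classes
  split <- split_train_test(imgs$labels, cfg$train_frac, cfg$data_seed)
  rows <- list()
  for (ne in cfg$n_ens) {
    for (ws in cfg$seeds) {
      topo <- build_topology(cfg$n_tot, ne, cfg$connectivity, im$size^2,
                             derive_seed(ws, ne))
      cc <- count_connections(topo)
      # per-liquid state blocks, kept separate so the MLMR arms can reuse them
      blocks <- per_liquid_states(topo, encoded, cfg$encoder$T,
                                  cfg$encoder$dt, cfg$neuron)
      states <- do.call(cbind, blocks)
      rc <- cfg$readout
      rc$seed <- derive_seed(ws, 777)
      model <- train_readout(states[split$train, , drop = FALSE],
                             imgs$labels[split$train], L = L, config = rc)
      acc <- mean(predict(model,
                          states[split$test, , drop = FALSE])$class ==
                    imgs$labels[split$test])
      rows[[length(rows) + 1L]] <- result_row("accuracy", ne, ws,
                                              "mlsr_accuracy", acc)
      rows[[length(rows) + 1L]] <- result_row("accuracy", ne, ws,
                                              "connections_internal",
                                              cc$internal)
      rows[[length(rows) + 1L]] <- result_row("accuracy", ne, ws,
                                              "connections_total", cc$total)
      if (isTRUE(cfg$mlmr$enabled) && ne > 1) {
        mlmr <- run_mlmr_arms(blocks, imgs, split, L, ne, cfg, ws)
        for (nm in names(mlmr)) {
          rows[[length(rows) + 1L]] <- result_row("accuracy", ne, ws, nm,
                                                  mlmr[[nm]])
        }
      }
    }
  }
  tab <- result_table(rows, cfg)
  acc_rows <- tab[tab$metric == "mlsr_accuracy", ]
  mean_acc <- tapply(acc_rows$value,
                     factor(acc_rows$n_ens, levels = cfg$n_ens), mean)
  attr(tab, "peak_n_ens") <- cfg$n_ens[which.max(mean_acc)]
  tab
}

per_liquid_states <- function(topo, encoded, T, dt, params) {
  if (inherits(topo, "liquid_topology")) {
    return(list(t(vapply(encoded, function(inp) {
      extract_state(run_liquid(topo, inp, T = T, dt = dt, params = params),
                    n_e = topo$n_e, T = T)
    }, numeric(topo$n_e)))))
  }
  recs <- lapply(encoded, run_ensemble, ensemble = topo, T = T, dt = dt,
                 params = params)
  lapply(seq_along(topo$liquids), function(k) {
    t(vapply(recs, function(r) {
      extract_state(r[[k]], n_e = topo$liquids[[k]]$n_e, T = T)
    }, numeric(topo$liquids[[k]]$n_e)))
  })
}

# MLMR arms: RD always; CD when the ensemble size matches the cluster count.
run_mlmr_arms <- function(blocks, imgs, split, L, ne, cfg, ws) {
  out <- list()
  rc <- cfg$readout
  test_truth <- imgs$labels[split$test]
  predict_mlmr <- function(models) {
    fused <- vapply(seq_along(split$test), function(i) {
      scores <- lapply(seq_along(models), function(k) {
        predict(models[[k]],
                blocks[[k]][split$test[i], , drop = FALSE])$scores[1, ]
      })
      mlmr_classify(scores)
    }, integer(1))
    mean(fused == test_truth)
  }
  # random division
  div <- random_division(length(split$train), ne, derive_seed(ws, 31))
  rd_models <- lapply(seq_len(ne), function(k) {
    idx <- split$train[div[[k]]]
    rck <- rc
    rck$seed <- derive_seed(ws, 400 + k)
    train_readout(blocks[[k]][idx, , drop = FALSE], imgs$labels[idx], L = L,
                  config = rck)
  })
  out$mlmr_rd_accuracy <- predict_mlmr(rd_models)
  # clustered division with the inhibition criterion: one s-LSM per cluster
  n_clusters <- length(unique(imgs$clusters))
  if (ne == cfg$mlmr$cd_clusters && ne == n_clusters) {
    train_clusters <- imgs$clusters[split$train]
    cd <- clustered_division(imgs$labels[split$train], train_clusters, L = L,
                             x_f = cfg$mlmr$x_f, seed = derive_seed(ws, 32))
    cd_models <- lapply(seq_along(cd), function(k) {
      idx <- split$train[cd[[k]]$indices]
      rck <- rc
      rck$seed <- derive_seed(ws, 500 + k)
      train_readout(blocks[[k]][idx, , drop = FALSE], cd[[k]]$targets,
                    L = L, config = rck)
    })
    out$mlmr_cd_accuracy <- predict_mlmr(cd_models)
    out$foreign_fraction_pct <-
      100 * mean(vapply(cd, function(x) mean(x$foreign), numeric(1)))
  }
  out
}
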