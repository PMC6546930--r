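# Tiny configs keep these runs to seconds; the full-scale trend runs live in
# test-acceptance.R.
tiny_sp_cfg <- function() {
  experiment_config(n_tot = 24, n_ens = c(1, 2), seeds = 1:2,
                    sp_data = list(n_pairs = 4, channels = 6, m = 4,
                                   n_base = 2, n_input_sets = 2,
                                   distance_bins = 2))
}

tiny_img_cfg <- function(...) {
  experiment_config(n_tot = 40, n_ens = c(1, 2), seeds = 1:2,
                    connectivity = connectivity_spec(p_in_e = 30),
                    image_data = list(n_classes = 3, per_cell = 3, size = 10),
                    readout = readout_config(epochs = 25), ...)
}

test_that("experiment_config validates fields with a path in the message", {
  expect_error(experiment_config(n_tot = 1), class = "config_error")
  expect_error(experiment_config(n_ens = c(1, 500)), class = "config_error")
  expect_error(experiment_config(train_frac = 1.5), class = "config_error")
  expect_error(experiment_config(encoder = list(r_max = 9999)),
               class = "config_error")
  expect_error(experiment_config(encoder = list(bogus = 1)),
               class = "config_error")
  err <- tryCatch(experiment_config(train_frac = 2), condition = identity)
  expect_match(conditionMessage(err), "train_frac")
})

test_that("config round-trips through JSON with a stable hash", {
  cfg <- tiny_img_cfg()
  path <- tempfile(fileext = ".json")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_identical(config_hash(back), config_hash(cfg))
})

test_that("run_sp_experiment emits the combinatorial row structure", {
  cfg <- tiny_sp_cfg()
  tab <- run_sp_experiment(cfg)
  df <- as.data.frame(tab)
  sp_rows <- df[grepl("^sp_pw_bin", df$metric), ]
  # |n_ens| x |seeds| x bins rows of pairwise separation
  expect_identical(nrow(sp_rows), 2L * 2L * 2L)
  rank_rows <- df[df$metric %in% c("sep_rank", "gen_rank"), ]
  expect_identical(nrow(rank_rows), 2L * 2L * 2L * 2L) # x input sets x 2
  expect_true(all(rank_rows$value >= 0 & rank_rows$value <= 4)) # m = 4 columns
  # rerun with the same config is identical (hash-equal, value-equal)
  tab2 <- run_sp_experiment(cfg)
  expect_identical(attr(tab, "config_hash"), attr(tab2, "config_hash"))
  expect_equal(df, as.data.frame(tab2))
})

test_that("n_ens = 1 sweep contains only baseline rows", {
  cfg <- experiment_config(n_tot = 24, n_ens = 1, seeds = 1,
                           sp_data = list(n_pairs = 2, channels = 6, m = 3,
                                          n_base = 1, n_input_sets = 1,
                                          distance_bins = 1))
  tab <- run_sp_experiment(cfg)
  expect_true(all(as.data.frame(tab)$n_ens == 1))
})

test_that("run_dr_sweep matches a metrics-module recomputation", {
  cfg <- tiny_img_cfg()
  tab <- run_dr_sweep(cfg)
  df <- as.data.frame(tab)
  expect_identical(nrow(df), 2L * 2L * 3L) # n_ens x seeds x 3 metrics
  expect_true(attr(tab, "saturation") %in% cfg$n_ens)
  # independent recomputation of one cell from scratch
  im <- cfg$image_data
  imgs <- gen_clustered_images(im$n_classes, im$per_cell, im$size,
                               im$rot_deg, im$shift_px, im$noise_sd,
                               seed = cfg$data_seed)
  encoded <- lapply(seq_along(imgs$images), function(i) {
    encode_image_poisson(image_stimulus(imgs$images[[i]], T = cfg$encoder$T),
                         r_max = cfg$encoder$r_max, dt = cfg$encoder$dt,
                         seed = derive_seed(cfg$data_seed, 50000 + i))
  })
  topo <- build_liquid(cfg$n_tot, cfg$connectivity, im$size^2,
                       derive_seed(1, 1))
  states <- t(vapply(encoded, function(inp) {
    extract_state(run_liquid(topo, inp), n_e = topo$n_e)
  }, numeric(topo$n_e)))
  dr <- discriminant_ratio(scatter_matrices(states, imgs$labels))
  got <- df$value[df$n_ens == 1 & df$seed == 1 & df$metric == "dr"]
  expect_equal(got, dr, tolerance = 1e-12)
})

test_that("single-class data yields zero between-class scatter and DR", {
  cfg <- experiment_config(n_tot = 30, n_ens = 1, seeds = 1,
                           connectivity = connectivity_spec(p_in_e = 40),
                           image_data = list(n_classes = 3, per_cell = 2,
                                             size = 10))
  im <- cfg$image_data
  imgs <- gen_clustered_images(im$n_classes, im$per_cell, im$size, seed = 1)
  keep <- imgs$labels == 1
  encoded <- lapply(which(keep), function(i) {
    encode_image_poisson(image_stimulus(imgs$images[[i]]), seed = i)
  })
  topo <- build_liquid(30, cfg$connectivity, 100, seed = 2)
  states <- t(vapply(encoded, function(inp) {
    extract_state(run_liquid(topo, inp), n_e = topo$n_e)
  }, numeric(topo$n_e)))
  sc <- scatter_matrices(states, imgs$labels[keep])
  expect_equal(sc$tr_sb, 0)
})

test_that("run_accuracy_sweep reports accuracies, counts, and MLMR arms", {
  cfg <- experiment_config(n_tot = 40, n_ens = c(1, 4), seeds = 1:2,
                           connectivity = connectivity_spec(p_in_e = 30),
                           image_data = list(n_classes = 3, per_cell = 3,
                                             size = 10),
                           readout = readout_config(epochs = 25),
                           mlmr = list(enabled = TRUE, cd_clusters = 4))
  tab <- run_accuracy_sweep(cfg)
  df <- as.data.frame(tab)
  expect_true(all(c("mlsr_accuracy", "connections_internal",
                    "connections_total", "mlmr_rd_accuracy",
                    "mlmr_cd_accuracy", "foreign_fraction_pct") %in%
                    df$metric))
  acc <- df$value[df$metric == "mlsr_accuracy"]
  expect_true(all(acc >= 0 & acc <= 1))
  expect_true(attr(tab, "peak_n_ens") %in% cfg$n_ens)
  # foreign fraction at x_f = 10 with 4 clusters ~ 23% (up to rounding of
  # the per-cluster 10% draws on a small training set)
  ff <- df$value[df$metric == "foreign_fraction_pct"]
  expect_gt(length(ff), 0)
  expect_true(all(abs(ff - foreign_instance_fraction(4, 10)) < 2))
  # result table round-trips to CSV + sidecar
  path <- tempfile(fileext = ".csv")
  write_result_table(tab, path)
  back <- read.csv(path)
  expect_equal(back$value, df$value)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$config_hash, attr(tab, "config_hash"))
})

test_that("connection counts in the sweep scale as 1/n_ens", {
  cfg <- experiment_config(n_tot = 120, n_ens = c(1, 4), seeds = 1:3,
                           connectivity = connectivity_spec(p_in_e = 30),
                           image_data = list(n_classes = 2, per_cell = 2,
                                             size = 8),
                           readout = readout_config(epochs = 5))
  tab <- run_accuracy_sweep(cfg)
  df <- as.data.frame(tab)
  internal <- tapply(df$value[df$metric == "connections_internal"],
                     df$n_ens[df$metric == "connections_internal"], mean)
  expect_lt(abs(internal[["4"]] - internal[["1"]] / 4),
            0.15 * internal[["1"]] / 4)
})

test_that("the CLI driver runs end to end", {
  script <- system.file("cli", "liquidens", package = "liquidens")
  expect_true(nzchar(script))
  out_dir <- tempfile("cli")
  cfg_path <- tempfile(fileext = ".json")
  write_experiment_config(tiny_img_cfg(), cfg_path)
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(script, "dr-sweep", "--config", cfg_path, "--seed", "1",
                   "--out", out_dir, "--n-ens", "1"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out_dir, "dr_sweep_results.csv")))
})
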