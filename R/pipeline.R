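default_preprocess_opts <- function() {
  list(bleach_correct = TRUE, bg_radius_px = 15, denoise_sigma_px = 0.75,
       n_low_freq = 1)
}

default_sticcs_opts <- function() {
  list(modes = c("gfp_auto", "eb3_auto", "cross"),
       roi_size_px = 16, roi_shift_px = 4,
       toi_len_frames = 30, toi_shift_frames = 15,
       tau_max = 10, quality_min = 0.7, amp_min_frac = 0.1, min_lags = 6,
       cross_tau_max = 4, cross_min_lags = 3, cross_p0_radius = 4,
       cross_quality_min = 0.3,
       angle_max_deg = 45, mag_ratio_max = 2, min_similar_neighbors = 2,
       cross_min_similar = 1, speed_ratio_max = 3, min_contrast = 0.05,
       min_polymer = 0.14)
}

default_tracking_opts <- function() {
  list(enabled = TRUE, sigma_px = 1.5, quality_min = 0.3, max_link_px = 3,
       max_gap_frames = 2, max_gap_px = NULL, min_quality = 0,
       min_displacement_um = 0.1, min_frames = 3)
}

merge_opts <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  utils::modifyList(defaults, user)
}

#' Analyse one cell: preprocessing, STICCS and comet tracking
#'
#' Runs the complete single-cell analysis chain: photobleaching
#' correction, background subtraction and denoising on each channel;
#' comet tracking on the preprocessed EB3 channel; the temporal Fourier
#' immobile filter; STICCS vector fields with similarity filtering and
#' cross-event classification; and the per-cell summary.
#'
#' @param gfp,eb3 raw [image_series()] for the two channels (`gfp` may be
#'   NULL when only EB3 modes are requested).
#' @param mask optional [cell_mask()].
#' @param cell_id,condition identifiers for the summary row.
#' @param preprocess,sticcs,tracking named lists overriding the default
#'   options (see the pipeline vignette for the full list).
#' @return List with `field` (classified `vector_field`), `tracking`
#'   ([track_cell()] output or NULL), and `summary`
#'   ([per_cell_summary()] row).
#' @export
analyze_cell <- function(gfp = NULL, eb3 = NULL, mask = NULL,
                         cell_id = "cell", condition = "",
                         preprocess = list(), sticcs = list(),
                         tracking = list()) {
  pp <- merge_opts(default_preprocess_opts(), preprocess)
  st <- merge_opts(default_sticcs_opts(), sticcs)
  tk <- merge_opts(default_tracking_opts(), tracking)
  if (is.null(eb3)) stop("the EB3 channel is required")

  prep <- function(s) {
    if (is.null(s)) return(NULL)
    if (pp$bleach_correct) s <- correct_photobleaching(s, mask)
    subtract_background_and_denoise(s, pp$bg_radius_px, pp$denoise_sigma_px)
  }
  gfp_p <- prep(gfp)
  eb3_p <- prep(eb3)

  trk <- NULL
  if (isTRUE(tk$enabled))
    trk <- track_cell(eb3_p, mask, sigma_px = tk$sigma_px,
                      quality_min = tk$quality_min,
                      max_link_px = tk$max_link_px,
                      max_gap_frames = tk$max_gap_frames,
                      max_gap_px = tk$max_gap_px,
                      min_quality = tk$min_quality,
                      min_displacement_um = tk$min_displacement_um,
                      min_frames = tk$min_frames)

  gfp_f <- if (!is.null(gfp_p)) immobile_filter(gfp_p, pp$n_low_freq)
  eb3_f <- immobile_filter(eb3_p, pp$n_low_freq)
  d <- dim(eb3_f$data)
  grid <- tile_voxels(d[1:2], d[3], mask = mask,
                      roi_size_px = st$roi_size_px,
                      roi_shift_px = st$roi_shift_px,
                      toi_len_frames = st$toi_len_frames,
                      toi_shift_frames = st$toi_shift_frames)
  field <- sticcs_vector_field(gfp_f, eb3_f, mask = mask, grid = grid,
                               modes = st$modes, tau_max = st$tau_max,
                               quality_min = st$quality_min,
                               amp_min_frac = st$amp_min_frac,
                               min_lags = st$min_lags,
                               cross_tau_max = st$cross_tau_max,
                               cross_min_lags = st$cross_min_lags,
                               cross_p0_radius = st$cross_p0_radius,
                               cross_quality_min = st$cross_quality_min,
                               gfp_mean_src = gfp_p, eb3_mean_src = eb3_p)
  field <- similarity_filter(field, st$angle_max_deg, st$mag_ratio_max,
                             st$min_similar_neighbors,
                             st$cross_min_similar)
  if (all(c("eb3_auto", "cross") %in% st$modes))
    field <- classify_cross_events(field,
                                   speed_ratio_max = st$speed_ratio_max,
                                   angle_max_deg = st$angle_max_deg,
                                   min_contrast = st$min_contrast,
                                   min_polymer = st$min_polymer)
  summ <- per_cell_summary(field, trk, cell_id = cell_id,
                           condition = condition)
  list(field = field, tracking = trk, summary = summ)
}

#' Bundled demonstration pipeline configuration
#'
#' Two simulated conditions (three cells each, 64 x 64 px x 100 frames)
#' differing in growth speed and explorative fraction, analysed with the
#' default parameters. Mirrors `inst/extdata/demo_config.json`.
#'
#' @param output_dir where [run_pipeline()] should write results.
#' @param seed master seed.
#' @return A pipeline configuration list.
#' @export
demo_config <- function(output_dir = tempfile("sticcs_demo_"), seed = 1) {
  list(
    output_dir = output_dir,
    seed = seed,
    conditions = list(
      list(name = "guided_fast", n_cells = 3,
           sim = list(explorative_fraction = 0.3, growth_speed_mean = 20)),
      list(name = "explorative_slow", n_cells = 3,
           sim = list(explorative_fraction = 0.6, growth_speed_mean = 12))),
    sim = list(image_shape = c(64, 64), n_frames = 100),
    preprocess = list(), sticcs = list(), tracking = list(),
    stats = list(reference = "guided_fast",
                 metrics = c("assembly_speed_um_min", "cross_fraction_pct",
                             "track_assembly_rate_um_min")),
    write_figures = TRUE)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  }
  cfg
}

#' Run the full simulate-and-analyse pipeline
#'
#' For every condition and cell in the configuration: simulate a
#' two-channel movie (seeded deterministically from the master seed),
#' analyse it with [analyze_cell()], and aggregate per-cell summaries and
#' group comparisons. All outputs are written under
#' `config$output_dir`: per-cell movies are not stored, but vector fields
#' (`vectors_<cell>.csv`), track metrics (`tracks_<cell>.csv`), the
#' per-cell summary table (`cell_summaries.csv`), group results
#' (`group_results.csv`), quiver maps (PNG) and a JSON report with every
#' parameter echoed for provenance. Identical configuration and seed give
#' identical outputs.
#'
#' @param config configuration list (see [demo_config()]) or a path to a
#'   JSON/YAML file.
#' @return Invisibly, a list with `summaries` (data.frame), `groups`
#'   (list of [group_compare()] results) and `output_dir`.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  summaries <- list()
  for (cond in config$conditions) {
    for (ci in seq_len(cond$n_cells)) {
      cell_id <- sprintf("%s_%02d", cond$name, ci)
      params <- stage("simulate", do.call(sim_params, c(
        merge_opts(config$sim %||% list(), cond$sim %||% list()),
        list(seed = derive_seed(seed, cell_id)))))
      sim <- stage("simulate", simulate_cell(params))
      res <- stage("analyze", analyze_cell(
        sim$gfp, sim$eb3, sim$mask, cell_id = cell_id,
        condition = cond$name,
        preprocess = config$preprocess %||% list(),
        sticcs = config$sticcs %||% list(),
        tracking = config$tracking %||% list()))
      stage("export", {
        write.csv(cbind(cell_id = cell_id, res$field$vectors),
                  file.path(out_dir, paste0("vectors_", cell_id, ".csv")),
                  row.names = FALSE)
        if (!is.null(res$tracking))
          write.csv(res$tracking$metrics,
                    file.path(out_dir, paste0("tracks_", cell_id, ".csv")),
                    row.names = FALSE)
        if (isTRUE(config$write_figures %||% TRUE))
          plot_vector_field(res$field, mode = "eb3_auto", it = 1,
                            file = file.path(out_dir,
                                             paste0("quiver_", cell_id,
                                                    ".png")))
      })
      summaries[[cell_id]] <- res$summary
    }
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  write.csv(summaries, file.path(out_dir, "cell_summaries.csv"),
            row.names = FALSE)

  groups <- list()
  if (length(config$conditions) >= 2) {
    ref <- config$stats$reference %||% config$conditions[[1]]$name
    for (metric in config$stats$metrics %||% "assembly_speed_um_min") {
      g <- stage("compare", tryCatch(
        group_compare(summaries, metric, reference = ref,
                      nonparametric =
                        isTRUE(config$stats$nonparametric)),
        error = function(e) NULL))
      if (!is.null(g)) groups[[metric]] <- g
    }
    if (length(groups)) {
      gr <- do.call(rbind, lapply(names(groups), function(m) {
        g <- groups[[m]]
        merge(cbind(metric = m, g$groups),
              data.frame(metric = m,
                         condition = c(as.character(g$groups$condition[1]),
                                       as.character(g$pairwise$condition)),
                         p_vs_reference = c(NA, g$pairwise$p.value)),
              by = c("metric", "condition"), all.x = TRUE, sort = FALSE)
      }))
      write.csv(gr, file.path(out_dir, "group_results.csv"),
                row.names = FALSE)
    }
  }

  report <- list(
    schema_version = "1.0",
    seed = seed,
    options = list(preprocess = merge_opts(default_preprocess_opts(),
                                           config$preprocess %||% list()),
                   sticcs = merge_opts(default_sticcs_opts(),
                                       config$sticcs %||% list()),
                   tracking = merge_opts(default_tracking_opts(),
                                         config$tracking %||% list())),
    conditions = config$conditions,
    tests = lapply(groups, function(g)
      list(test = g$omnibus$test, statistic = g$omnibus$statistic,
           p.value = g$omnibus$p.value,
           pairwise = g$pairwise)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(summaries = summaries, groups = groups,
                 output_dir = out_dir))
}

#' Generate the named validation fixture suites
#'
#' Writes the simulated movies and ground-truth files used by the
#' validation tests: `"uniform_flow"` (particle fields translating at
#' 0.2, 0.5 and 1.0 px/frame), `"static"` (a cell with no growth events),
#' `"explorative_mix"` (explorative fraction 0.5 with a large event
#' sample) and `"comet_field"` (50 growth events at 20 um/min).
#'
#' @param suite one of the suite names above.
#' @param dir output directory.
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(suite = c("uniform_flow", "static",
                                    "explorative_mix", "comet_field"),
                          dir = tempfile("fixtures_"), seed = 1) {
  suite <- match.arg(suite)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(suite,
    uniform_flow = {
      for (v in c(0.2, 0.5, 1.0)) {
        s <- simulate_uniform_flow(v = c(v, 0),
                                   seed = derive_seed(seed, paste0("uf", v)))
        tag <- sprintf("flow_v%03d", round(100 * v))
        write_movie(s, file.path(dir, paste0(tag, ".tif")))
        jsonlite::write_json(list(vx = v, vy = 0),
                             file.path(dir, paste0(tag, "_truth.json")),
                             auto_unbox = TRUE, digits = NA)
      }
    },
    static = {
      p <- sim_params(n_events = 0, seed = derive_seed(seed, "static"))
      write_simulation(simulate_cell(p), p, dir, "static")
    },
    explorative_mix = {
      p <- sim_params(explorative_fraction = 0.5, n_events = 2000,
                      seed = derive_seed(seed, "mix"))
      fibers <- build_fiber_map(p)
      events <- sample_growth_events(fibers, p)
      truth <- ground_truth(events, p)
      rows <- do.call(rbind, lapply(seq_along(events), function(i) {
        ev <- events[[i]]
        data.frame(event = i, frame = ev$trajectory$t, x = ev$trajectory$x,
                   y = ev$trajectory$y, speed_um_min = ev$speed_um_min,
                   explorative = ev$explorative)
      }))
      write.csv(rows, file.path(dir, "mix_truth.csv"), row.names = FALSE)
      jsonlite::write_json(truth, file.path(dir, "mix_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      # render a movie with a workable number of events for image tests
      p2 <- sim_params(explorative_fraction = 0.5,
                       seed = derive_seed(seed, "mix_movie"))
      write_simulation(simulate_cell(p2), p2, dir, "mix")
    },
    comet_field = {
      # larger field and longer movie so 50 events sit at a realistic
      # comet density for single-particle tracking (comets closer than
      # the PSF merge optically)
      p <- sim_params(image_shape = c(96, 96), n_frames = 150,
                      n_fibers = 48, n_events = 50,
                      seed = derive_seed(seed, "comets"))
      write_simulation(simulate_cell(p), p, dir, "comets")
    })
  invisible(dir)
}
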