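# Config-driven orchestration of the full analysis: simulate or ingest an
# ensemble, assign chi states, cluster with symmetry, trace convergence
# (windowed populations and KLD), build the PC1/PC2 free-energy landscape,
# optionally classify C/C mismatch hydrogen bonding, and write a
# machine-readable JSON report with full provenance.

default_config <- function() {
  list(
    sequence = "UCUGGGGCCAGA",
    loop = c(6L, 7L, 18L, 19L),
    selection = list(atoms = "heavy"),   # residues default to loop
    symmetry = TRUE,
    cluster_method = "greedy",
    cutoff = 1.0,
    min_pct = 1.0,
    burn_in = 0L,
    window = NULL,                       # frames; default nf/10
    pca_modes = 1:2,
    nbins_1d = 300L,
    nbins_2d = 100L,
    n_eval = 50L,
    temperature = 300,
    hbond = list(d_max = 3.5, a_min = 135),
    mismatch = NULL,                     # c(i, j) residue pair, optional
    seed = 1L)
}

merge_config <- function(user) {
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

stage <- function(name, expr, log) {
  t0 <- proc.time()[3L]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %-12s %6.1f s", name, proc.time()[3L] - t0))
  res
}

#' Run the full ensemble-analysis pipeline
#'
#' Stages: input (a supplied trajectory, an [ensemble_spec()], or a
#' trajectory file), chi state labels, symmetry-aware clustering with the
#' population report, windowed cluster-population trace, PCA + KLD
#' convergence (first vs second half of the ensemble), PC1/PC2 free-energy
#' landscape with basin detection, and optional C/C mismatch hydrogen-bond
#' classification.  Every stage's table is written under `outdir` as plain
#' CSV, and `report.json` aggregates the headline numbers with a
#' provenance block sufficient to reproduce the run.
#'
#' @param config named list overriding the defaults (sequence, loop,
#'   symmetry, cluster_method `"greedy"`/`"average"`, cutoff, min_pct,
#'   burn_in, window, pca_modes, nbins_1d = 300, nbins_2d = 100, n_eval,
#'   temperature, hbond criteria, mismatch, seed), or a path to a JSON
#'   file of the same shape.  Exactly one of `config$spec` (an
#'   [ensemble_spec()]), `config$traj` (a [trajectory()]), or
#'   `config$input` (a trajectory file path, with `config$topology_file`)
#'   must supply the ensemble.
#' @param outdir output directory (created if needed).
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("loopdyn_run_")) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), msg)
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }

  input <- stage("input", {
    if (!is.null(cfg$traj)) {
      list(traj = cfg$traj, labels = NULL)
    } else if (!is.null(cfg$spec)) {
      sample_ensemble(cfg$spec)
    } else if (!is.null(cfg$input)) {
      top <- load_topology(cfg$topology_file %||% cfg$input)
      list(traj = load_trajectory(cfg$input, top), labels = NULL)
    } else stop("no input: supply spec, traj, or input path")
  }, log)
  traj <- input$traj
  top <- traj$topology
  if (cfg$symmetry && length(top$symmetry_perms) < 2L) {
    chains <- unique(top$atoms$chain)
    if (length(chains) == 2L)
      top <- tryCatch(set_symmetry(top, chains[1L], chains[2L]),
                      error = function(e) top)
    traj$topology <- top
  }
  nf <- n_frames(traj)
  loop <- cfg$loop
  sel_res <- cfg$selection$residues %||% loop
  sel <- select_atoms(top, residues = sel_res, atoms = cfg$selection$atoms %||% "heavy")

  chi_tab <- stage("chi", {
    cs <- chi_series(traj, loop)
    states <- matrix(classify_state(cs$values), nrow = nf)
    d <- data.frame(frame = rep(seq_len(nf), times = length(loop)),
                    residue = rep(loop, each = nf),
                    chi_deg = as.vector(cs$values),
                    state = as.vector(states))
    utils::write.csv(d, file.path(outdir, "chi.csv"), row.names = FALSE)
    d
  }, log)

  n1 <- length(loop) %/% 2L
  labeler <- function(f) {
    cs <- chi_series(trajectory(frame_coords(traj, f), top), loop)
    st <- classify_state(cs$values[1L, ])
    loop_state_label(st[seq_len(n1)], st[(n1 + 1L):length(loop)],
                     symmetry = cfg$symmetry)
  }

  clust <- stage("cluster", {
    cl <- if (cfg$cluster_method == "average")
      hier_cluster_average_linkage(traj, cfg$cutoff, sel, cfg$symmetry)
    else greedy_cluster(traj, cfg$cutoff, sel, cfg$symmetry)
    utils::write.csv(data.frame(frame = seq_len(nf), cluster = cl$labels),
                     file.path(outdir, "cluster_labels.csv"), row.names = FALSE)
    cl
  }, log)
  report_tab <- report_clusters(clust, cfg$min_pct, state_labeler = labeler)
  utils::write.csv(report_tab, file.path(outdir, "cluster_report.csv"),
                   row.names = FALSE)

  window <- cfg$window %||% max(1L, nf %/% 10L)
  trace <- stage("population_trace", {
    tracked <- report_tab$cluster[!is.na(report_tab$cluster)]
    tr <- population_trace(clust$labels, window = window,
                           burn_in = cfg$burn_in, track = tracked)
    utils::write.csv(tr, file.path(outdir, "population_trace.csv"),
                     row.names = FALSE)
    tr
  }, log)

  conv <- stage("converge", {
    pcm <- fit_pca(traj, sel)
    proj <- project_pcs(traj, pcm, cfg$pca_modes)
    half <- nf %/% 2L
    curves <- lapply(seq_along(cfg$pca_modes), function(k) {
      kc <- kld_curve(proj[seq_len(half), k], proj[(half + 1L):nf, k],
                      nbins = cfg$nbins_1d, n_eval = cfg$n_eval)
      cbind(mode = cfg$pca_modes[k], as.data.frame(kc))
    })
    kld_tab <- do.call(rbind, curves)
    utils::write.csv(kld_tab, file.path(outdir, "kld.csv"), row.names = FALSE)
    list(pcm = pcm, proj = proj, kld = kld_tab)
  }, log)

  land <- stage("landscape", {
    grid <- pmf2d(conv$proj[, 1L], conv$proj[, 2L], nbins = cfg$nbins_2d,
                  temperature = cfg$temperature)
    basins <- find_minima(grid)
    utils::write.csv(basins, file.path(outdir, "basins.csv"), row.names = FALSE)
    list(grid = grid, basins = basins)
  }, log)

  cc <- if (!is.null(cfg$mismatch)) stage("ccstate", {
    classify_cc_state(traj, cfg$mismatch, cfg$hbond$d_max, cfg$hbond$a_min)
  }, log) else NULL

  report <- list(
    n_frames = nf,
    clusters = report_tab,
    kld_final = stats::aggregate(kld ~ mode, conv$kld, function(x) x[length(x)]),
    basins = land$basins,
    cc_fractions = if (!is.null(cc)) as.list(cc$fractions) else NULL,
    provenance = list(
      package = "loopdyn",
      version = as.character(utils::packageVersion("loopdyn")),
      seed = cfg$seed,
      parameters = cfg[c("sequence", "loop", "symmetry", "cluster_method",
                         "cutoff", "min_pct", "burn_in", "pca_modes",
                         "nbins_1d", "nbins_2d", "n_eval", "temperature")],
      window = window,
      selection = list(residues = sel_res, atoms = cfg$selection$atoms %||% "heavy")))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
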